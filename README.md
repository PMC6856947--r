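# homgroups

Latent interpretive groups in judgments of plural definite descriptions.

## The scientific problem

Plural definite descriptions show *homogeneity*: in a mixed ("gap")
situation where some but not all of the trucks are blue, both *The trucks
are blue* and *The trucks aren't blue* are neither true nor false. How a
subject — in particular a preschool child still acquiring the construction
— resolves this gap reveals their interpretation of the definite plural:

* an **existential** reader (`exi`) accepts the positive sentence and
  rejects the negation (∃: true iff k ≥ 1 of n objects match);
* a **universal** reader (`uni`) does the reverse (∀: true iff k = n);
* a **homogeneous** (adult-like) reader (`hom`) treats both as non-true.

A prominent semantic analysis derives homogeneity as a *scalar
implicature*: the definite has a literal existential meaning which
recursive exhaustification over the alternatives {some, all} strengthens
to the universal one, exh(exh(the)) = ∀. If that is right, no subject
should show homogeneity without also computing the ordinary
some-but-not-all implicature. Testing this requires classifying individual
subjects jointly by their reading of the definite and their implicature
behaviour (`hom/-si`, `exi/+si`, …) — a latent-class problem over noisy
categorical judgments.

`homgroups` implements the full analysis chain for the two standard
designs (a binary accept/reject task with 24 test trials, and a ternary
reward task, −1/0/+1, with 26 trials and extra strategy controls):

1. **Semantics → templates.** A finite-model trivalent semantics with
   (recursive) exhaustification derives each group's predicted response
   per condition (`derive_template()`, `exhaustify()`).
2. **Synthetic cohorts.** A seeded generator produces cohorts with known
   latent groups and a symmetric lapse rate ε over the exact trial
   inventories (`simulate_cohort()`).
3. **Descriptive categorization.** Majority-rule classification,
   6-of-8-controls inclusion, ternary response-bias flags, and Pearson
   chi-square comparisons of group distributions
   (`categorize_homogeneity()`, `chi_square_2xk()`).
4. **Randomness enumeration.** Exact multinomial tail probabilities that
   the observed group configuration arose from random responders, with a
   Monte-Carlo cross-check through the real categorizer
   (`tail_prob_scenario_a()`, `tail_prob_scenario_b()`).
5. **Latent-group mixture model.** A Bayesian finite mixture with a
   per-subject latent group: Bernoulli-logit
   (P(accept) = logistic(α + β·t), t the template value) or
   cumulative-logit (cutpoints c₁ < c₂, predictor β·t) observation model;
   posterior group probabilities; leave-one-out elpd comparison across
   group inventories (`fit_mixture()`, `loo_elpd()`,
   `compare_inventories()`).

## Worked example

Simulate a 24-child binary cohort whose mixture mirrors a typical child
distribution, categorize, fit, and compare inventories:

```r
library(homgroups)

cfg <- sim_config("binary", n_subjects = 24,
                  group_weights = c("hom/-si" = 6, "hom/+si" = 10,
                                    "exi/-si" = 7, "exi/+si" = 1) / 24,
                  lapse_rate = 0.05, seed = 42)
records <- simulate_cohort(cfg)

kept <- apply_inclusion(records)            # 6-of-8 controls criterion
group_count_table(summarize_subjects(records))
#>             minus_si plus_si mixed
#> homogeneous        6       9     0
#> existential        9       0     0
#> universal          0       0     0

fit <- fit_mixture(records[records$subject_id %in% kept, ],
                   model_spec("binary", seed = 1))
assignment_counts(fit)
#>     -si +si
#> exi   9   0
#> hom   6   9
#> uni   0   0

compare_inventories(records, list(
  all = model_spec("binary", seed = 1),
  no_hom_minus = model_spec("binary",
    groups = setdiff(design_groups("binary"), "hom/-si"), seed = 1)))
#>      inventory   elpd    se  delpd delpd_se
#> 1          all -115.4 15.28   0.00      0.0
#> 2 no_hom_minus -153.9 17.65 -38.48     11.3
```

The descriptive table and the model's argmax assignments agree (at this
lapse rate one noisy `hom/+si` subject drifts between cells), and removing
the homogeneous/no-implicature group from the inventory costs about 38
elpd units — strong evidence that the group is populated in this cohort.
The exact tail probability that six-or-more of eight random responders
would produce such a configuration is `tail_prob_scenario_a(8)` =
5.65e-04.

The ternary paradigm works identically with `sim_config("ternary", ...)`,
`model_spec("ternary", ...)` and the analysis presets in
`exp2_analysis_specs()`, which compare inventories containing the
scope-ambiguity (`sa`), strict wide-scope (`ws`) and partial-truth (`pt`)
strategy readings.

`run_pipeline(pipeline_config(...))` executes the whole chain and writes
every table (subject summaries, group counts, chi-square, enumeration,
posterior group probabilities, inventory comparison, per-subject means)
as CSV with a JSON manifest.

## Methods

See the methods vignette (`vignettes/latent-groups.Rmd`) for the model,
priors, the grid and Gibbs inference backends, what the synthetic cohorts
do and do not emulate, and known limitations.
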