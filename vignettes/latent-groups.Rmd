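---
title: "Latent interpretive groups in homogeneity judgments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent interpretive groups in homogeneity judgments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homgroups)
```

This vignette documents the scientific and numerical choices behind
`homgroups`: the trivalent semantics that generates the response
templates, the synthetic-cohort generator, the descriptive and
model-based categorizations, the exact enumeration of the
random-responder null, and the mixture model's inference backends.

## 1. The semantic fragment and response templates

All design sentences are evaluated over a finite domain of `n_objects`
displayed objects (4 by default, matching the displays used in this
paradigm; the domain size is a parameter everywhere). A positive
sentence's meaning is its truth set, the set of counts `k` of matching
objects at which it is true: `some` is `{k >= 1}`, `all` is `{k = n}`,
and the plural definite is ambiguous between an existential construal
(`{k >= 1}`) and a universal one (`{k = n}`).

Truth values are trivalent. The homogeneous reading of a positive
definite is true iff all objects match, false iff none do, and otherwise
falls in a truth-value gap; trivalent negation swaps true and false and
fixes the gap, so the negated definite is gappy in exactly the same mixed
situations. The existential and universal readings are bivalent, with
sentential negation scoping over them; the wide-scope construals (`ws`,
`wse`) instead give the quantifier scope over negation.

`exhaustify()` implements the covert only-like operator behind scalar
implicatures: the prejacent is conjoined with the negations of its
excludable alternatives. Exclusion is computed greedily in the listed
alternative order: an alternative is excluded iff it is not entailed by
the prejacent and negating it jointly with the alternatives already
excluded leaves the meaning non-empty. On this three-determiner fragment
the criterion coincides with excluding strictly stronger alternatives in
the single-level case, and — unlike the stricter "innocent exclusion"
intersection over all maximal excludable sets, which excludes nothing at
the recursive step because the strengthened alternatives jointly cover
the prejacent — it lets the two-level application go through:

```{r}
exhaustify(1:4, list(4L), 4)                 # some + {all} -> 1..3
recursive_exhaustify(1:4, list(1:4, 4L), 4)  # the + {some, all} -> 4
```

The second line is the derivation at the heart of the implicature account
of homogeneity: recursively exhaustifying the existential literal meaning
of the definite yields the universal meaning, at every domain size
(checked for n = 2..8 in the tests).

`derive_template()` turns the semantics into a predicted response per
condition for each interpretive group (a reading paired with an
implicature flag, e.g. `hom/-si`). Binary paradigm: accept iff true, and
a truth-value gap maps to rejection — the operationalization under which
gap-context definites are assessed as non-true. Ternary paradigm: true
maps to the maximal reward (+1), false to the minimal (−1), a gap to the
intermediate (0), and a literally true sentence with a false implicature
also earns the intermediate reward. The implicature flag acts only on
sentences with lexical *some*: this is required for the template algebra
to make the existential/`+si` group accept a positive gap-context
definite, and reflects the assumption that an implicature computer who
still construes the definite existentially does not strengthen it.

Two groups of cells are not fixed by the semantics alone and are exposed
as explicit choices:

* **Strategy readings.** `sa` (universal reading plus a scope-ambiguity
  strategy) scores the negated definite in a gap context intermediate —
  true on one scopal construal, false on the other — while the positive
  one is plainly false. `pt` (wide-scope universal plus partial truth)
  upgrades any false-but-partially-true universal claim to the
  intermediate reward.
* **The negated universal in a gap context (`all-gap-neg`) under
  `sa`/`ws`/`pt`.** The sentence has a true low-scope construal and a
  false surface-scope construal, and nothing in the reading definitions
  dictates how a strategy user scores it. The defaults
  (`strategy_overrides()`: `sa` → maximal, `ws`/`pt` → intermediate)
  are fixed conventions: `sa` keeps the plain low-scope evaluation (maximal), while `ws` and `pt` score the scopally conflicted sentence intermediate;
  they are overridable because they are conventions, not derivations.

## 2. The synthetic-cohort generator

`simulate_cohort()` generates the two designs exactly: 24 binary test
trials (3+3 gap-context definites, 8 clearly true/false definite
controls, 3+3 universal controls, 4 implicature targets) or 26 ternary
trials (3+3 definites, 8 controls, 3 implicature targets, 3
incomplete-description, 3 partial-truth and 3 scope-ambiguity controls).
Orders are pseudorandom from the seed with every third trial a definite
control, as in the original interactive procedure. The original
experiments chose each control's truth value online in reaction to the
child's previous answers; that policy is irrelevant to inference, so the
generator balances the eight controls (half clearly true, half clearly
false), preserving the anti-bias purpose of the dynamic selection.

Each subject draws a latent group from configurable mixture weights; the
default binary weights (0.25, 0.42, 0.29, 0.04 over
`hom/-si, hom/+si, exi/-si, exi/+si`) mirror a typical child
distribution in this paradigm. Responses equal the group's template value
except with probability ε (the lapse rate), when they are replaced by a
uniform draw over the other response option(s). A single symmetric ε
shared across conditions is a deliberate simplification: real children
show condition-specific infelicity effects (e.g. on negated definites in
"none" contexts) which the generator does not model. Consequently,
passing recovery tests on synthetic cohorts demonstrates that the
estimators invert the generative model they assume — not that real
judgment data are this clean. One master seed feeds independent derived
streams for trial order, group draws and lapses, so changing the cohort
size never perturbs the trial list.

## 3. Descriptive categorization

The majority rules operate on the three positive and three negative
gap-context definite trials. Binary: reject/reject is homogeneous,
accept/reject existential, reject/accept universal, accept/accept the
fourth logically possible (wide-scope existential) pattern; the four
categories partition all 2^6 response patterns. Ternary: mostly-maximal /
mostly-minimal is existential, the reverse universal, and
mostly-non-maximal on both sides is homogeneous; existential and
universal are checked before homogeneous, and the homogeneous category
additionally requires at least one intermediate response so that an
all-minimal pattern (the strict wide-scope universal profile) is left
`inconsistent` rather than conflated with homogeneity.

Implicature categorization uses at-least-3-of-4 (binary, four targets)
or majority-of-3 (ternary) thresholds, with ternary "rejection" meaning
any non-maximal reward — a minimal *or* intermediate reward for a true
but underinformative sentence indicates the implicature. The ternary
majority threshold is adopted by analogy with the homogeneity rule, the
four-trial rule having no three-trial analogue stated for it.

Inclusion requires 6 of 8 definite controls correct; the ternary bias
flags (incomplete description: fewer than 2/3 maximal; partial truth:
fewer than 2/3 minimal; scope ambiguity: more than 1/3 intermediate)
implement the maximally stringent exclusion criterion.
`chi_square_2xk()` is the plain Pearson statistic with no continuity
correction; the package reports the statistic and df and leaves p-value
lookups to the caller.

## 4. The random-responder null

If `n` children answered at random, their majority patterns land in the
four homogeneity categories with probability 1/4 each; adding four
random implicature answers factors in 5/16, 5/16, 6/16 for
`plus_si`/`minus_si`/`mixed`. Scenario A (random on homogeneity targets
only) has the closed form
$(1/4)^n \sum_{k \ge 6} \binom{n}{k}$, computed with exact integer
numerator and denominator (both representable exactly in double
precision for all relevant `n`; the `n = 8` value is exactly
$37/65536$). Scenario B (random on both target types) is an exact
multinomial tail over the count in the homogeneous/`-si` cell (≥ 6, at
5/64), the existential/`+si` cell (≤ 1, at 5/64) and the forbidden
universal/wide-scope cells (0, total 1/2); terms are evaluated in log
space (relative error ~1e−12, ten orders of magnitude below the 1e−4
bound of interest). Children in implicature-`mixed` cells of allowed
rows are left unconstrained by the event, matching the event description;
`constrain_mixed = TRUE` computes the stricter reading, and the tests
verify the reported bound holds either way. `monte_carlo_tail()`
simulates random responders through the actual majority-rule categorizer,
so the enumeration and the categorizer validate each other.

## 5. The latent-group mixture model

Each subject `s` carries a latent group `z_s` with mixture weights `pi`.
Given the group, responses are conditionally independent across trials:

* binary: `P(accept) = logistic(alpha + beta * t)` with `t` in {0, 1}
  the group's template value for the condition;
* ternary: a cumulative logit with linear predictor `beta * t`,
  `t` in {−1, 0, 1}, and ordered cutpoints `c1 < c2` separating the
  minimal / intermediate / maximal rewards. The ternary model has no
  separate intercept: with free cutpoints an intercept is not
  identified, so the cutpoints absorb it (standard cumulative-logit
  identifiability).

The likelihood marginalizes the group per subject,
`p(y_s | theta, pi) = sum_g pi_g prod_i p(y_si | g, theta)` (checked
against brute-force enumeration over group assignments on small cohorts).
Priors are weakly informative and zero-centred: `alpha ~ N(0, 3)`,
cutpoints `N(0, 4)`, `beta ~ half-N(0, 4)` constrained positive — the
sign constraint pins the direction of the template effect and makes the
mixture identifiable — and a flat Dirichlet on `pi`.

Two backends share all of this structure:

* **`grid`** (default, deterministic): the continuous parameters live on
  a coarse grid (binary: 13 intercepts × 10 slopes; ternary: 6 × 6
  cutpoint pairs × 10 slopes) extending into the saturated regime
  (|alpha| ≤ 6, beta ≤ 12), so noiseless cohorts can be fit essentially
  perfectly. Mixture weights are estimated by an EM fixed point
  (tolerance 1e−9, capped at 500 iterations, non-convergence warned);
  the posterior over the grid is then exact given those weights.
  Per-subject group probabilities average the conditional
  `p(z_s | y_s, theta, pi)` over the grid posterior.
* **`mcmc`**: a Gibbs sampler alternating the group labels (categorical),
  the weights (Dirichlet), and the grid cell of the continuous
  parameters (categorical over the grid). A split R-hat on the
  log-posterior trace is reported and a warning is raised above 1.1.

For leave-one-out comparison both backends produce posterior draws of
(parameters, group labels); the pointwise log-likelihood of each
observation under each draw feeds a truncated-importance-sampling LOO
(ratios truncated at `mean * sqrt(S)`), with the fraction of truncated
observations reported as a diagnostic and an exact
refit-per-observation oracle (`loo_exact()`) available — the two agree
within Monte-Carlo error on the small cohorts where the exact version is
affordable. Comparison tables report each inventory's elpd with its
standard error and the difference to the best model with a paired
standard error from the pointwise contributions.

Group assignment is the posterior argmax with a deterministic
lowest-index tie-break (ties flagged). The ternary analysis presets
(`exp2_analysis_specs()`) encode the three model families: Analysis 1
restricts to the definite conditions plus the implicature target,
allows `hom/+si` as the only implicature-computing group, and crosses the
presence of `hom/-si`, `ws/-si` and `sa/-si`; Analysis 2 drops the
implicatures-imply-homogeneity assumption by always allowing `sa/+si`
and `ws/+si`; Analysis 3 adds the positive universal gap condition, which
is what separates the partial-truth strategy from true homogeneity, and
pairs each model with a `pt/-si` counterpart. The existential/`+si`
group is excluded from ternary inventories by default, carrying over its
near-absence in the binary paradigm.

## 6. Problem sizes, determinism, degenerate inputs

The shipped tests and the acceptance script run cohorts of 24 subjects
(the experiments' size) for identifiability checks, 240 subjects per
lapse level for the noise-robustness curve, 1e5–2e5 Monte-Carlo
repetitions for the enumeration cross-checks, and cohorts of ≤ 4 subjects
for the exact-LOO and brute-force-marginalization oracles; these sizes
give the relevant standard errors (≈ 3% on a recovery proportion,
≈ 5e−5 on a tail estimate) while keeping a full run in the low minutes
on one CPU. All randomness flows from explicit integer seeds through
independent derived streams; rerunning any function with the same inputs
is bit-reproducible. Degenerate inputs fail loudly: empty prejacents,
inadmissible (group, paradigm) pairs, missing trials, zero chi-square
margins, impossible enumeration events (`n < 6`) and malformed CSVs all
raise errors naming the offender rather than coercing.

## 7. Known limitations

* The lapse model is a single symmetric ε; condition-specific infelicity
  and response biases in real data are flagged (ternary) but not
  generated or modelled.
* Age is a label, not a covariate; the mixture pools all subjects it is
  given.
* The grid backend's posterior is conditional on EM point estimates of
  the mixture weights (an empirical-Bayes approximation); the Gibbs
  backend integrates over the weights but discretizes the continuous
  parameters to the same grid. Neither resolves parameters finer than
  the grid spacing, which is intentional: the quantities of interest
  (group probabilities, elpd differences) are insensitive to it at these
  sample sizes, and the tests compare the two backends against each
  other and against exact oracles.
* The recursive-exhaustification machinery covers the three-determiner
  fragment only; it is not a general implicature calculus, and
  non-maximality pragmatics are out of scope.
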