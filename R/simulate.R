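#' Simulation configuration
#'
#' Bundles everything needed to generate a synthetic cohort: the judgment
#' paradigm, the cohort size, the mixture of latent interpretive groups, a
#' lapse rate, the display's domain size and a master seed. The lapse rate
#' `epsilon` is the probability that a response deviates from the subject's
#' template, replaced by a uniform draw over the other response option(s);
#' it stands in for the unmodelled trial-level noise visible in real
#' judgment data.
#'
#' @param paradigm `"binary"` or `"ternary"`.
#' @param n_subjects Number of simulated subjects.
#' @param group_weights Named numeric vector of group probabilities (names
#'   are group labels such as `"hom/-si"`); must sum to 1.
#' @param lapse_rate Lapse probability in `[0, 1]`.
#' @param age_group `"child"` or `"adult"` (a label carried through to the
#'   records; age is not a covariate of any model here).
#' @param n_objects Domain size of the displays (default 4).
#' @param seed Master integer seed; trial order, group draws and lapses use
#'   independent streams derived from it, so changing `n_subjects` does not
#'   perturb the trial list.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(paradigm = c("binary", "ternary"),
                       n_subjects = 24L,
                       group_weights = c("hom/-si" = 0.25, "hom/+si" = 0.42,
                                         "exi/-si" = 0.29, "exi/+si" = 0.04),
                       lapse_rate = 0.05,
                       age_group = c("child", "adult"),
                       n_objects = 4L,
                       seed = 1L) {
  paradigm <- match.arg(paradigm)
  age_group <- match.arg(age_group)
  stopifnot(n_subjects >= 0L, lapse_rate >= 0, lapse_rate <= 1,
            n_objects >= 2L, length(group_weights) >= 1L)
  if (is.null(names(group_weights)) || any(!nzchar(names(group_weights)))) {
    stop("group_weights must be a named vector of group labels",
         call. = FALSE)
  }
  for (g in names(group_weights)) check_group(g, paradigm)
  if (abs(sum(group_weights) - 1) > 1e-8) {
    stop("group_weights must sum to 1", call. = FALSE)
  }
  structure(
    list(paradigm = paradigm, n_subjects = as.integer(n_subjects),
         group_weights = group_weights, lapse_rate = lapse_rate,
         age_group = age_group, n_objects = as.integer(n_objects),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# independent small-integer streams derived from one master seed
derive_seed <- function(seed, stream) {
  m <- 2147483647
  as.integer((((as.numeric(seed) %% m) * 69069 + 12345 * stream) %% m))
}

exp1_composition <- function() {
  c("the-gap-pos" = 3L, "the-gap-neg" = 3L,
    "the-all-pos" = 2L, "the-all-neg" = 2L,
    "the-none-pos" = 2L, "the-none-neg" = 2L,
    "all-gap-pos" = 3L, "all-gap-neg" = 3L,
    "some-all-pos" = 4L)
}

exp2_composition <- function() {
  c("the-gap-pos" = 3L, "the-gap-neg" = 3L,
    "the-all-pos" = 2L, "the-all-neg" = 2L,
    "the-none-pos" = 2L, "the-none-neg" = 2L,
    "some-all-pos" = 3L, "some-gap-pos" = 3L,
    "all-gap-pos" = 3L, "all-gap-neg" = 3L)
}

#' Build a trial list replicating an experiment's design
#'
#' Experiment 1 (binary) has 24 test trials: six homogeneity targets (3
#' positive, 3 negative gap-context definites), eight clearly true/false
#' definite controls, six universal-quantification controls and four scalar
#' implicature targets. Experiment 2 (ternary) has 26: the same targets and
#' definite controls plus three implicature targets, three incomplete-
#' description controls, three partial-truth controls and three
#' scope-ambiguity controls. The original procedure selected the truth value
#' of each definite control online in reaction to the child's answers; here
#' the eight controls are balanced, half clearly true and half clearly
#' false, which preserves the anti-bias purpose without the interactivity.
#' Ordering is pseudorandom from the seed with every third trial a definite
#' control, as in the original presentation.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param seed Integer seed for the trial ordering.
#' @return Data frame with columns `trial_index` and `condition`.
#' @export
build_trial_list <- function(experiment = c("exp1", "exp2"), seed = 1L) {
  experiment <- match.arg(experiment)
  comp <- if (experiment == "exp1") exp1_composition() else exp2_composition()
  all_trials <- rep(names(comp), comp)
  is_control <- grepl("^the-(all|none)-", all_trials)
  controls <- all_trials[is_control]
  targets <- all_trials[!is_control]
  n <- length(all_trials)
  control_slots <- seq(3L, n, by = 3L)[seq_along(controls)]
  out <- character(n)
  rng <- local_rng(derive_seed(seed, 1L))
  on.exit(rng())
  out[control_slots] <- sample(controls)
  out[-control_slots] <- sample(targets)
  data.frame(trial_index = seq_len(n), condition = out,
             stringsAsFactors = FALSE)
}

# evaluate expr under a temporary RNG state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Draw a cohort of subjects with latent groups
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `subject_id`, `age_group`, `true_group`.
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  if (n == 0L) {
    return(data.frame(subject_id = character(0), age_group = character(0),
                      true_group = character(0), stringsAsFactors = FALSE))
  }
  rng <- local_rng(derive_seed(config$seed, 2L))
  on.exit(rng())
  groups <- sample(names(config$group_weights), n, replace = TRUE,
                   prob = config$group_weights)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age_group = config$age_group,
    true_group = groups,
    stringsAsFactors = FALSE
  )
}

#' Simulate responses for a cohort over a trial list
#'
#' Each response equals the subject's template value with probability
#' `1 - epsilon`; with probability `epsilon` it is replaced by a uniform draw
#' over the other response option(s) (one other option in the binary
#' paradigm, two in the ternary).
#'
#' @param subjects Data frame from [sample_population()].
#' @param trials Data frame from [build_trial_list()].
#' @param config A [sim_config()].
#' @return Long-format data frame of response records with columns
#'   `subject_id`, `age_group`, `paradigm`, `trial_index`, `condition`,
#'   `response`, `true_group`.
#' @export
simulate_responses <- function(subjects, trials, config) {
  stopifnot(inherits(config, "sim_config"))
  paradigm <- config$paradigm
  opts <- if (paradigm == "binary") c(0, 1) else c(-1, 0, 1)
  templates <- vapply(unique(subjects$true_group), function(g) {
    derive_template(g, paradigm, config$n_objects)
  }, numeric(length(design_conditions(paradigm))))
  rng <- local_rng(derive_seed(config$seed, 3L))
  on.exit(rng())
  n_s <- nrow(subjects)
  n_t <- nrow(trials)
  rec <- expand.grid(trial_index = trials$trial_index,
                     subject_id = subjects$subject_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec <- rec[, c("subject_id", "trial_index")]
  rec$condition <- trials$condition[rec$trial_index]
  rec$true_group <- subjects$true_group[match(rec$subject_id,
                                              subjects$subject_id)]
  rec$age_group <- subjects$age_group[match(rec$subject_id,
                                            subjects$subject_id)]
  template_val <- templates[cbind(rec$condition, rec$true_group)]
  lapse <- stats::runif(n_s * n_t) < config$lapse_rate
  response <- template_val
  if (any(lapse)) {
    response[lapse] <- vapply(template_val[lapse], function(t) {
      others <- opts[opts != t]
      if (length(others) == 1L) others else sample(others, 1L)
    }, numeric(1L))
  }
  rec$response <- response
  rec$paradigm <- paradigm
  rec[, c("subject_id", "age_group", "paradigm", "trial_index",
          "condition", "response", "true_group")]
}

#' Simulate a full cohort (population + trial list + responses)
#'
#' @param config A [sim_config()]. The binary paradigm uses the Experiment 1
#'   trial list, the ternary paradigm the Experiment 2 list.
#' @return Long-format response records (see [simulate_responses()]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  experiment <- if (config$paradigm == "binary") "exp1" else "exp2"
  trials <- build_trial_list(experiment, seed = derive_seed(config$seed, 1L))
  subjects <- sample_population(config)
  simulate_responses(subjects, trials, config)
}

# -- long-format CSV I/O -----------------------------------------------------

record_columns <- c("subject_id", "age_group", "paradigm", "trial_index",
                    "condition", "response", "true_group")

#' Read and write long-format response records
#'
#' One row per subject x trial; columns `subject_id`, `age_group`,
#' `paradigm`, `trial_index`, `condition`, `response` and (for simulated
#' data) `true_group`. The round trip through `write_responses()` /
#' `read_responses()` is lossless.
#'
#' @param records Response records data frame.
#' @param path CSV file path.
#' @return `read_responses()` returns the records data frame.
#' @export
write_responses <- function(records, path) {
  keep <- intersect(record_columns, names(records))
  utils::write.csv(records[, keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(record_columns, "true_group"), names(df))
  if (length(missing) > 0L) {
    stop("response CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$trial_index <- as.integer(df$trial_index)
  df$response <- as.numeric(df$response)
  df
}

#' @rdname write_responses
#' @param config A [sim_config()] to serialize.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$group_weights <- as.list(x$group_weights)  # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(paradigm = x$paradigm, n_subjects = x$n_subjects,
             group_weights = unlist(x$group_weights),
             lapse_rate = x$lapse_rate, age_group = x$age_group,
             n_objects = x$n_objects, seed = x$seed)
}
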