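#' Pipeline configuration
#'
#' Describes one end-to-end run: either a simulation block (one
#' [sim_config()] per age group) or a path to an input response CSV,
#' the mixture inventories to compare, an output directory and a master
#' seed. Exactly one of `cohorts` / `input` must be given.
#'
#' @param experiment `"exp1"` (binary) or `"exp2"` (ternary).
#' @param cohorts Named list of [sim_config()] objects (names are age-group
#'   labels, e.g. `child`, `adult`), or `NULL` when reading from `input`.
#' @param input Path to a long-format response CSV, or `NULL`.
#' @param inventories Named list of group inventories (character vectors)
#'   to compare with the mixture model; `NULL` for a single default fit.
#' @param backend Mixture backend, `"grid"` or `"mcmc"`.
#' @param enumeration_n Range of hypothetical random-responder counts for
#'   the enumeration table.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = c("exp1", "exp2"),
                            cohorts = NULL, input = NULL,
                            inventories = NULL, backend = "grid",
                            enumeration_n = 6:24,
                            out_dir = tempfile("homgroups_run_"),
                            seed = 1L) {
  experiment <- match.arg(experiment)
  if (is.null(cohorts) == is.null(input)) {
    stop("exactly one of cohorts/input must be given", call. = FALSE)
  }
  structure(
    list(experiment = experiment, cohorts = cohorts, input = input,
         inventories = inventories, backend = backend,
         enumeration_n = enumeration_n, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Validate a long-format response CSV
#'
#' Checks column presence, the condition-label vocabulary, response ranges
#' for the paradigm and per-subject trial counts against the experiment's
#' design; returns the records or stops with the full list of violations.
#'
#' @param path CSV path.
#' @param experiment `"exp1"` or `"exp2"` (sets the expected design).
#' @return Validated records data frame.
#' @export
validate_input <- function(path, experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  paradigm <- if (experiment == "exp1") "binary" else "ternary"
  comp <- if (experiment == "exp1") exp1_composition() else
    exp2_composition()
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  violations <- character(0)
  need <- c("subject_id", "paradigm", "trial_index", "condition",
            "response")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    violations <- c(violations,
                    paste("missing columns:", paste(miss, collapse = ", ")))
  } else {
    bad_cond <- setdiff(unique(df$condition), names(comp))
    if (length(bad_cond) > 0L) {
      violations <- c(violations,
                      paste("unknown condition label(s):",
                            paste(bad_cond, collapse = ", ")))
    }
    opts <- if (paradigm == "binary") c(0, 1) else c(-1, 0, 1)
    bad_resp <- setdiff(unique(df$response), opts)
    if (length(bad_resp) > 0L) {
      violations <- c(violations,
                      paste0("response value(s) outside the ", paradigm,
                             " range: ", paste(bad_resp, collapse = ", ")))
    }
    tab <- table(df$subject_id)
    wrong_n <- names(tab)[tab != sum(comp)]
    if (length(wrong_n) > 0L) {
      violations <- c(violations,
                      paste0("subjects with trial count != ", sum(comp),
                             ": ", paste(wrong_n, collapse = ", ")))
    }
  }
  if (length(violations) > 0L) {
    stop("invalid input ", path, ":\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  if (!"age_group" %in% names(df)) df$age_group <- "unknown"
  df
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, applies the inclusion criterion,
#' runs the descriptive categorization and the chi-square comparison of
#' age-group distributions, tabulates the random-responder enumeration,
#' fits the latent-group mixture (comparing inventories when several are
#' configured) and writes every table as CSV with a JSON manifest.
#' Deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all result objects; side effect: CSV/JSON
#'   files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paradigm <- if (config$experiment == "exp1") "binary" else "ternary"

  if (!is.null(config$input)) {
    records <- validate_input(config$input, config$experiment)
  } else {
    records <- do.call(rbind, lapply(names(config$cohorts), function(nm) {
      rec <- simulate_cohort(config$cohorts[[nm]])
      rec$subject_id <- paste0(nm, "_", rec$subject_id)
      rec
    }))
  }
  write_responses(records, file.path(out, "responses.csv"))

  kept <- apply_inclusion(records)
  excluded <- setdiff(unique(records$subject_id), kept)
  summary_df <- summarize_subjects(records)
  utils::write.csv(summary_df, file.path(out, "subject_summary.csv"),
                   row.names = FALSE)

  kept_summary <- summary_df[summary_df$included, ]
  counts_by_age <- lapply(split(kept_summary, kept_summary$age_group),
                          group_count_table, included_only = TRUE)
  for (nm in names(counts_by_age)) {
    utils::write.csv(counts_by_age[[nm]],
                     file.path(out, paste0("group_counts_", nm, ".csv")))
  }

  chi <- NULL
  if (length(counts_by_age) == 2L) {
    cats <- c("homogeneous", "existential", "universal")
    tab <- t(vapply(counts_by_age, function(m) {
      rowSums(m)[cats]
    }, numeric(length(cats))))
    colnames(tab) <- cats
    keep_cols <- colSums(tab) > 0
    chi <- chi_square_2xk(tab[, keep_cols, drop = FALSE])
    utils::write.csv(
      data.frame(statistic = chi$statistic, df = chi$df, n = chi$n),
      file.path(out, "chi_square.csv"), row.names = FALSE)
  }

  enum <- enumeration_table(config$enumeration_n)
  utils::write.csv(enum, file.path(out, "enumeration.csv"),
                   row.names = FALSE)

  model_records <- records[records$subject_id %in% kept, , drop = FALSE]
  if (is.null(config$inventories)) {
    spec <- model_spec(paradigm, backend = config$backend,
                       seed = derive_seed(config$seed, 11L))
    fit <- fit_mixture(model_records, spec)
    fits <- list(default = fit)
    comparison <- NULL
  } else {
    specs <- lapply(config$inventories, function(gr) {
      model_spec(paradigm, groups = gr, backend = config$backend,
                 seed = derive_seed(config$seed, 11L))
    })
    comparison <- compare_inventories(model_records, specs)
    fits <- attr(comparison, "fits")
    fit <- fits[[which.max(comparison$elpd)]]
    utils::write.csv(comparison, file.path(out, "inventory_comparison.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(predict(fit, type = "group"),
                   file.path(out, "fit_group_probabilities.csv"),
                   row.names = FALSE)
  utils::write.csv(assignment_counts(fit),
                   file.path(out, "assignment_counts.csv"))
  utils::write.csv(
    summary_df[, c("subject_id", "age_group", "mean_the_gap_pos",
                   "mean_some_all_pos")],
    file.path(out, "subject_means.csv"), row.names = FALSE)

  manifest <- list(
    experiment = config$experiment,
    paradigm = paradigm,
    seed = config$seed,
    n_subjects = length(unique(records$subject_id)),
    n_included = length(kept),
    excluded_subjects = excluded,
    backend = config$backend,
    files = list.files(out),
    inventories = config$inventories
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(records = records, kept = kept, summary = summary_df,
                 group_counts = counts_by_age, chi_square = chi,
                 enumeration = enum, fit = fit, fits = fits,
                 comparison = comparison, out_dir = out))
}
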