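#' Posterior group assignment
#'
#' Assigns each subject to the group with the highest posterior
#' probability, breaking exact ties deterministically toward the
#' lowest-index group (and flagging them).
#'
#' @param fit A [fit_mixture()] result.
#' @return Data frame with columns `subject_id`, `group`, `probability`,
#'   `tie`.
#' @export
assign_groups <- function(fit) {
  stopifnot(inherits(fit, "homog_fit"))
  p <- fit$p_group
  idx <- apply(p, 1L, which.max)
  mx <- p[cbind(seq_len(nrow(p)), idx)]
  tie <- apply(p, 1L, function(row) sum(row == max(row)) > 1L)
  data.frame(
    subject_id = fit$subjects,
    group = fit$groups[idx],
    probability = unname(mx),
    tie = unname(tie),
    stringsAsFactors = FALSE
  )
}

#' Count table of posterior group assignments
#'
#' Tabulates [assign_groups()] as readings x implicature flag, the shape in
#' which latent-class headcounts are usually reported.
#'
#' @param fit A [fit_mixture()] result.
#' @return Integer matrix, rows readings, columns `-si` / `+si`.
#' @export
assignment_counts <- function(fit) {
  asg <- assign_groups(fit)
  parsed <- lapply(asg$group, parse_group)
  readings <- unique(vapply(fit$groups, function(g) parse_group(g)$reading,
                            character(1L)))
  tab <- matrix(0L, length(readings), 2L,
                dimnames = list(readings, c("-si", "+si")))
  for (p in parsed) {
    col <- if (p$si) "+si" else "-si"
    tab[p$reading, col] <- tab[p$reading, col] + 1L
  }
  tab
}

#' Leave-one-out expected log pointwise predictive density
#'
#' Estimates the LOO elpd from the stored pointwise log-likelihood draws by
#' truncated importance sampling: per observation the importance ratios
#' `1/p(y_i | draw)` are truncated at `mean(ratio) * sqrt(S)` to tame the
#' heavy right tail, and the LOO predictive density is the weighted
#' average of the pointwise densities under those ratios. The fraction of
#' observations whose raw ratios hit the truncation bound is reported as a
#' reliability diagnostic; [loo_exact()] is the slow exact alternative
#' (refit per left-out observation) for small problems.
#'
#' @param fit A [fit_mixture()] result.
#' @return List with `elpd`, `se` (standard error over observations),
#'   `pointwise` (per-observation elpd contributions) and
#'   `prop_truncated`.
#' @export
loo_elpd <- function(fit) {
  stopifnot(inherits(fit, "homog_fit"))
  ll <- fit$pointwise_ll
  S <- nrow(ll)
  # importance ratios to the leave-one-out posterior
  lr <- -ll
  lr_bar <- apply(lr, 2L, logsumexp) - log(S)
  bound <- lr_bar + 0.5 * log(S)
  truncated <- sweep(lr, 2L, bound, `>`)
  lw <- pmin(lr, rep(bound, each = S))
  # elpd_i = log( sum_d w_d p_d / sum_d w_d ), all in log space
  num <- apply(lw + ll, 2L, logsumexp)
  den <- apply(lw, 2L, logsumexp)
  pointwise <- num - den
  n <- length(pointwise)
  list(
    elpd = sum(pointwise),
    se = sqrt(n) * stats::sd(pointwise),
    pointwise = pointwise,
    prop_truncated = mean(colSums(truncated) > 0)
  )
}

# posterior predictive probability of a single (subject, condition,
# response) under a grid-backend fit; new subjects fall back to pi
predictive_prob <- function(fit, subject_id, condition, response) {
  spec <- fit$spec
  tmpl <- template_matrix(spec)
  grid <- spec$priors$grid
  opts <- fit$opts
  c_idx <- match(condition, spec$conditions)
  o_idx <- match(as.character(response), as.character(opts))
  s_idx <- match(subject_id, fit$subjects)
  S <- length(fit$subjects)
  w <- fit$grid_weights
  logpi <- log(fit$pi)
  total <- 0
  for (d in which(w > 1e-12)) {
    if (is.na(s_idx)) {
      pg <- exp(logpi - logsumexp(logpi))
    } else {
      M <- matrix(fit$L[, , d], nrow = S)[s_idx, ] + logpi
      pg <- exp(M - logsumexp(M))
    }
    logp <- grid_logprobs(tmpl, grid[d, , drop = FALSE], spec$paradigm,
                          opts)
    p_obs <- sum(pg * exp(logp[c_idx, , o_idx]))
    total <- total + w[d] * p_obs
  }
  total
}

#' Exact leave-one-out cross-validation by refitting
#'
#' Refits the grid-backend model once per left-out observation and scores
#' the observation under the refit posterior predictive. Exact but
#' quadratic in the data size; intended as the oracle against which the
#' importance-sampling estimate in [loo_elpd()] is validated on small
#' cohorts.
#'
#' @param records Long-format response records.
#' @param spec A [model_spec()] with `backend = "grid"`.
#' @return List with `elpd`, `se` and `pointwise`, as in [loo_elpd()].
#' @export
loo_exact <- function(records, spec) {
  records <- records[records$condition %in% spec$conditions, , drop = FALSE]
  n <- nrow(records)
  pointwise <- numeric(n)
  for (i in seq_len(n)) {
    f <- fit_mixture(records[-i, , drop = FALSE], spec)
    pointwise[i] <- log(predictive_prob(
      f, records$subject_id[i], records$condition[i], records$response[i]
    ))
  }
  list(elpd = sum(pointwise), se = sqrt(n) * stats::sd(pointwise),
       pointwise = pointwise)
}

#' Compare group inventories by LOO elpd
#'
#' Fits the mixture under each candidate inventory (all sharing the same
#' records and conditions), estimates each model's LOO elpd, and reports
#' pairwise differences to the best model with paired standard errors
#' computed from the pointwise elpd contributions.
#'
#' @param records Long-format response records.
#' @param specs Named list of [model_spec()] objects sharing `paradigm` and
#'   `conditions`.
#' @return Data frame with one row per inventory: `inventory`, `elpd`,
#'   `se`, `delpd` (difference to the best model), `delpd_se` (paired).
#'   Fits and loo objects are attached as attributes `fits` and `loos`.
#' @export
compare_inventories <- function(records, specs) {
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    names(specs) <- paste0("model", seq_along(specs))
  }
  cond0 <- specs[[1L]]$conditions
  par0 <- specs[[1L]]$paradigm
  for (sp in specs) {
    if (!identical(sort(sp$conditions), sort(cond0)) ||
        !identical(sp$paradigm, par0)) {
      stop("all specs must share paradigm and conditions_used",
           call. = FALSE)
    }
  }
  fits <- lapply(specs, fit_mixture, records = records)
  loos <- lapply(fits, loo_elpd)
  elpd <- vapply(loos, `[[`, numeric(1L), "elpd")
  se <- vapply(loos, `[[`, numeric(1L), "se")
  best <- which.max(elpd)
  delpd <- elpd - elpd[best]
  delpd_se <- vapply(seq_along(loos), function(i) {
    if (i == best) return(0)
    d <- loos[[i]]$pointwise - loos[[best]]$pointwise
    sqrt(length(d)) * stats::sd(d)
  }, numeric(1L))
  out <- data.frame(
    inventory = names(specs), elpd = elpd, se = se,
    delpd = delpd, delpd_se = delpd_se,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "fits") <- fits
  attr(out, "loos") <- loos
  out
}

#' Ternary-analysis model inventories
#'
#' Named presets for the three ternary (Experiment 2 design) analyses.
#' Analysis 1 restricts the data to the definite-description conditions
#' plus the implicature target `some-all-pos`, assumes implicature
#' computers have adult homogeneity (the only `+si` group is `hom/+si`),
#' and explores all non-empty combinations of `hom/-si`, `ws/-si` and
#' `sa/-si` alongside the always-present `exi/-si` and `hom/+si`.
#' Analysis 2 additionally allows `sa/+si` and `ws/+si` in every model.
#' Analysis 3 adds the `all-gap-pos` condition (needed to separate the
#' partial-truth strategy from homogeneity) and pairs each Analysis-1
#' model with its counterpart that also allows `pt/-si`.
#'
#' @param analysis 1, 2 or 3.
#' @param ... Passed to [model_spec()] (e.g. `backend`, `seed`).
#' @return Named list of [model_spec()] objects. For analysis 3 the list
#'   interleaves each base model with its `+pt` counterpart.
#' @export
exp2_analysis_specs <- function(analysis = 1L, ...) {
  the_conds <- grep("^the-", design_conditions("ternary"), value = TRUE)
  conds1 <- c(the_conds, "some-all-pos")
  optional <- c("hom/-si", "ws/-si", "sa/-si")
  subsets <- unlist(lapply(seq_along(optional), function(k)
    utils::combn(optional, k, simplify = FALSE)), recursive = FALSE)
  subset_name <- function(ss) paste(sub("/-si", "", ss), collapse = "+")
  specs <- list()
  for (ss in subsets) {
    base_groups <- c("exi/-si", "hom/+si", ss)
    nm <- subset_name(ss)
    if (analysis == 1L) {
      specs[[nm]] <- model_spec("ternary", groups = base_groups,
                                conditions = conds1, ...)
    } else if (analysis == 2L) {
      specs[[nm]] <- model_spec("ternary",
                                groups = c(base_groups, "sa/+si", "ws/+si"),
                                conditions = conds1, ...)
    } else {
      conds3 <- c(conds1, "all-gap-pos")
      specs[[nm]] <- model_spec("ternary", groups = base_groups,
                                conditions = conds3, ...)
      specs[[paste0(nm, "+pt")]] <- model_spec(
        "ternary", groups = c(base_groups, "pt/-si"),
        conditions = conds3, ...)
    }
  }
  specs
}
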