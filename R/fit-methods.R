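#' @export
print.homog_fit <- function(x, ...) {
  cat("Latent-group mixture fit (", x$spec$paradigm, " paradigm, ",
      x$spec$backend, " backend)\n", sep = "")
  cat("  subjects: ", length(x$subjects),
      ", observations: ", nrow(x$obs),
      ", conditions: ", length(x$spec$conditions), "\n", sep = "")
  cat("  groups: ", paste(x$groups, collapse = ", "), "\n", sep = "")
  cat("  mixture weights:\n")
  print(round(x$pi, 3))
  invisible(x)
}

#' @export
summary.homog_fit <- function(object, ...) {
  asg <- assign_groups(object)
  out <- list(
    paradigm = object$spec$paradigm,
    backend = object$spec$backend,
    n_subjects = length(object$subjects),
    n_obs = nrow(object$obs),
    pi = object$pi,
    coef = coef(object),
    counts = assignment_counts(object),
    min_max_prob = min(asg$probability),
    loo = loo_elpd(object),
    diagnostics = object$diagnostics
  )
  class(out) <- "summary.homog_fit"
  out
}

#' @export
print.summary.homog_fit <- function(x, ...) {
  cat("Latent-group mixture model (", x$paradigm, ", ", x$backend,
      " backend)\n", sep = "")
  cat("Subjects:", x$n_subjects, " Observations:", x$n_obs, "\n\n")
  cat("Posterior means of observation parameters:\n")
  print(round(x$coef, 3))
  cat("\nMixture weights:\n")
  print(round(x$pi, 3))
  cat("\nPosterior group assignments (argmax):\n")
  print(x$counts)
  cat("\nSmallest maximal assignment probability:",
      round(x$min_max_prob, 3), "\n")
  cat("LOO elpd:", round(x$loo$elpd, 2), " (se ", round(x$loo$se, 2),
      ")\n", sep = "")
  invisible(x)
}

#' @export
coef.homog_fit <- function(object, ...) {
  grid <- object$spec$priors$grid
  w <- object$grid_weights
  theta <- vapply(names(grid), function(p) sum(w * grid[[p]]), numeric(1L))
  c(theta, object$pi)
}

#' Model-implied response probabilities or group probabilities
#'
#' `type = "group"` returns the per-subject posterior group probabilities.
#' `type = "response"` returns, per subject and condition, the posterior
#' predictive probability of each response option (averaging the
#' observation model over the posterior draws of the parameters and the
#' subject's group).
#'
#' @param object A [fit_mixture()] result.
#' @param type `"group"` or `"response"`.
#' @param ... Unused.
#' @return A data frame.
#' @export
predict.homog_fit <- function(object, type = c("group", "response"), ...) {
  type <- match.arg(type)
  if (type == "group") {
    out <- as.data.frame(object$p_group)
    out <- cbind(subject_id = object$subjects, out)
    rownames(out) <- NULL
    return(out)
  }
  spec <- object$spec
  tmpl <- template_matrix(spec)
  grid <- spec$priors$grid
  opts <- object$opts
  draws <- object$draws
  S <- length(object$subjects)
  n_draws <- length(draws$d)
  acc <- array(0, c(S, length(spec$conditions), length(opts)))
  used <- sort(unique(draws$d))
  logp_by_d <- lapply(used, function(d)
    grid_logprobs(tmpl, grid[d, , drop = FALSE], spec$paradigm, opts))
  names(logp_by_d) <- as.character(used)
  for (j in seq_len(n_draws)) {
    logp <- logp_by_d[[as.character(draws$d[j])]]
    for (s in seq_len(S)) {
      acc[s, , ] <- acc[s, , ] + exp(logp[, draws$z[j, s], ]) / n_draws
    }
  }
  out <- expand.grid(subject_id = object$subjects,
                     condition = spec$conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (o in seq_along(opts)) {
    out[[paste0("p_", opts[o])]] <-
      as.vector(acc[, , o][cbind(match(out$subject_id, object$subjects),
                                 match(out$condition, spec$conditions))])
  }
  out
}

#' Posterior-mean response residuals
#'
#' Observed response minus the posterior predictive mean response for each
#' observation the model was fit to.
#'
#' @param object A [fit_mixture()] result.
#' @param ... Unused.
#' @return Numeric vector, one element per observation.
#' @export
residuals.homog_fit <- function(object, ...) {
  pred <- predict(object, type = "response")
  opts <- object$opts
  pcols <- paste0("p_", opts)
  ey <- as.matrix(pred[pcols]) %*% opts
  key_pred <- paste(pred$subject_id, pred$condition)
  key_obs <- paste(object$obs$subject_id, object$obs$condition)
  object$obs$response - ey[match(key_obs, key_pred)]
}

#' Simulate cohorts from the posterior predictive
#'
#' Draws `nsim` synthetic cohorts over the fitted design: for each cohort a
#' posterior draw of (parameters, per-subject groups) is selected and
#' responses are sampled from the observation model.
#'
#' @param object A [fit_mixture()] result.
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of `nsim` data frames shaped like the fitted observation
#'   table with a `response` column.
#' @export
simulate.homog_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  spec <- object$spec
  tmpl <- template_matrix(spec)
  grid <- spec$priors$grid
  opts <- object$opts
  rng <- local_rng(if (is.null(seed)) derive_seed(spec$seed, 9L) else seed)
  on.exit(rng())
  draws <- object$draws
  picks <- sample.int(length(draws$d), nsim, replace = TRUE)
  lapply(picks, function(j) {
    logp <- grid_logprobs(tmpl, grid[draws$d[j], , drop = FALSE],
                          spec$paradigm, opts)
    obs <- object$obs
    s_idx <- match(obs$subject_id, object$subjects)
    c_idx <- match(obs$condition, spec$conditions)
    g_idx <- draws$z[j, s_idx]
    obs$response <- vapply(seq_len(nrow(obs)), function(i) {
      p <- exp(logp[c_idx[i], g_idx[i], ])
      sample(opts, 1L, prob = p)
    }, numeric(1L))
    obs
  })
}

#' @export
logLik.homog_fit <- function(object, ...) {
  # posterior-mean marginal log-likelihood over the grid
  S <- dim(object$L)[1L]
  logpi <- log(object$pi)
  w <- object$grid_weights
  total <- 0
  for (d in which(w > 1e-12)) {
    M <- sweep(matrix(object$L[, , d], nrow = S), 2L, logpi, `+`)
    total <- total + w[d] * sum(row_logsumexp(M))
  }
  structure(total, df = ncol(object$spec$priors$grid) +
              length(object$pi) - 1L, class = "logLik")
}

#' Heatmap of posterior group probabilities
#'
#' @param x A [fit_mixture()] result.
#' @param ... Passed to [graphics::image()].
#' @export
plot.homog_fit <- function(x, ...) {
  p <- x$p_group
  graphics::image(seq_len(ncol(p)), seq_len(nrow(p)), t(p),
                  col = grDevices::grey.colors(64, start = 1, end = 0),
                  axes = FALSE, xlab = "group", ylab = "subject",
                  main = "posterior group probabilities", ...)
  graphics::axis(1, at = seq_len(ncol(p)), labels = x$groups, las = 2)
  graphics::axis(2, at = seq_len(nrow(p)), labels = x$subjects, las = 1,
                 cex.axis = 0.6)
  graphics::box()
  invisible(x)
}
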