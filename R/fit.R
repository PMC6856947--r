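# Latent-group finite-mixture response model. Every subject carries a
# discrete latent interpretive group; given the group, responses follow the
# group's template through a Bernoulli-logit (binary paradigm) or
# cumulative-logit (ternary paradigm) observation model with parameters
# shared across subjects. The group is marginalized out of the likelihood;
# posterior computation is either a deterministic coarse-grid posterior
# over the continuous parameters with mixture weights estimated by an EM
# fixed point ("grid"), or a Gibbs sampler over groups, weights and gridded
# continuous parameters ("mcmc").

#' Model specification for the latent-group mixture
#'
#' @param paradigm `"binary"` or `"ternary"`.
#' @param groups Group labels the model may assign (the inventory). Default:
#'   the full design inventory, except that the existential/`+si` group is
#'   excluded from ternary inventories by default (it was all but
#'   unpopulated in the binary paradigm and is dropped from the ternary
#'   analyses).
#' @param conditions Conditions entering the likelihood (default: the
#'   paradigm's full design).
#' @param backend `"grid"` (deterministic; default) or `"mcmc"` (Gibbs).
#' @param priors Prior/grid description, see [default_priors()].
#' @param n_draws Posterior draws to retain (pseudo-draws resampled from the
#'   grid posterior, or kept Gibbs iterations).
#' @param warmup Discarded initial Gibbs iterations (mcmc backend).
#' @param seed Integer seed for all sampling.
#' @param n_objects Domain size used when deriving templates.
#' @param overrides Template strategy overrides, see [strategy_overrides()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(paradigm = c("binary", "ternary"),
                       groups = NULL,
                       conditions = design_conditions(paradigm),
                       backend = c("grid", "mcmc"),
                       priors = default_priors(paradigm),
                       n_draws = 400L, warmup = 400L, seed = 1L,
                       n_objects = 4L, overrides = strategy_overrides()) {
  paradigm <- match.arg(paradigm)
  backend <- match.arg(backend)
  if (is.null(groups)) {
    groups <- setdiff(design_groups(paradigm),
                      if (paradigm == "ternary") "exi/+si" else character(0))
  }
  if (length(groups) < 1L) stop("empty group inventory", call. = FALSE)
  for (g in groups) check_group(g, paradigm)
  bad <- setdiff(conditions, design_conditions(paradigm))
  if (length(bad) > 0L) {
    stop("conditions outside the ", paradigm, " design: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(paradigm = paradigm, groups = groups, conditions = conditions,
         backend = backend, priors = priors,
         n_draws = as.integer(n_draws), warmup = as.integer(warmup),
         seed = as.integer(seed), n_objects = as.integer(n_objects),
         overrides = overrides),
    class = "model_spec"
  )
}

#' Default priors and parameter grids
#'
#' Weakly-informative zero-centred priors: the binary model has an intercept
#' `alpha ~ N(0, 3)` and a positive slope `beta ~ half-N(0, 4)` on the
#' template value (positivity makes the mixture identifiable: a higher
#' template value must raise the acceptance probability); the ternary model
#' has ordered cutpoints `c1 < 0 < c2`, each `N(0, 4)`, and the same
#' positive slope. The posterior over these continuous parameters is
#' computed on the coarse grids returned here; the grids extend far enough
#' into the saturated regime that noiseless cohorts are fit essentially
#' perfectly.
#'
#' @param paradigm `"binary"` or `"ternary"`.
#' @return List with the grid data frame (`grid`) and its log prior
#'   (`log_prior`), plus the scale hyper-parameters.
#' @export
default_priors <- function(paradigm = c("binary", "ternary")) {
  paradigm <- match.arg(paradigm)
  beta_vals <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12)
  if (paradigm == "binary") {
    grid <- expand.grid(alpha = seq(-6, 6, length.out = 13),
                        beta = beta_vals,
                        KEEP.OUT.ATTRS = FALSE)
    log_prior <- stats::dnorm(grid$alpha, 0, 3, log = TRUE) +
      stats::dnorm(grid$beta, 0, 4, log = TRUE)
  } else {
    cut_vals <- c(0.5, 1, 2, 3, 4, 6)
    grid <- expand.grid(c1 = -cut_vals, c2 = cut_vals, beta = beta_vals,
                        KEEP.OUT.ATTRS = FALSE)
    log_prior <- stats::dnorm(grid$c1, 0, 4, log = TRUE) +
      stats::dnorm(grid$c2, 0, 4, log = TRUE) +
      stats::dnorm(grid$beta, 0, 4, log = TRUE)
  }
  list(grid = grid, log_prior = log_prior,
       alpha_scale = 3, beta_scale = 4, cut_scale = 4)
}

# response-category probabilities given a template value t
response_probs <- function(t, params, paradigm) {
  if (paradigm == "binary") {
    p1 <- stats::plogis(params$alpha + params$beta * t)
    c("0" = 1 - p1, "1" = p1)
  } else {
    eta <- params$beta * t
    p_min <- stats::plogis(params$c1 - eta)
    p_lo2 <- stats::plogis(params$c2 - eta)
    c("-1" = p_min, "0" = p_lo2 - p_min, "1" = 1 - p_lo2)
  }
}

#' Log-likelihood of one observation under the mixture's observation model
#'
#' Binary: `log Bernoulli` with `P(accept) = logistic(alpha + beta * t)`,
#' `t` in `{0, 1}` the group's template value for the condition. Ternary:
#' cumulative logit with linear predictor `beta * t`, `t` in `{-1, 0, 1}`,
#' and cutpoints `c1 < c2` separating the minimal, intermediate and maximal
#' reward categories.
#'
#' @param response Observed response (0/1 or -1/0/+1).
#' @param condition Condition label.
#' @param group Group label.
#' @param params List of parameters: `alpha`, `beta` (binary) or `c1`,
#'   `c2`, `beta` (ternary).
#' @param paradigm `"binary"` or `"ternary"`.
#' @param n_objects Domain size for the template.
#' @return Log-probability of the response.
#' @export
observation_loglik <- function(response, condition, group, params,
                               paradigm = c("binary", "ternary"),
                               n_objects = 4L) {
  paradigm <- match.arg(paradigm)
  template <- derive_template(group, paradigm, n_objects)
  if (!condition %in% names(template)) {
    stop("template undefined for condition ", condition, call. = FALSE)
  }
  t <- template[[condition]]
  p <- response_probs(t, params, paradigm)
  key <- as.character(response)
  if (!key %in% names(p)) {
    stop("response ", response, " outside the ", paradigm,
         " response set", call. = FALSE)
  }
  log(p[[key]])
}

# counts array N[s, c, o] and the flat observation table
build_counts <- function(records, spec) {
  records <- records[records$condition %in% spec$conditions, , drop = FALSE]
  if (nrow(records) == 0L) stop("no observations in conditions_used",
                                call. = FALSE)
  missing <- setdiff(spec$conditions, unique(records$condition))
  if (length(missing) > 0L) {
    stop("conditions never observed: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  opts <- if (spec$paradigm == "binary") c(0, 1) else c(-1, 0, 1)
  bad <- setdiff(unique(records$response), opts)
  if (length(bad) > 0L) {
    stop("responses outside the ", spec$paradigm, " response set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  subjects <- unique(records$subject_id)
  counts <- table(
    factor(records$subject_id, levels = subjects),
    factor(records$condition, levels = spec$conditions),
    factor(records$response, levels = opts)
  )
  list(records = records, subjects = subjects, opts = opts, counts = counts)
}

# template matrix T[c, g] over conditions_used
template_matrix <- function(spec) {
  vapply(spec$groups, function(g) {
    derive_template(g, spec$paradigm, spec$n_objects,
                    spec$overrides)[spec$conditions]
  }, numeric(length(spec$conditions)))
}

# log-probability lookup logP[c, g, o] for one grid point
grid_logprobs <- function(tmpl, grid_row, paradigm, opts) {
  tv <- sort(unique(as.vector(tmpl)))
  pm <- vapply(tv, response_probs, numeric(length(opts)),
               params = as.list(grid_row), paradigm = paradigm)
  # pm: options x template values
  logp <- array(NA_real_, c(nrow(tmpl), ncol(tmpl), length(opts)))
  for (o in seq_along(opts)) {
    logp[, , o] <- log(pm[o, match(tmpl, tv)])
  }
  logp
}

# marginal per-subject x group log-likelihood array L[s, g, d]
loglik_array <- function(counts_obj, spec) {
  tmpl <- template_matrix(spec)
  grid <- spec$priors$grid
  S <- length(counts_obj$subjects)
  G <- length(spec$groups)
  D <- nrow(grid)
  C <- length(spec$conditions)
  O <- length(counts_obj$opts)
  # N as S x (C*O)
  Nmat <- matrix(as.vector(counts_obj$counts), nrow = S)
  L <- array(NA_real_, c(S, G, D),
             dimnames = list(counts_obj$subjects, spec$groups, NULL))
  for (d in seq_len(D)) {
    logp <- grid_logprobs(tmpl, grid[d, , drop = FALSE], spec$paradigm,
                          counts_obj$opts)
    # reshape logp to (C*O) x G
    lpm <- matrix(aperm(logp, c(1, 3, 2)), nrow = C * O)
    L[, , d] <- Nmat %*% lpm
  }
  L
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Fit the latent-group mixture model
#'
#' Marginalizes the discrete per-subject group out of the likelihood
#' (`p(y_s | theta, pi) = sum_g pi_g prod_i p(y_si | g, theta)`), computes
#' the posterior over the continuous observation parameters and the mixture
#' weights, and returns per-subject posterior group probabilities together
#' with per-observation pointwise log-likelihood draws for leave-one-out
#' comparison. Apply the inclusion criterion before fitting if the analysis
#' calls for it.
#'
#' @param records Long-format response records.
#' @param spec A [model_spec()].
#' @return An object of class `homog_fit` with components including
#'   `p_group` (subjects x groups posterior probabilities), `pi` (posterior
#'   mixture-weight estimate), `grid_weights` (grid backend), `draws`
#'   (posterior draws of grid index and group labels), `pointwise_ll`
#'   (draws x observations log-likelihood matrix) and `obs` (the
#'   observation table the model was fit to).
#' @export
fit_mixture <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  co <- build_counts(records, spec)
  L <- loglik_array(co, spec)
  S <- dim(L)[1L]; G <- dim(L)[2L]; D <- dim(L)[3L]
  lp <- spec$priors$log_prior

  if (spec$backend == "grid") {
    post <- grid_posterior(L, lp)
    diagn <- list(backend = "grid", em_iters = post$iters,
                  em_converged = post$converged)
    if (!post$converged) {
      warning("EM fixed point for the mixture weights did not converge",
              call. = FALSE)
    }
  } else {
    post <- gibbs_posterior(L, lp, n_draws = spec$n_draws,
                            warmup = spec$warmup,
                            seed = derive_seed(spec$seed, 7L))
    diagn <- post$diagnostics
    if (is.finite(diagn$rhat_logpost) && diagn$rhat_logpost > 1.1) {
      warning("split R-hat of the log-posterior trace is ",
              round(diagn$rhat_logpost, 3),
              "; the Gibbs chain may not have converged", call. = FALSE)
    }
  }

  draws <- make_draws(post, L, spec, seed = derive_seed(spec$seed, 8L))
  pll <- pointwise_ll(draws, co, spec)

  structure(
    list(spec = spec, subjects = co$subjects, groups = spec$groups,
         opts = co$opts, counts = co$counts, L = L,
         p_group = post$p_group, pi = post$pi,
         grid_weights = post$grid_weights,
         draws = draws, pointwise_ll = pll$ll, obs = pll$obs,
         diagnostics = diagn),
    class = "homog_fit"
  )
}

# deterministic grid posterior; pi by EM fixed point (flat Dirichlet prior)
grid_posterior <- function(L, lp, max_iter = 500L, tol = 1e-9) {
  S <- dim(L)[1L]; G <- dim(L)[2L]; D <- dim(L)[3L]
  pi <- rep(1 / G, G)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    # A[s, d] = log sum_g pi_g exp(L[s, g, d])
    A <- matrix(NA_real_, S, D)
    R <- array(NA_real_, c(S, G, D))
    logpi <- log(pi)
    for (d in seq_len(D)) {
      M <- sweep(matrix(L[, , d], nrow = S), 2L, logpi, `+`)
      a <- row_logsumexp(M)
      A[, d] <- a
      R[, , d] <- exp(M - a)
    }
    lw <- lp + colSums(A)
    w <- exp(lw - logsumexp(lw))
    r <- matrix(0, S, G)
    for (d in seq_len(D)) r <- r + w[d] * matrix(R[, , d], nrow = S)
    pi_new <- colSums(r) / S
    pi_new <- pmax(pi_new, 1e-12)
    pi_new <- pi_new / sum(pi_new)
    if (max(abs(pi_new - pi)) < tol) {
      pi <- pi_new
      converged <- TRUE
      break
    }
    pi <- pi_new
  }
  # final responsibilities at the converged weights
  logpi <- log(pi)
  A <- matrix(NA_real_, S, D)
  R <- array(NA_real_, c(S, G, D))
  for (d in seq_len(D)) {
    M <- matrix(L[, , d], nrow = S)
    M <- sweep(M, 2L, logpi, `+`)
    a <- row_logsumexp(M)
    A[, d] <- a
    R[, , d] <- exp(M - a)
  }
  lw <- lp + colSums(A)
  w <- exp(lw - logsumexp(lw))
  p_group <- matrix(0, S, G, dimnames = dimnames(L)[1:2])
  for (d in seq_len(D)) {
    p_group <- p_group + w[d] * matrix(R[, , d], nrow = S)
  }
  list(pi = stats::setNames(pi, dimnames(L)[[2L]]), grid_weights = w,
       p_group = p_group, iters = iters, converged = converged,
       cond_group = R)
}

# Gibbs sampler over (z, pi, grid index)
gibbs_posterior <- function(L, lp, n_draws, warmup, seed) {
  S <- dim(L)[1L]; G <- dim(L)[2L]; D <- dim(L)[3L]
  rng <- local_rng(seed)
  on.exit(rng())
  pi <- rep(1 / G, G)
  # initialize d at the prior-weighted mode under uniform pi
  init_score <- lp + vapply(seq_len(D), function(d)
    sum(row_logsumexp(matrix(L[, , d], nrow = S) + log(1 / G))),
    numeric(1L))
  d_cur <- which.max(init_score)
  z <- integer(S)
  keep_d <- integer(n_draws)
  keep_z <- matrix(NA_integer_, n_draws, S)
  keep_pi <- matrix(NA_real_, n_draws, G)
  p_group <- matrix(0, S, G, dimnames = dimnames(L)[1:2])
  logpost_trace <- numeric(n_draws)
  total <- warmup + n_draws
  for (it in seq_len(total)) {
    # z | pi, d
    M <- sweep(matrix(L[, , d_cur], nrow = S), 2L, log(pi), `+`)
    Pz <- exp(M - row_logsumexp(M))
    z <- vapply(seq_len(S), function(s)
      sample.int(G, 1L, prob = Pz[s, ]), integer(1L))
    # pi | z  (flat Dirichlet prior)
    cnt <- tabulate(z, nbins = G)
    gam <- stats::rgamma(G, shape = cnt + 1, rate = 1)
    pi <- gam / sum(gam)
    # d | z
    ld <- lp + vapply(seq_len(D), function(d)
      sum(L[cbind(seq_len(S), z, d)]), numeric(1L))
    d_cur <- sample.int(D, 1L, prob = exp(ld - logsumexp(ld)))
    if (it > warmup) {
      j <- it - warmup
      keep_d[j] <- d_cur
      keep_z[j, ] <- z
      keep_pi[j, ] <- pi
      p_group <- p_group + Pz / n_draws
      logpost_trace[j] <- ld[d_cur] + sum(log(pi) * cnt)
    }
  }
  rhat <- split_rhat(logpost_trace)
  list(pi = stats::setNames(colMeans(keep_pi), dimnames(L)[[2L]]),
       grid_weights = tabulate(keep_d, nbins = D) / n_draws,
       p_group = p_group,
       keep = list(d = keep_d, z = keep_z, pi = keep_pi),
       diagnostics = list(backend = "mcmc", rhat_logpost = rhat,
                          n_draws = n_draws, warmup = warmup))
}

split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 2L) return(NA_real_)
  chains <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  w <- mean(apply(chains, 2L, stats::var))
  b <- n * stats::var(colMeans(chains))
  if (w == 0) return(1)
  sqrt((w * (n - 1) / n + b / n) / w)
}

# posterior draws of (grid index, group assignment) for pointwise loglik
make_draws <- function(post, L, spec, seed) {
  S <- dim(L)[1L]; G <- dim(L)[2L]; D <- dim(L)[3L]
  n_draws <- spec$n_draws
  rng <- local_rng(seed)
  on.exit(rng())
  if (!is.null(post$keep)) {          # mcmc: reuse kept iterations
    d_idx <- post$keep$d
    z <- post$keep$z
  } else {                            # grid: resample grid points, then z|d
    d_idx <- sample.int(D, n_draws, replace = TRUE,
                        prob = post$grid_weights)
    logpi <- log(post$pi)
    z <- matrix(NA_integer_, n_draws, S)
    for (j in seq_len(n_draws)) {
      M <- sweep(matrix(L[, , d_idx[j]], nrow = S), 2L, logpi, `+`)
      Pz <- exp(M - row_logsumexp(M))
      z[j, ] <- vapply(seq_len(S), function(s)
        sample.int(G, 1L, prob = Pz[s, ]), integer(1L))
    }
  }
  list(d = d_idx, z = z)
}

# pointwise log-likelihood matrix (draws x observations)
pointwise_ll <- function(draws, counts_obj, spec) {
  rec <- counts_obj$records
  obs <- data.frame(
    subject_id = rec$subject_id,
    condition = rec$condition,
    response = rec$response,
    stringsAsFactors = FALSE
  )
  s_idx <- match(obs$subject_id, counts_obj$subjects)
  c_idx <- match(obs$condition, spec$conditions)
  o_idx <- match(as.character(obs$response), as.character(counts_obj$opts))
  tmpl <- template_matrix(spec)
  grid <- spec$priors$grid
  used <- sort(unique(draws$d))
  logp_by_d <- lapply(used, function(d) {
    grid_logprobs(tmpl, grid[d, , drop = FALSE], spec$paradigm,
                  counts_obj$opts)
  })
  names(logp_by_d) <- as.character(used)
  n_draws <- length(draws$d)
  ll <- matrix(NA_real_, n_draws, nrow(obs))
  for (j in seq_len(n_draws)) {
    logp <- logp_by_d[[as.character(draws$d[j])]]
    g_of_obs <- draws$z[j, s_idx]
    ll[j, ] <- logp[cbind(c_idx, g_of_obs, o_idx)]
  }
  list(ll = ll, obs = obs)
}

#' Marginalized mixture log-likelihood at fixed parameters
#'
#' The mixture likelihood with the per-subject group summed out:
#' `sum_s log sum_g pi_g prod_i p(y_si | g, params)`. Exposed mainly so the
#' marginalization can be checked against brute-force enumeration over
#' group assignments on small cohorts.
#'
#' @param records Long-format response records.
#' @param groups Group inventory.
#' @param params Observation-model parameters (see [observation_loglik()]).
#' @param weights Mixture weights over `groups` (summing to 1).
#' @param paradigm `"binary"` or `"ternary"`.
#' @param conditions Conditions entering the likelihood.
#' @param n_objects Domain size.
#' @return Total log-likelihood (scalar).
#' @export
mixture_loglik <- function(records, groups, params, weights,
                           paradigm = c("binary", "ternary"),
                           conditions = design_conditions(paradigm),
                           n_objects = 4L) {
  paradigm <- match.arg(paradigm)
  stopifnot(length(weights) == length(groups),
            abs(sum(weights) - 1) < 1e-8)
  spec <- model_spec(paradigm, groups, conditions,
                     priors = list(grid = as.data.frame(params),
                                   log_prior = 0),
                     n_objects = n_objects)
  co <- build_counts(records, spec)
  L <- loglik_array(co, spec)  # S x G x 1
  M <- sweep(matrix(L[, , 1L], nrow = dim(L)[1L]), 2L, log(weights), `+`)
  sum(row_logsumexp(M))
}
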