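test_that("observation log-likelihood implements the two link functions", {
  # saturation: huge slope makes the templated response near-certain
  ll <- observation_loglik(1, "the-gap-pos", "exi/-si",
                           list(alpha = 0, beta = 50), "binary")
  expect_gt(ll, -1e-6)
  # null slope: everything is a coin flip
  expect_equal(observation_loglik(1, "the-gap-pos", "exi/-si",
                                  list(alpha = 0, beta = 0), "binary"),
               log(0.5))
  expect_equal(observation_loglik(0, "the-gap-neg", "hom/+si",
                                  list(alpha = 0, beta = 0), "binary"),
               log(0.5))
  # ternary cumulative logit: the intermediate category is modal at t = 0
  p <- vapply(c(-1, 0, 1), function(r) {
    exp(observation_loglik(r, "the-gap-pos", "hom/-si",
                           list(c1 = -1, c2 = 1, beta = 8), "ternary"))
  }, numeric(1))
  expect_equal(sum(p), 1)
  expect_identical(which.max(p), 2L)
  # closed-form cumulative-logit probabilities
  expect_equal(p, c(plogis(-1), plogis(1) - plogis(-1), 1 - plogis(1)))
  expect_error(observation_loglik(1, "no-such-cond", "exi/-si",
                                  list(alpha = 0, beta = 1), "binary"),
               "undefined")
})

test_that("noiseless cohorts are identified essentially perfectly", {
  groups4 <- c("hom/-si", "hom/+si", "exi/-si", "exi/+si")
  set.seed(1)
  gg <- sample(groups4, 24, replace = TRUE)
  rec <- template_cohort(gg, "binary", lapse = 0, seed = 31)
  fit <- fit_mixture(rec, model_spec("binary", groups = groups4, seed = 1))
  asg <- assign_groups(fit)
  truth <- true_groups_of(rec)
  expect_identical(stats::setNames(asg$group, asg$subject_id), truth)
  expect_true(all(asg$probability > 0.99))
  # posterior probabilities sum to one per subject
  expect_equal(unname(rowSums(fit$p_group)), rep(1, 24))
})

test_that("a single-group inventory gives certain assignment", {
  rec <- template_cohort(rep("hom/-si", 5), "binary", lapse = 0.1,
                         seed = 8)
  fit <- fit_mixture(rec, model_spec("binary", groups = "hom/-si"))
  expect_equal(unname(fit$p_group[, 1]), rep(1, 5))
  expect_equal(unname(fit$pi), 1)
})

test_that("posterior group probabilities are invariant under relabeling", {
  groups <- c("hom/-si", "hom/+si", "exi/-si")
  set.seed(3)
  gg <- sample(groups, 12, replace = TRUE)
  rec <- template_cohort(gg, "binary", lapse = 0.1, seed = 17)
  f1 <- fit_mixture(rec, model_spec("binary", groups = groups, seed = 5))
  f2 <- fit_mixture(rec, model_spec("binary", groups = rev(groups),
                                    seed = 5))
  expect_equal(f1$p_group, f2$p_group[, colnames(f1$p_group)],
               tolerance = 1e-8)
  expect_equal(f1$pi, f2$pi[names(f1$pi)], tolerance = 1e-8)
})

test_that("the Gibbs backend agrees with the grid backend on recovery", {
  groups4 <- c("hom/-si", "hom/+si", "exi/-si", "exi/+si")
  set.seed(2)
  gg <- sample(groups4, 24, replace = TRUE)
  rec <- template_cohort(gg, "binary", lapse = 0, seed = 23)
  fit <- fit_mixture(rec, model_spec("binary", groups = groups4,
                                     backend = "mcmc", n_draws = 300,
                                     warmup = 200, seed = 2))
  asg <- assign_groups(fit)
  expect_identical(stats::setNames(asg$group, asg$subject_id),
                   true_groups_of(rec))
  expect_false(is.null(fit$diagnostics$rhat_logpost))
})

test_that("assignment accuracy degrades monotonically with lapse noise", {
  groups4 <- c("hom/-si", "hom/+si", "exi/-si", "exi/+si")
  acc <- vapply(c(0, 0.1, 0.2), function(eps) {
    cfg <- sim_config("binary", 24,
                      stats::setNames(rep(0.25, 4), groups4),
                      lapse_rate = eps, seed = 41)
    rec <- simulate_cohort(cfg)
    fit <- fit_mixture(rec, model_spec("binary", groups = groups4,
                                       seed = 1))
    asg <- assign_groups(fit)
    mean(asg$group == true_groups_of(rec))
  }, numeric(1))
  expect_identical(acc[1], 1)
  expect_true(all(diff(acc) <= 0.1))  # allow small-sample wiggle
})

test_that("ties in the posterior break to the lowest-index group and are flagged", {
  fake <- structure(list(
    p_group = rbind(c(0.95, 0.05), c(0.5, 0.5)),
    subjects = c("A", "B"), groups = c("g1", "g2")
  ), class = "homog_fit")
  asg <- assign_groups(fake)
  expect_identical(asg$group, c("g1", "g1"))
  expect_identical(asg$tie, c(FALSE, TRUE))
})

test_that("marginalized likelihood equals brute-force assignment enumeration", {
  groups <- c("hom/-si", "hom/+si", "exi/-si")
  weights <- c(0.5, 0.3, 0.2)
  params <- list(alpha = -1, beta = 2.5)
  for (n_sub in 1:3) {
    set.seed(n_sub)
    gg <- sample(groups, n_sub, replace = TRUE)
    rec <- template_cohort(gg, "binary", lapse = 0.15, seed = n_sub)
    ours <- mixture_loglik(rec, groups, params, weights, "binary")
    # oracle: sum over all |groups|^n assignments of prod_s pi * lik
    subjects <- unique(rec$subject_id)
    per_subject_lik <- vapply(subjects, function(s) {
      vapply(groups, function(g) {
        rs <- rec[rec$subject_id == s, ]
        exp(sum(vapply(seq_len(nrow(rs)), function(i) {
          observation_loglik(rs$response[i], rs$condition[i], g, params,
                             "binary")
        }, numeric(1))))
      }, numeric(1))
    }, numeric(length(groups)))
    asn <- expand.grid(rep(list(seq_along(groups)), length(subjects)))
    total <- sum(apply(asn, 1L, function(a) {
      prod(weights[a] * per_subject_lik[cbind(a, seq_along(subjects))])
    }))
    expect_equal(ours, log(total), tolerance = 1e-8,
                 info = paste("subjects:", n_sub))
  }
})

test_that("with a vanishing slope the model collapses to the frequency null", {
  rec <- template_cohort(rep("exi/-si", 10), "binary", lapse = 0.3,
                         seed = 55)
  phat <- mean(rec$response)
  m <- nrow(rec)
  null_ll <- sum(rec$response) * log(phat) +
    sum(1 - rec$response) * log(1 - phat)
  ours <- mixture_loglik(rec, "exi/-si",
                         list(alpha = qlogis(phat), beta = 1e-9),
                         1, "binary")
  expect_equal(ours, null_ll, tolerance = 1e-4)
})

test_that("fit methods expose coherent summaries and predictions", {
  groups <- c("hom/-si", "exi/-si")
  rec <- template_cohort(rep(groups, 4), "binary", lapse = 0.05, seed = 19)
  fit <- fit_mixture(rec, model_spec("binary", groups = groups, seed = 3))
  expect_output(print(fit), "Latent-group mixture fit")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.homog_fit")
  expect_output(print(sm), "LOO elpd")
  cf <- coef(fit)
  expect_true(all(c("alpha", "beta", groups) %in% names(cf)))
  expect_gt(cf[["beta"]], 0)
  pg <- predict(fit, type = "group")
  expect_identical(nrow(pg), 8L)
  pr <- predict(fit, type = "response")
  expect_equal(unname(rowSums(as.matrix(pr[c("p_0", "p_1")]))),
               rep(1, nrow(pr)))
  res <- residuals(fit)
  expect_identical(length(res), nrow(fit$obs))
  expect_true(all(abs(res) <= 1))
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_identical(length(sims), 2L)
  expect_true(all(sims[[1]]$response %in% c(0, 1)))
  expect_lt(as.numeric(logLik(fit)), 0)
})
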