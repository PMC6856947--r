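# Exact tail probabilities for the "random responder" null: if n children
# answered at random (fair coin over response options) on the homogeneity
# targets (scenario A) or on both homogeneity and implicature targets
# (scenario B), how likely is a group configuration at least as extreme as
# the observed one?

#' Cell probabilities for a random responder
#'
#' With three positive and three negative homogeneity targets, a random
#' binary responder's majority responses put them in each of the four
#' homogeneity patterns (homogeneous, existential, universal, wide-scope
#' existential) with probability 1/4. Under scenario B the responder is also
#' random on the four implicature targets, giving implicature categories
#' `plus_si` (at least 3 of 4 rejections) with probability 5/16, `minus_si`
#' with 5/16 and `mixed` with 6/16, independent of the homogeneity pattern.
#'
#' @param scenario `"A"` (random on homogeneity targets only) or `"B"`
#'   (random on homogeneity and implicature targets).
#' @param n_hom_trials Homogeneity trials per polarity (odd, so the majority
#'   is well defined; default 3).
#' @param n_si_trials Implicature trials (default 4, scenario B only).
#' @return Named numeric vector of cell probabilities summing to 1.
#' @export
random_cell_probs <- function(scenario = c("A", "B"), n_hom_trials = 3L,
                              n_si_trials = 4L) {
  scenario <- match.arg(scenario)
  if (n_hom_trials %% 2L == 0L) {
    stop("n_hom_trials must be odd for a well-defined majority",
         call. = FALSE)
  }
  patterns <- c("homogeneous", "existential", "universal",
                "wide_scope_existential")
  hom <- stats::setNames(rep(1 / 4, 4L), patterns)
  if (scenario == "A") return(hom)
  # P(>= ceil(3/4 * trials) rejections of fair coins); with 4 trials the
  # thresholds are >=3 rejections (plus_si) / >=3 acceptances (minus_si)
  thresh <- n_si_trials - 1L
  p_si <- sum(stats::dbinom(thresh:n_si_trials, n_si_trials, 0.5))
  si <- c(plus_si = p_si, minus_si = p_si, mixed = 1 - 2 * p_si)
  out <- as.vector(outer(hom, si))
  names(out) <- as.vector(outer(patterns, names(si), paste, sep = "."))
  out
}

#' Exact tail probability, scenario A
#'
#' Probability that, of `n_random` children answering randomly on the
#' homogeneity targets (all of them failing to compute implicatures, so all
#' land in a `-si` cell), at least six are categorized homogeneous and all
#' the rest existential, with the universal and wide-scope existential
#' patterns empty: the closed form
#' `(1/4)^n * sum_{k=6}^{n} choose(n, k)`, computed with exact integer
#' numerator and denominator (representable without rounding for the `n`
#' of interest).
#'
#' @param n_random Number of hypothetically random children (>= 6; below
#'   that the event is impossible).
#' @param min_hom Threshold for the homogeneous count (default 6).
#' @return Probability.
#' @examples
#' tail_prob_scenario_a(8)  # 37/65536
#' @export
tail_prob_scenario_a <- function(n_random, min_hom = 6L) {
  n <- as.integer(n_random)
  if (n < min_hom) {
    stop("event impossible: n_random < ", min_hom, call. = FALSE)
  }
  numerator <- sum(choose(n, min_hom:n))
  numerator / 4^n
}

#' Exact tail probability, scenario B
#'
#' Here the `n_random` children are random on both homogeneity and
#' implicature targets, so each falls in one of twelve cells (four
#' homogeneity patterns x three implicature categories). The event "at
#' least as extreme as observed" is: at least six children in the
#' homogeneous/`-si` cell (probability 5/64), none in any universal or
#' wide-scope existential cell (total probability 1/2), and at most one in
#' the existential/`+si` cell (5/64); children in the remaining allowed
#' cells (total 22/64) are unconstrained. The exact multinomial tail is
#' summed by enumerating the homogeneous/`-si` count `h` and the
#' existential/`+si` count `e`, with the remainder in closed form; terms
#' are evaluated in log space.
#'
#' @inheritParams tail_prob_scenario_a
#' @param constrain_mixed If `TRUE`, additionally requires the
#'   implicature-`mixed` cells in the allowed homogeneity rows to be empty
#'   (a stricter reading of the event; the remainder probability drops from
#'   22/64 to 10/64). Default `FALSE`.
#' @return Probability.
#' @export
tail_prob_scenario_b <- function(n_random, min_hom = 6L,
                                 constrain_mixed = FALSE) {
  n <- as.integer(n_random)
  if (n < min_hom) {
    stop("event impossible: n_random < ", min_hom, call. = FALSE)
  }
  p_hom <- 5 / 64   # homogeneous & minus_si
  p_exi <- 5 / 64   # existential & plus_si
  p_rest <- if (constrain_mixed) 10 / 64 else 22 / 64
  total <- 0
  for (h in min_hom:n) {
    for (e in 0:min(1L, n - h)) {
      r <- n - h - e
      log_term <- lgamma(n + 1) - lgamma(h + 1) - lgamma(e + 1) -
        lgamma(r + 1) + h * log(p_hom) + e * log(p_exi) +
        if (r > 0) r * log(p_rest) else 0
      total <- total + exp(log_term)
    }
  }
  total
}

#' Monte-Carlo cross-check of the enumeration
#'
#' Simulates `n_random` random responders per repetition through the actual
#' categorization path ([categorize_homogeneity()] /
#' [categorize_implicature()]) and counts how often the scenario's event
#' occurs. Because this goes through the real majority-rule categorizer, it
#' validates the categorizer and the closed-form enumeration against each
#' other.
#'
#' @param scenario `"A"` or `"B"`.
#' @param n_random Number of random responders per repetition.
#' @param reps Number of Monte-Carlo repetitions.
#' @param seed Integer seed.
#' @param min_hom Threshold for the homogeneous count (default 6).
#' @return List with `estimate`, `se` (binomial standard error) and `reps`.
#' @export
monte_carlo_tail <- function(scenario = c("A", "B"), n_random, reps,
                             seed = 1L, min_hom = 6L) {
  scenario <- match.arg(scenario)
  stopifnot(reps >= 1)
  rng <- local_rng(derive_seed(seed, 4L))
  on.exit(rng())
  n <- as.integer(n_random)
  hits <- 0L
  # batch all subjects of all reps into one records table per block
  block <- max(1L, min(reps, 5000L %/% max(n, 1L)))
  done <- 0L
  while (done < reps) {
    b <- min(block, reps - done)
    m <- b * n
    ids <- paste0("r", rep(seq_len(b), each = n), "s", rep(seq_len(n), b))
    conds <- c(rep("the-gap-pos", 3L), rep("the-gap-neg", 3L),
               rep("some-all-pos", 4L))
    rec <- data.frame(
      subject_id = rep(ids, each = length(conds)),
      paradigm = "binary",
      condition = rep(conds, m),
      response = sample(c(0, 1), m * length(conds), replace = TRUE),
      stringsAsFactors = FALSE
    )
    hom <- categorize_homogeneity(rec, "binary")
    rep_of <- rep(seq_len(b), each = n)
    if (scenario == "A") {
      ok <- tapply(hom, rep_of, function(h) {
        sum(h == "homogeneous") >= min_hom &&
          all(h %in% c("homogeneous", "existential"))
      })
    } else {
      si <- categorize_implicature(rec, "binary")
      cell_hom <- hom == "homogeneous" & si == "minus_si"
      cell_exi_si <- hom == "existential" & si == "plus_si"
      bad <- hom %in% c("universal", "wide_scope_existential")
      ok <- tapply(seq_along(hom), rep_of, function(ix) {
        sum(cell_hom[ix]) >= min_hom && !any(bad[ix]) &&
          sum(cell_exi_si[ix]) <= 1L
      })
    }
    hits <- hits + sum(ok)
    done <- done + b
  }
  est <- hits / reps
  list(estimate = est, se = sqrt(est * (1 - est) / reps), reps = reps)
}

#' Table of tail probabilities over a range of n
#'
#' @param n_values Integer vector of hypothetical random-responder counts.
#' @return Data frame with columns `n`, `scenario_a`, `scenario_b` (`NA`
#'   where the event is impossible).
#' @export
enumeration_table <- function(n_values = 6:24) {
  data.frame(
    n = n_values,
    scenario_a = vapply(n_values, function(n)
      if (n >= 6) tail_prob_scenario_a(n) else NA_real_, numeric(1L)),
    scenario_b = vapply(n_values, function(n)
      if (n >= 6) tail_prob_scenario_b(n) else NA_real_, numeric(1L))
  )
}
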