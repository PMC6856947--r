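test_that("inclusion requires six of eight definite controls correct", {
  expect_identical(apply_inclusion(binary_subject(c(0, 0, 0), c(0, 0, 0),
                                                  controls_correct = 6L)),
                   "S1")
  expect_identical(length(apply_inclusion(
    binary_subject(c(0, 0, 0), c(0, 0, 0), controls_correct = 5L))), 0L)
  expect_identical(apply_inclusion(binary_subject(c(0, 0, 0), c(0, 0, 0),
                                                  controls_correct = 8L)),
                   "S1")
  # ternary: correct = maximal for true, minimal for false
  expect_identical(apply_inclusion(ternary_subject(c(0, 0, 0), c(0, 0, 0))),
                   "S1")
  bad <- ternary_subject(c(0, 0, 0), c(0, 0, 0))
  bad$response[bad$condition == "the-all-pos"] <- 0     # 2 wrong
  bad$response[bad$condition == "the-none-pos"][1] <- 0 # 3rd wrong
  expect_identical(length(apply_inclusion(bad)), 0L)
  # malformed control inventory errors
  short <- binary_subject(c(0, 0, 0), c(0, 0, 0))
  short <- short[-which(short$condition == "the-all-pos")[1], ]
  expect_error(apply_inclusion(short), "expected 8")
})

test_that("binary majority rule recovers the four response patterns", {
  cat1 <- function(pos, neg) {
    unname(categorize_homogeneity(binary_subject(pos, neg), "binary"))
  }
  expect_identical(cat1(c(0, 0, 0), c(0, 1, 0)), "homogeneous")
  expect_identical(cat1(c(1, 1, 1), c(0, 0, 0)), "existential")
  expect_identical(cat1(c(0, 0, 1), c(1, 1, 1)), "universal")
  expect_identical(cat1(c(1, 1, 0), c(1, 1, 1)), "wide_scope_existential")
  # the four categories partition all 2^6 response patterns
  grids <- expand.grid(rep(list(0:1), 6))
  cats <- apply(grids, 1L, function(r) cat1(r[1:3], r[4:6]))
  expect_true(all(cats %in% c("homogeneous", "existential", "universal",
                              "wide_scope_existential")))
  # independent recomputation from majorities
  maj <- apply(grids, 1L, function(r) {
    acc_p <- sum(r[1:3]) >= 2
    acc_n <- sum(r[4:6]) >= 2
    if (acc_p && !acc_n) "existential" else
      if (!acc_p && acc_n) "universal" else
        if (acc_p && acc_n) "wide_scope_existential" else "homogeneous"
  })
  expect_identical(cats, maj)
})

test_that("ternary categorization distinguishes homogeneity from the strategies", {
  cat2 <- function(pos, neg) {
    unname(categorize_homogeneity(ternary_subject(pos, neg), "ternary"))
  }
  expect_identical(cat2(c(1, 1, 1), c(-1, -1, -1)), "existential")
  expect_identical(cat2(c(-1, -1, -1), c(1, 1, 1)), "universal")
  expect_identical(cat2(c(0, 0, 1), c(0, 0, 0)), "homogeneous")
  expect_identical(cat2(c(-1, -1, -1), c(0, 0, 0)), "homogeneous")
  # an all-minimal pattern (strict wide-scope universal) is not homogeneous
  expect_identical(cat2(c(-1, -1, -1), c(-1, -1, -1)), "inconsistent")
  expect_identical(cat2(c(1, 1, 1), c(1, 1, 1)), "inconsistent")
})

test_that("implicature categorization follows the majority thresholds", {
  si1 <- function(si) {
    unname(categorize_implicature(binary_subject(c(0, 0, 0), c(0, 0, 0),
                                                 si = si), "binary"))
  }
  expect_identical(si1(c(0, 0, 0, 1)), "plus_si")   # 3/4 rejections
  expect_identical(si1(c(1, 1, 1, 0)), "minus_si")  # 3/4 acceptances
  expect_identical(si1(c(1, 1, 0, 0)), "mixed")
  si2 <- function(si) {
    unname(categorize_implicature(ternary_subject(c(0, 0, 0), c(0, 0, 0),
                                                  si = si), "ternary"))
  }
  expect_identical(si2(c(1, 1, 1)), "minus_si")
  expect_identical(si2(c(0, 1, 0)), "plus_si")   # non-maximal = rejection
  expect_identical(si2(c(-1, 0, 1)), "plus_si")
})

test_that("ternary bias flags follow the control thresholds", {
  f <- function(...) flag_biases(ternary_subject(c(0, 0, 0), c(0, 0, 0), ...))
  expect_false(any(unlist(f()[, -1])))
  expect_true(f(some_gap = c(1, 0, 0))$incomplete_description)
  expect_false(f(some_gap = c(1, 1, 0))$incomplete_description)
  expect_true(f(all_gap_pos = c(-1, 0, 0))$partial_truth)
  expect_false(f(all_gap_pos = c(-1, -1, -1))$partial_truth)
  expect_true(f(all_gap_neg = c(0, 0, 1))$scope_ambiguity)
  expect_false(f(all_gap_neg = c(0, 1, 1))$scope_ambiguity)
  expect_error(flag_biases(binary_subject(c(0, 0, 0), c(0, 0, 0))),
               "ternary")
})

test_that("Pearson chi-square matches the closed form and the reference", {
  ex <- chi_square_2xk(rbind(c(16, 0, 6), c(16, 8, 0)))
  expect_equal(ex$statistic, 13.94, tolerance = 0.001)
  expect_identical(ex$df, 2L)
  expect_identical(ex$n, 46)
  expect_equal(chi_square_2xk(rbind(c(5, 3, 2), c(5, 3, 2)))$statistic, 0)
  expect_equal(chi_square_2xk(rbind(c(10, 0), c(0, 10)))$statistic, 20)
  expect_error(chi_square_2xk(rbind(c(1, 0), c(2, 0))), "zero expected")
  expect_error(chi_square_2xk(rbind(c(-1, 2), c(3, 4))), "nonnegative")
  # property: agreement with the standard implementation on random tables
  set.seed(99)
  for (i in 1:25) {
    tab <- matrix(rpois(6, 8) + 1, 2, 3)
    ours <- chi_square_2xk(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_identical(ours$df, as.integer(ref$parameter))
  }
})

test_that("group-count tables have the homogeneity-by-implicature shape", {
  set.seed(4)
  groups <- sample(c("hom/-si", "hom/+si", "exi/-si"), 15, replace = TRUE)
  rec <- template_cohort(groups, "binary", lapse = 0, seed = 4)
  tab <- group_count_table(summarize_subjects(rec))
  expect_identical(sum(tab), 15L)
  expect_identical(unname(tab["homogeneous", "minus_si"]),
                   sum(groups == "hom/-si"))
  expect_identical(unname(tab["existential", "minus_si"]),
                   sum(groups == "exi/-si"))
})
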