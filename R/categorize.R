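# truth targets of the eight definite controls
control_truth <- c("the-all-pos" = 1, "the-none-neg" = 1,
                   "the-none-pos" = 0, "the-all-neg" = 0)

subject_condition_responses <- function(records, subject, condition) {
  records$response[records$subject_id == subject &
                     records$condition == condition]
}

#' Inclusion criterion: six of eight definite controls correct
#'
#' A subject is kept iff at least six of their eight clearly true / clearly
#' false definite description controls are answered correctly (the standard
#' 75%-accuracy-on-controls criterion). In the binary paradigm "correct"
#' means matching the truth value; in the ternary paradigm a clearly true
#' control must get the maximal reward and a clearly false control the
#' minimal reward.
#'
#' @param records Long-format response records.
#' @return Character vector of kept `subject_id`s.
#' @export
apply_inclusion <- function(records) {
  paradigm <- records$paradigm[1L]
  subjects <- unique(records$subject_id)
  kept <- vapply(subjects, function(s) {
    n_correct <- 0L
    n_trials <- 0L
    for (cond in names(control_truth)) {
      resp <- subject_condition_responses(records, s, cond)
      n_trials <- n_trials + length(resp)
      target <- if (paradigm == "binary") control_truth[[cond]] else
        if (control_truth[[cond]] == 1) 1 else -1
      n_correct <- n_correct + sum(resp == target)
    }
    if (n_trials != 8L) {
      stop("subject ", s, " has ", n_trials,
           " definite control trials; expected 8", call. = FALSE)
    }
    n_correct >= 6L
  }, logical(1L))
  subjects[kept]
}

#' Majority-rule homogeneity categorization
#'
#' Categorizes each subject by their majority responses to the three
#' positive and three negative gap-context definite targets. Binary:
#' homogeneous rejects a majority of both; existential accepts the positive
#' and rejects the negative; universal rejects the positive and accepts the
#' negative; wide-scope existential (the fourth logically possible pattern)
#' accepts both. Ternary: existential gives mostly maximal rewards to the
#' positive and minimal to the negative; universal the reverse; homogeneous
#' gives mostly non-maximal rewards to both, is not classifiable as
#' existential or universal, and shows at least one intermediate reward
#' (an all-minimal pattern is left `inconsistent` rather than conflated with
#' homogeneity); anything else is `inconsistent`.
#'
#' @param records Long-format response records.
#' @param paradigm `"binary"` or `"ternary"` (default: taken from the
#'   records).
#' @return Named character vector, subject id -> category in
#'   `homogeneous`, `existential`, `universal`, `wide_scope_existential`,
#'   `inconsistent`.
#' @export
categorize_homogeneity <- function(records, paradigm = records$paradigm[1L]) {
  subjects <- unique(records$subject_id)
  opts <- if (paradigm == "binary") c(0, 1) else c(-1, 0, 1)
  counts <- function(cond) {
    r <- records[records$condition == cond, ]
    tab <- table(factor(r$subject_id, levels = subjects),
                 factor(r$response, levels = opts))
    if (any(rowSums(tab) != 3L)) {
      bad <- subjects[rowSums(tab) != 3L][1L]
      stop("subject ", bad, " is missing homogeneity target trials",
           call. = FALSE)
    }
    tab
  }
  pos <- counts("the-gap-pos")
  neg <- counts("the-gap-neg")
  if (paradigm == "binary") {
    acc_pos <- pos[, "1"] >= 2L
    acc_neg <- neg[, "1"] >= 2L
    out <- ifelse(!acc_pos & !acc_neg, "homogeneous",
           ifelse(acc_pos & !acc_neg, "existential",
           ifelse(!acc_pos & acc_neg, "universal",
                  "wide_scope_existential")))
  } else {
    max_pos <- pos[, "1"] >= 2L
    max_neg <- neg[, "1"] >= 2L
    min_pos <- pos[, "-1"] >= 2L
    min_neg <- neg[, "-1"] >= 2L
    lo_pos <- pos[, "-1"] + pos[, "0"] >= 2L
    lo_neg <- neg[, "-1"] + neg[, "0"] >= 2L
    has_int <- pos[, "0"] + neg[, "0"] > 0L
    out <- ifelse(max_pos & min_neg, "existential",
           ifelse(min_pos & max_neg, "universal",
           ifelse(lo_pos & lo_neg & has_int, "homogeneous",
                  "inconsistent")))
  }
  stats::setNames(as.vector(out), subjects)
}

#' Majority-rule scalar-implicature categorization
#'
#' Experiment 1 has four implicature targets (`some-all-pos`, binary):
#' `plus_si` rejects at least three of four, `minus_si` accepts at least
#' three of four, anything else is `mixed`. Experiment 2 has three ternary
#' targets and uses the majority rule, with "rejection" meaning any
#' non-maximal reward (a minimal or intermediate reward for a true but
#' underinformative sentence indicates the implicature).
#'
#' @inheritParams categorize_homogeneity
#' @return Named character vector, subject id -> `plus_si` / `minus_si` /
#'   `mixed`.
#' @export
categorize_implicature <- function(records, paradigm = records$paradigm[1L]) {
  subjects <- unique(records$subject_id)
  opts <- if (paradigm == "binary") c(0, 1) else c(-1, 0, 1)
  n_trials <- if (paradigm == "binary") 4L else 3L
  thresh <- if (paradigm == "binary") 3L else 2L
  r <- records[records$condition == "some-all-pos", ]
  tab <- table(factor(r$subject_id, levels = subjects),
               factor(r$response, levels = opts))
  if (any(rowSums(tab) != n_trials)) {
    bad <- subjects[rowSums(tab) != n_trials][1L]
    stop("subject ", bad, " is missing implicature trials", call. = FALSE)
  }
  n_reject <- rowSums(tab) - tab[, as.character(1)]
  n_accept <- tab[, as.character(1)]
  out <- ifelse(n_reject >= thresh, "plus_si",
         ifelse(n_accept >= thresh, "minus_si", "mixed"))
  stats::setNames(as.vector(out), subjects)
}

#' Response-bias flags (ternary paradigm)
#'
#' Flags each subject for the three biases that could mimic or mask an
#' intermediate homogeneity response: a bias against incomplete descriptions
#' (maximal reward on fewer than two of the three gap-context existential
#' controls), a bias in favour of partial truth (minimal reward on fewer
#' than two of the three gap-context positive universal controls), and a
#' scope-ambiguity effect (intermediate response on more than one of the
#' three gap-context negated universal controls). A subject with any flag
#' fails the maximally stringent inclusion criterion.
#'
#' @param records Long-format ternary response records.
#' @return Data frame with columns `subject_id`, `incomplete_description`,
#'   `partial_truth`, `scope_ambiguity` (logicals).
#' @export
flag_biases <- function(records) {
  if (records$paradigm[1L] != "ternary") {
    stop("bias flags are defined for the ternary paradigm only",
         call. = FALSE)
  }
  subjects <- unique(records$subject_id)
  one <- function(s, cond) {
    resp <- subject_condition_responses(records, s, cond)
    if (length(resp) != 3L) {
      stop("subject ", s, " is missing ", cond, " trials", call. = FALSE)
    }
    resp
  }
  data.frame(
    subject_id = subjects,
    incomplete_description = vapply(subjects, function(s)
      sum(one(s, "some-gap-pos") == 1) < 2L, logical(1L)),
    partial_truth = vapply(subjects, function(s)
      sum(one(s, "all-gap-pos") == -1) < 2L, logical(1L)),
    scope_ambiguity = vapply(subjects, function(s)
      sum(one(s, "all-gap-neg") == 0) > 1L, logical(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-subject descriptive summary
#'
#' Applies the inclusion criterion, the homogeneity and implicature
#' categorizations and (ternary) the bias flags, and records each subject's
#' mean response to the positive homogeneity and implicature targets (the
#' per-subject coordinates used to visualize clustering of subjects into
#' groups).
#'
#' @param records Long-format response records.
#' @return Data frame, one row per subject.
#' @export
summarize_subjects <- function(records) {
  paradigm <- records$paradigm[1L]
  subjects <- unique(records$subject_id)
  kept <- apply_inclusion(records)
  hom <- categorize_homogeneity(records, paradigm)
  si <- categorize_implicature(records, paradigm)
  mean_cond <- function(s, cond) {
    mean(subject_condition_responses(records, s, cond))
  }
  out <- data.frame(
    subject_id = subjects,
    age_group = records$age_group[match(subjects, records$subject_id)],
    included = subjects %in% kept,
    homogeneity_category = unname(hom[subjects]),
    si_category = unname(si[subjects]),
    mean_the_gap_pos = vapply(subjects, mean_cond, numeric(1L),
                              cond = "the-gap-pos"),
    mean_the_gap_neg = vapply(subjects, mean_cond, numeric(1L),
                              cond = "the-gap-neg"),
    mean_some_all_pos = vapply(subjects, mean_cond, numeric(1L),
                               cond = "some-all-pos"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if ("true_group" %in% names(records)) {
    out$true_group <- records$true_group[match(subjects, records$subject_id)]
  }
  if (paradigm == "ternary") {
    out <- merge(out, flag_biases(records), by = "subject_id", sort = FALSE)
  }
  out
}

#' Group-count table (homogeneity category x implicature category)
#'
#' @param summary A data frame from [summarize_subjects()] (included
#'   subjects are counted; pass a subset to change that).
#' @param included_only Count only subjects passing the inclusion criterion.
#' @return Integer matrix, rows homogeneity categories, columns
#'   `minus_si` / `plus_si` / `mixed`.
#' @export
group_count_table <- function(summary, included_only = TRUE) {
  if (included_only) summary <- summary[summary$included, ]
  rows <- c("homogeneous", "existential", "universal",
            "wide_scope_existential", "inconsistent")
  cols <- c("minus_si", "plus_si", "mixed")
  tab <- matrix(0L, length(rows), length(cols),
                dimnames = list(rows, cols))
  for (i in seq_len(nrow(summary))) {
    tab[summary$homogeneity_category[i], summary$si_category[i]] <-
      tab[summary$homogeneity_category[i], summary$si_category[i]] + 1L
  }
  tab[rowSums(tab) > 0 | rows %in% c("homogeneous", "existential",
                                     "universal"), , drop = FALSE]
}

#' Pearson chi-square for a 2 x k count table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with expectations from the
#' row/column margins and `df = (rows - 1) * (cols - 1)`; no continuity
#' correction. Used to compare the distribution of two samples (e.g. adults
#' vs children) over response categories.
#'
#' @param table Matrix of nonnegative integer counts.
#' @return List with elements `statistic`, `df`, `n`.
#' @examples
#' chi_square_2xk(rbind(adults = c(16, 0, 6), children = c(16, 8, 0)))
#' @export
chi_square_2xk <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) {
    bad <- if (any(rs == 0)) paste("row", which(rs == 0)[1L]) else
      paste("column", which(cs == 0)[1L])
    stop("zero expected cell: margin of ", bad, " is zero", call. = FALSE)
  }
  expected <- outer(rs, cs) / n
  list(statistic = sum((table - expected)^2 / expected),
       df = (nrow(table) - 1L) * (ncol(table) - 1L),
       n = n)
}
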