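# shared fixtures, built in code

# map descriptive categories back onto group labels
category_to_group <- function(hom_cat, si_cat) {
  reading <- unname(c(homogeneous = "hom", existential = "exi",
                      universal = "uni",
                      wide_scope_existential = "wse")[hom_cat])
  si <- unname(c(plus_si = "+si", minus_si = "-si")[si_cat])
  ifelse(is.na(reading) | is.na(si), NA_character_,
         paste0(reading, "/", si))
}

# a binary cohort mirroring the child composition of the original study
child_weights_binary <- c("hom/-si" = 6, "hom/+si" = 10,
                          "exi/-si" = 7, "exi/+si" = 1) / 24

# hand-build records for one subject from per-condition response vectors
records_from_responses <- function(responses, paradigm = "binary",
                                   subject_id = "S1") {
  rows <- lapply(names(responses), function(cond) {
    data.frame(subject_id = subject_id, age_group = "child",
               paradigm = paradigm, trial_index = NA_integer_,
               condition = cond, response = responses[[cond]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$trial_index <- seq_len(nrow(out))
  out
}

# binary records with all controls correct and given gap/implicature answers
binary_subject <- function(gap_pos, gap_neg, si = c(1, 1, 1, 1),
                           controls_correct = 8L, subject_id = "S1") {
  ctrl <- list("the-all-pos" = c(1, 1), "the-all-neg" = c(0, 0),
               "the-none-pos" = c(0, 0), "the-none-neg" = c(1, 1))
  # flip controls to make exactly controls_correct of them correct
  n_wrong <- 8L - controls_correct
  if (n_wrong > 0L) {
    flat <- unlist(ctrl)
    flat[seq_len(n_wrong)] <- 1 - flat[seq_len(n_wrong)]
    ctrl <- split(unname(flat), sub("[0-9]+$", "", names(flat)))
  }
  records_from_responses(
    c(list("the-gap-pos" = gap_pos, "the-gap-neg" = gap_neg,
           "some-all-pos" = si,
           "all-gap-pos" = c(0, 0, 0), "all-gap-neg" = c(1, 1, 1)),
      ctrl),
    paradigm = "binary", subject_id = subject_id
  )
}

# ternary records with all controls correct and given target answers
ternary_subject <- function(gap_pos, gap_neg, si = c(1, 1, 1),
                            some_gap = c(1, 1, 1),
                            all_gap_pos = c(-1, -1, -1),
                            all_gap_neg = c(1, 1, 1),
                            subject_id = "S1") {
  records_from_responses(
    list("the-gap-pos" = gap_pos, "the-gap-neg" = gap_neg,
         "some-all-pos" = si, "some-gap-pos" = some_gap,
         "all-gap-pos" = all_gap_pos, "all-gap-neg" = all_gap_neg,
         "the-all-pos" = c(1, 1), "the-all-neg" = c(-1, -1),
         "the-none-pos" = c(-1, -1), "the-none-neg" = c(1, 1)),
    paradigm = "ternary", subject_id = subject_id
  )
}

# noiseless-template records for a whole cohort with known groups
template_cohort <- function(groups, paradigm = "binary", lapse = 0,
                            seed = 1L) {
  cfg <- sim_config(paradigm, n_subjects = length(groups),
                    group_weights = stats::setNames(
                      rep(1 / length(unique(groups)),
                          length(unique(groups))), unique(groups)),
                    lapse_rate = lapse, seed = seed)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_along(groups)),
    age_group = "child", true_group = groups, stringsAsFactors = FALSE)
  experiment <- if (paradigm == "binary") "exp1" else "exp2"
  trials <- build_trial_list(experiment, seed = seed)
  simulate_responses(subjects, trials, cfg)
}

true_groups_of <- function(records) {
  subjects <- unique(records$subject_id)
  stats::setNames(records$true_group[match(subjects, records$subject_id)],
                  subjects)
}
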