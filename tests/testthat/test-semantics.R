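test_that("literal meanings of the determiner fragment are correct", {
  expect_identical(literal_meaning("some", 4), 1:4)
  expect_identical(literal_meaning("all", 4), 4L)
  expect_identical(literal_meaning("the", 4, "exi"), 1:4)
  expect_identical(literal_meaning("the", 4, "uni"), 4L)
  expect_error(literal_meaning("the", 4, "hom"), "reading")
  expect_error(literal_meaning("most", 4), "determiner")
})

test_that("exhaustification excludes non-entailed, consistently negatable alternatives", {
  # some + {all} -> some-but-not-all
  expect_identical(exhaustify(1:4, list(4L), 4), 1:3)
  # nothing to exclude
  expect_identical(exhaustify(1:4, list(), 4), 1:4)
  # alternative entailed by the prejacent is not excludable
  expect_identical(exhaustify(4L, list(1:4), 4), 4L)
  expect_error(exhaustify(integer(0), list(), 4), "vacuous")
})

test_that("recursive exhaustification of the THE-literal yields the universal meaning", {
  # two-level strengthening with scalar alternatives {some, all}
  expect_identical(recursive_exhaustify(1:4, list(1:4, 4L), 4), 4L)
  # fixed point
  expect_identical(recursive_exhaustify(4L, list(), 4), 4L)
  # a lone non-scalar alternative reduces to single exhaustification
  expect_identical(recursive_exhaustify(1:4, list(4L), 4),
                   exhaustify(1:4, list(4L), 4))
  # equivalence with the universal meaning at every domain size
  for (n in 2:8) {
    expect_identical(
      recursive_exhaustify(literal_meaning("the", n, "exi"),
                           list(literal_meaning("some", n),
                                literal_meaning("all", n)), n),
      literal_meaning("all", n),
      info = paste("n =", n)
    )
  }
})

test_that("trivalent evaluation matches the readings' truth conditions", {
  expect_identical(evaluate_sentence("the", "pos", "hom", 2, 4), "GAP")
  expect_identical(evaluate_sentence("the", "neg", "hom", 2, 4), "GAP")
  expect_identical(evaluate_sentence("the", "neg", "uni", 2, 4), "TRUE")
  expect_identical(evaluate_sentence("the", "neg", "hom", 0, 4), "TRUE")
  expect_identical(evaluate_sentence("the", "pos", "exi", 2, 4), "TRUE")
  expect_identical(evaluate_sentence("the", "neg", "exi", 2, 4), "FALSE")
  expect_identical(evaluate_sentence("the", "neg", "ws", 2, 4), "FALSE")
  expect_identical(evaluate_sentence("the", "neg", "ws", 0, 4), "TRUE")
  expect_identical(evaluate_sentence("the", "neg", "wse", 2, 4), "TRUE")
  expect_identical(evaluate_sentence("all", "neg", k = 2, n_objects = 4),
                   "TRUE")
  expect_identical(evaluate_sentence("some", "pos", k = 0, n_objects = 4),
                   "FALSE")
})

test_that("negation is the trivalent dual for the non-strategy readings", {
  neg3 <- function(v) switch(v, "TRUE" = "FALSE", "FALSE" = "TRUE", "GAP")
  for (reading in c("exi", "hom", "uni")) {
    for (k in 0:4) {
      expect_identical(
        evaluate_sentence("the", "neg", reading, k, 4),
        neg3(evaluate_sentence("the", "pos", reading, k, 4)),
        info = paste(reading, k)
      )
    }
  }
})

test_that("templates are total, single-valued and anchored on the controls", {
  for (paradigm in c("binary", "ternary")) {
    conds <- design_conditions(paradigm)
    rng <- if (paradigm == "binary") c(0, 1) else c(-1, 0, 1)
    for (g in design_groups(paradigm)) {
      tmpl <- derive_template(g, paradigm)
      expect_identical(names(tmpl), conds)
      expect_true(all(tmpl %in% rng), info = paste(paradigm, g))
      # clearly-true controls maximal, clearly-false controls minimal
      expect_identical(unname(tmpl["the-all-pos"]), max(rng))
      expect_identical(unname(tmpl["the-none-neg"]), max(rng))
      expect_identical(unname(tmpl["the-none-pos"]), min(rng))
      expect_identical(unname(tmpl["the-all-neg"]), min(rng))
    }
  }
  expect_error(derive_template("ws/-si", "binary"), "not admissible")
  expect_error(derive_template("wse/-si", "ternary"), "not admissible")
})

test_that("binary templates reproduce the group-by-condition predictions", {
  expect_identical(unname(derive_template("hom/-si", "binary")[
    c("the-gap-pos", "the-gap-neg")]), c(0, 0))
  expect_identical(unname(derive_template("exi/-si", "binary")[
    c("the-gap-pos", "the-gap-neg")]), c(1, 0))
  expect_identical(unname(derive_template("uni/-si", "binary")[
    c("the-gap-pos", "the-gap-neg")]), c(0, 1))
  expect_identical(unname(derive_template("wse/-si", "binary")[
    c("the-gap-pos", "the-gap-neg")]), c(1, 1))
  # implicature flag acts on lexical "some" only
  for (g in c("exi", "hom", "uni")) {
    plus <- derive_template(paste0(g, "/+si"), "binary")
    minus <- derive_template(paste0(g, "/-si"), "binary")
    expect_identical(unname(plus["some-all-pos"]), 0)
    expect_identical(unname(minus["some-all-pos"]), 1)
    expect_identical(plus[setdiff(names(plus), "some-all-pos")],
                     minus[setdiff(names(minus), "some-all-pos")])
  }
})

test_that("ternary templates implement the strategy readings", {
  sa <- derive_template("sa/-si", "ternary")
  expect_identical(unname(sa[c("the-gap-pos", "the-gap-neg")]), c(-1, 0))
  ws <- derive_template("ws/-si", "ternary")
  expect_identical(unname(ws[c("the-gap-pos", "the-gap-neg")]), c(-1, -1))
  pt <- derive_template("pt/-si", "ternary")
  expect_identical(
    unname(pt[c("the-gap-pos", "the-gap-neg", "all-gap-pos")]), c(0, 0, 0))
  hom <- derive_template("hom/-si", "ternary")
  expect_identical(unname(hom[c("the-gap-pos", "the-gap-neg",
                                "all-gap-pos")]), c(0, 0, -1))
  # implicature-relevant ternary cells: intermediate for a true sentence
  # with a false implicature, maximal otherwise
  expect_identical(unname(derive_template("hom/+si", "ternary")[
    c("some-all-pos", "some-gap-pos")]), c(0, 1))
  expect_identical(unname(derive_template("hom/-si", "ternary")[
    c("some-all-pos", "some-gap-pos")]), c(1, 1))
  # the unresolved negated-universal gap cells honour the overrides
  expect_identical(unname(sa["all-gap-neg"]), 1)
  expect_identical(unname(ws["all-gap-neg"]), 0)
  expect_identical(unname(pt["all-gap-neg"]), 0)
  ov <- strategy_overrides()
  ov$ws["all-gap-neg"] <- 1
  expect_identical(
    unname(derive_template("ws/-si", "ternary",
                           overrides = ov)["all-gap-neg"]), 1)
})

test_that("template export is long-format CSV with the shared vocabulary", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_templates(path, "binary")
  df <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(names(df),
                   c("condition", "group", "paradigm", "expected_response"))
  expect_identical(nrow(df), 9L * 6L)
  expect_true(all(df$condition %in% design_conditions("binary")))
})
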