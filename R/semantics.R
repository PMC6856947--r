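#' Finite-model meanings
#'
#' With a domain of `n_objects` objects, the (positive) meaning of a design
#' sentence is fully described by its truth set: the set of counts `k` of
#' matching objects at which it is true. `literal_meaning()` returns that set
#' for the three determiners; the plural definite (`"the"`) is ambiguous
#' between a literal existential construal (`reading = "exi"`, the default,
#' the literal meaning under the implicature account of homogeneity) and a
#' universal construal (`reading` `"uni"` or `"ws"`).
#'
#' @param determiner `"the"`, `"some"` or `"all"`.
#' @param n_objects Domain size (>= 1).
#' @param reading Reading of the definite, used only for `determiner = "the"`.
#' @return Sorted integer vector of `k` values (subset of `0:n_objects`).
#' @examples
#' literal_meaning("some", 4)            # 1 2 3 4
#' literal_meaning("the", 4, "uni")      # 4
#' @export
literal_meaning <- function(determiner, n_objects = 4L, reading = "exi") {
  stopifnot(n_objects >= 1L)
  n <- as.integer(n_objects)
  if (determiner == "some") return(seq_len(n))
  if (determiner == "all") return(n)
  if (determiner == "the") {
    if (reading %in% c("exi", "wse")) return(seq_len(n))
    if (reading %in% c("uni", "ws")) return(n)
    stop("no literal meaning for determiner 'the' under reading '",
         reading, "'", call. = FALSE)
  }
  stop("unknown determiner: ", determiner, call. = FALSE)
}

#' Exhaustification over a finite domain
#'
#' `exhaustify()` strengthens a prejacent meaning by conjoining it with the
#' negation of its excludable alternatives, the mechanism behind scalar
#' implicatures ("some" strengthened to "some but not all"). An alternative is
#' excluded iff it is not entailed by the prejacent and negating it, jointly
#' with the alternatives already excluded (taken in the given order), leaves
#' the strengthened meaning non-empty. At this fragment's size the
#' consistency-preserving criterion coincides with excluding strictly
#' stronger alternatives.
#'
#' `recursive_exhaustify()` applies exhaustification at two levels: each
#' alternative is first exhaustified against the remaining alternatives, and
#' the prejacent is then exhaustified against these strengthened alternatives.
#' Applied to the literal existential meaning of the plural definite with the
#' scalar alternatives "some" (whose own alternative is "all") this derives
#' the universal meaning, turning an existential literal into a homogeneity-
#' style maximal claim.
#'
#' @param prejacent Integer vector: truth set of the asserted meaning.
#' @param alternatives List of integer vectors: truth sets of the
#'   alternatives, in the order in which exclusion is considered.
#' @param n_objects Domain size shared by all meanings.
#' @return Sorted integer vector: the strengthened truth set.
#' @examples
#' exhaustify(1:4, list(4L), 4)                      # 1 2 3
#' recursive_exhaustify(1:4, list(1:4, 4L), 4)       # 4
#' @export
exhaustify <- function(prejacent, alternatives = list(), n_objects = 4L) {
  domain <- 0:as.integer(n_objects)
  prejacent <- sort(unique(as.integer(prejacent)))
  if (length(prejacent) == 0L) {
    stop("empty prejacent: vacuous assertion", call. = FALSE)
  }
  if (any(!prejacent %in% domain)) {
    stop("prejacent outside the domain 0..", n_objects, call. = FALSE)
  }
  result <- prejacent
  for (alt in alternatives) {
    alt <- sort(unique(as.integer(alt)))
    if (any(!alt %in% domain)) {
      stop("alternative outside the domain 0..", n_objects, call. = FALSE)
    }
    entailed <- all(prejacent %in% alt)
    if (entailed) next
    candidate <- setdiff(result, alt)
    if (length(candidate) > 0L) result <- candidate
  }
  result
}

#' @rdname exhaustify
#' @export
recursive_exhaustify <- function(prejacent, alternatives = list(),
                                 n_objects = 4L) {
  strengthened <- lapply(seq_along(alternatives), function(i) {
    exhaustify(alternatives[[i]], alternatives[-i], n_objects)
  })
  out <- exhaustify(prejacent, strengthened, n_objects)
  if (length(out) == 0L) {
    stop("contradictory strengthening: empty result", call. = FALSE)
  }
  out
}

# -- trivalent evaluation ----------------------------------------------------

trivalent_negate <- function(v) {
  switch(v, "TRUE" = "FALSE", "FALSE" = "TRUE", "GAP" = "GAP")
}

#' Trivalent evaluation of a design sentence
#'
#' Evaluates a sentence (determiner + polarity), under a reading of the
#' plural definite, in a world with `k` of `n_objects` matching objects.
#' Values are `"TRUE"`, `"FALSE"` or `"GAP"` (neither true nor false).
#'
#' The homogeneous reading (`"hom"`) of a positive definite is true iff all
#' objects match, false iff none do, and gappy otherwise; its negation is the
#' trivalent negation (swapping true and false, fixing the gap). The
#' existential (`"exi"`) and universal (`"uni"`) readings are bivalent with
#' negation taking scope over them (so the negated existential is true iff
#' `k = 0` and the negated universal iff `k < n`). `"ws"` construes the
#' negated definite with the universal scoping over negation (true iff
#' `k = 0`), and `"wse"` with a wide-scope existential (true iff `k < n`).
#' The strategy readings `"sa"` and `"pt"` evaluate as `"uni"` and `"ws"`
#' respectively; their characteristic intermediate responses are applied at
#' the template level (see [derive_template()]). Sentences with `some`/`all`
#' evaluate classically; the negated universal ("pas tous") is read as
#' not-all.
#'
#' @param determiner `"the"`, `"some"` or `"all"`.
#' @param polarity `"pos"` or `"neg"`.
#' @param reading Reading of the definite (ignored for `some`/`all`).
#' @param k Number of matching objects.
#' @param n_objects Domain size.
#' @return `"TRUE"`, `"FALSE"` or `"GAP"`.
#' @examples
#' evaluate_sentence("the", "pos", "hom", k = 2, n_objects = 4)  # "GAP"
#' evaluate_sentence("the", "neg", "uni", k = 2, n_objects = 4)  # "TRUE"
#' @export
evaluate_sentence <- function(determiner, polarity, reading = "exi",
                              k, n_objects = 4L) {
  n <- as.integer(n_objects)
  k <- as.integer(k)
  stopifnot(k >= 0L, k <= n)
  tv <- function(x) if (x) "TRUE" else "FALSE"

  if (determiner == "some") {
    pos <- tv(k >= 1L)
    return(if (polarity == "pos") pos else trivalent_negate(pos))
  }
  if (determiner == "all") {
    pos <- tv(k == n)
    # "pas tous" = not-all
    return(if (polarity == "pos") pos else trivalent_negate(pos))
  }
  if (determiner != "the") stop("unknown determiner: ", determiner,
                                call. = FALSE)

  base <- switch(reading,
    exi = , wse = tv(k >= 1L),
    uni = , sa = tv(k == n),
    ws = , pt = tv(k == n),
    hom = if (k == n) "TRUE" else if (k == 0L) "FALSE" else "GAP",
    stop("unknown reading: ", reading, call. = FALSE)
  )
  if (polarity == "pos") return(base)
  switch(reading,
    exi = , hom = , uni = , sa = trivalent_negate(base),
    ws = , pt = tv(k == 0L),   # wide-scope universal over negation
    wse = tv(k < n),           # wide-scope existential over negation
    stop("unknown reading: ", reading, call. = FALSE)
  )
}

# -- predicted response templates --------------------------------------------

#' Default strategy overrides for the ternary template
#'
#' The scope-ambiguity (`sa`), strict wide-scope (`ws`) and partial-truth
#' (`pt`) strategies do not determine a unique prediction for the negated
#' universal sentence in a gap context (`all-gap-neg`): the sentence has a
#' true low-scope construal but a false surface-scope construal, and how a
#' strategy user scores it is a choice about the strategy, not a consequence
#' of the semantics. The defaults here score it maximal under `sa` (the
#' low-scope construal, which the plain evaluation already gives),
#' intermediate under `ws` and under `pt`. Pass a modified list to
#' [derive_template()] to explore other conventions, e.g. to force the
#' prose-unconstrained `sa` cells of the strategy readings.
#'
#' @return Named list: per reading, a named numeric vector of
#'   condition -> response overrides.
#' @export
strategy_overrides <- function() {
  list(
    sa = c("all-gap-neg" = 1),
    ws = c("all-gap-neg" = 0),
    pt = c("all-gap-neg" = 0)
  )
}

# does a false evaluation count as "partially true" for the pt strategy?
# positive universal claim with k > 0, or wide-scope negative universal
# claim with k < n.
partially_true <- function(determiner, polarity, reading, k, n) {
  if (polarity == "pos" &&
      (determiner == "all" || (determiner == "the" && reading == "pt"))) {
    return(k > 0L)
  }
  if (polarity == "neg" && determiner == "the" && reading == "pt") {
    return(k < n)
  }
  FALSE
}

#' Predicted response template of an interpretive group
#'
#' Derives, from the trivalent semantics, the response a noiseless member of
#' a group is expected to give in every condition of a paradigm. In the
#' binary paradigm the response is 1 (accept) iff the sentence evaluates true
#' and, for implicature computers, carries no false implicature; a truth
#' value gap maps to rejection (gap-context definites were assessed as
#' non-true). In the ternary paradigm true maps to the maximal reward (+1),
#' false to the minimal (-1) and a gap to the intermediate (0); a literally
#' true sentence with a false scalar implicature also earns the intermediate
#' reward. Strategy readings add their characteristic adjustments: `sa`
#' scores the negated definite in a gap context intermediate (true on one
#' scopal construal only), and `pt` upgrades false-but-partially-true
#' universal claims to intermediate.
#'
#' @param group Group label, e.g. `"hom/-si"` (see [design_groups()]).
#' @param paradigm `"binary"` or `"ternary"`.
#' @param n_objects Domain size.
#' @param overrides Strategy override list, see [strategy_overrides()].
#' @return Named numeric vector over [design_conditions()] of the paradigm:
#'   0/1 (binary) or -1/0/1 (ternary).
#' @examples
#' derive_template("hom/-si", "binary")["the-gap-pos"]   # 0
#' derive_template("exi/-si", "binary")["the-gap-pos"]   # 1
#' @export
derive_template <- function(group, paradigm = c("binary", "ternary"),
                            n_objects = 4L, overrides = strategy_overrides()) {
  paradigm <- match.arg(paradigm)
  g <- check_group(group, paradigm)
  conds <- design_conditions(paradigm)
  n <- as.integer(n_objects)
  # scalar-implicature strengthened meaning of lexical "some"
  some_strengthened <- exhaustify(literal_meaning("some", n),
                                  list(literal_meaning("all", n)), n)
  out <- vapply(conds, function(cond) {
    p <- parse_condition(cond)
    k <- context_k(p$context, n)
    v <- evaluate_sentence(p$determiner, p$polarity, g$reading, k, n)
    # implicature flag affects only sentences with lexical "some"
    false_si <- g$si && p$determiner == "some" && p$polarity == "pos" &&
      v == "TRUE" && !(k %in% some_strengthened)
    if (paradigm == "binary") {
      r <- if (v == "TRUE" && !false_si) 1 else 0
    } else {
      r <- switch(v, "TRUE" = 1, "FALSE" = -1, "GAP" = 0)
      if (false_si) r <- 0
      if (g$reading == "sa" && cond == "the-gap-neg") r <- 0
      if (g$reading == "pt" && r == -1 &&
          partially_true(p$determiner, p$polarity, g$reading, k, n)) {
        r <- 0
      }
      ov <- overrides[[g$reading]]
      if (!is.null(ov) && cond %in% names(ov)) r <- unname(ov[[cond]])
    }
    r
  }, numeric(1L))
  out
}

#' Template table for a full group inventory
#'
#' @param paradigm `"binary"` or `"ternary"`.
#' @param groups Group labels (default: the paradigm's design inventory).
#' @param ... Passed to [derive_template()].
#' @return A data frame in long format with columns `condition`, `group`,
#'   `paradigm`, `expected_response`.
#' @export
template_table <- function(paradigm = c("binary", "ternary"),
                           groups = design_groups(paradigm), ...) {
  paradigm <- match.arg(paradigm)
  conds <- design_conditions(paradigm)
  rows <- lapply(groups, function(g) {
    data.frame(
      condition = conds,
      group = g,
      paradigm = paradigm,
      expected_response = unname(derive_template(g, paradigm, ...)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @rdname template_table
#' @param path File path for the CSV export.
#' @export
write_templates <- function(path, paradigm = c("binary", "ternary"), ...) {
  utils::write.csv(template_table(paradigm, ...), path, row.names = FALSE)
  invisible(path)
}
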