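#' Condition vocabulary
#'
#' Every cell of the two experimental designs is named by a
#' `"[determiner]-[context]-[polarity]"` label, e.g. `"the-gap-pos"`: a plural
#' definite description, uttered about a display in which some but not all
#' objects match the predicate, in a positive sentence. This vocabulary is the
#' single source of truth shared by the simulator, the categorizer and the
#' mixture model.
#'
#' @param paradigm `"binary"` (accept/reject) or `"ternary"` (reward -1/0/+1).
#' @return Character vector of condition labels in a fixed canonical order.
#' @examples
#' design_conditions("binary")
#' @export
design_conditions <- function(paradigm = c("binary", "ternary")) {
  paradigm <- match.arg(paradigm)
  base <- c(
    "the-gap-pos", "the-gap-neg",
    "the-all-pos", "the-all-neg",
    "the-none-pos", "the-none-neg",
    "all-gap-pos", "all-gap-neg",
    "some-all-pos"
  )
  if (paradigm == "ternary") base <- c(base, "some-gap-pos")
  base
}

#' @rdname design_conditions
#' @param condition A condition label.
#' @return `parse_condition()`: a list with elements `determiner`
#'   (`"the"`/`"some"`/`"all"`), `context` (`"gap"`/`"all"`/`"none"`) and
#'   `polarity` (`"pos"`/`"neg"`).
#' @export
parse_condition <- function(condition) {
  parts <- strsplit(condition, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 3L ||
      !parts[1L] %in% c("the", "some", "all") ||
      !parts[2L] %in% c("gap", "all", "none") ||
      !parts[3L] %in% c("pos", "neg")) {
    stop("malformed condition label: ", condition, call. = FALSE)
  }
  list(determiner = parts[1L], context = parts[2L], polarity = parts[3L])
}

#' Number of matching objects in a context
#'
#' Maps a context label to the count `k` of objects satisfying the colour
#' predicate out of `n_objects` displayed: `all` has `k = n`, `none` has
#' `k = 0`, and `gap` has `0 < k < n` (the displays used two of four).
#'
#' @param context `"gap"`, `"all"` or `"none"`.
#' @param n_objects Domain size (default 4, the displays' object count).
#' @return Integer `k`.
#' @export
context_k <- function(context, n_objects = 4L) {
  stopifnot(n_objects >= 2L)
  switch(context,
    all  = as.integer(n_objects),
    none = 0L,
    gap  = as.integer(n_objects %/% 2L),
    stop("unknown context: ", context, call. = FALSE)
  )
}

# -- interpretive groups -----------------------------------------------------

#' Interpretive groups
#'
#' A group pairs a reading of the plural definite with an implicature flag.
#' Readings: `exi` (low-scope existential), `hom` (homogeneous), `uni`
#' (low-scope universal), `wse` (wide-scope existential; binary paradigm
#' only), `sa` (universal with scope-ambiguity strategy), `ws` (strict
#' wide-scope universal), `pt` (wide-scope universal with partial-truth
#' strategy; the latter three ternary only). Groups are written as labels like
#' `"hom/-si"` or `"exi/+si"`.
#'
#' `design_groups()` returns the full inventory for which response templates
#' are tabulated: the six binary groups (`exi`/`hom`/`uni` crossed with
#' implicature) and the ten ternary groups.
#'
#' @param paradigm `"binary"` or `"ternary"`.
#' @return Character vector of group labels.
#' @export
design_groups <- function(paradigm = c("binary", "ternary")) {
  paradigm <- match.arg(paradigm)
  readings <- if (paradigm == "binary") c("exi", "hom", "uni") else
    c("exi", "hom", "sa", "ws", "pt")
  as.vector(t(outer(readings, c("/+si", "/-si"), paste0)))
}

#' @rdname design_groups
#' @param group A group label such as `"hom/-si"`.
#' @return `parse_group()`: a list with elements `reading` and `si` (logical).
#' @export
parse_group <- function(group) {
  parts <- strsplit(group, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L ||
      !parts[1L] %in% c("exi", "hom", "uni", "wse", "sa", "ws", "pt") ||
      !parts[2L] %in% c("+si", "-si")) {
    stop("malformed group label: ", group, call. = FALSE)
  }
  list(reading = parts[1L], si = parts[2L] == "+si")
}

#' @rdname design_groups
#' @param reading Reading code.
#' @param si Logical: does the group compute scalar implicatures?
#' @export
make_group <- function(reading, si) {
  paste0(reading, if (isTRUE(si)) "/+si" else "/-si")
}

# readings admissible per paradigm (wse is the fourth logically possible
# binary pattern: accept both gap targets)
admissible_readings <- function(paradigm) {
  if (paradigm == "binary") c("exi", "hom", "uni", "wse") else
    c("exi", "hom", "sa", "ws", "pt")
}

check_group <- function(group, paradigm) {
  g <- parse_group(group)
  if (!g$reading %in% admissible_readings(paradigm)) {
    stop("group ", group, " is not admissible in the ", paradigm,
         " paradigm", call. = FALSE)
  }
  g
}
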