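#' A measured quantity with optional spread, range and bound information
#'
#' Motility compilations report each measured value in a compact cell
#' notation: a bare mean (`"5"`), a mean with a standard deviation
#' (`"24.1 ± 10"`), a range (`"(2 − 7)"`), an upper bound
#' (`"max 35"`), or combinations such as `"24.1 ± 10 (14.2 − 60)"`.
#' `quantity()` is the typed in-memory form of one such cell.
#'
#' @param point Central (mean) value, or `NA` when only a range or bound was
#'   reported.
#' @param sd Standard deviation; requires `point`.
#' @param lo,hi Lower and upper end of the reported range. `hi` alone (with
#'   `bound_only = TRUE`) represents a "max" cell.
#' @param bound_only Logical; `TRUE` when the cell carried only an upper
#'   bound ("max ...") and nothing else.
#'
#' @details At least one of `point`, `lo`, `hi` must be present. `lo <= hi`
#'   is enforced when both are present. A point lying outside the printed
#'   range occurs in real tables and is accepted with a warning.
#'
#' @return An object of class `"quantity"`: a list with fields `point`,
#'   `sd`, `lo`, `hi`, `bound_only` (absent values are `NA`).
#' @seealso [parse_quantity()], [collapse_quantity()]
#' @export
#' @examples
#' quantity(point = 24.1, sd = 10, lo = 14.2, hi = 60)
#' quantity(lo = 2, hi = 7)
quantity <- function(point = NA_real_, sd = NA_real_, lo = NA_real_,
                     hi = NA_real_, bound_only = FALSE) {
  q <- structure(
    list(point = as.numeric(point), sd = as.numeric(sd),
         lo = as.numeric(lo), hi = as.numeric(hi),
         bound_only = isTRUE(bound_only)),
    class = "quantity")
  validate_quantity(q)
  q
}

validate_quantity <- function(q) {
  if (is.na(q$point) && is.na(q$lo) && is.na(q$hi))
    stop("quantity: at least one of point/lo/hi must be present",
         call. = FALSE)
  if (!is.na(q$sd)) {
    if (q$sd < 0) stop("quantity: sd must be >= 0", call. = FALSE)
    if (is.na(q$point))
      stop("quantity: sd requires a point value", call. = FALSE)
  }
  if (!is.na(q$lo) && !is.na(q$hi) && q$lo > q$hi)
    stop("quantity: lo must not exceed hi", call. = FALSE)
  if (!is.na(q$point)) {
    if ((!is.na(q$lo) && q$point < q$lo) ||
        (!is.na(q$hi) && q$point > q$hi))
      warning("quantity: point lies outside the reported range",
              call. = FALSE)
  }
  invisible(q)
}

#' @export
print.quantity <- function(x, ...) {
  cat("<quantity> ", format_quantity(x), "\n", sep = "")
  invisible(x)
}

#' @rdname quantity
#' @param x Object to test.
#' @export
is_quantity <- function(x) inherits(x, "quantity")

# footnote markers that may decorate table cells; stripped before parsing
.qty_markers <- c("\u2020", "\u2021", "\u22c6", "\u00d7", "\u2662",
                  "\u2663", "\u2660", "\u266f", "\u25ca", "*")

#' Parse a printed table cell into a [quantity()]
#'
#' Understands the cell grammar of published motility tables:
#' `a`, `a ± s`, `(a − b)`, `max b`, and the combinations
#' `a (b − c)`, `a ± s (b − c)`, `a (max b)`,
#' `a ± s (max b)`. ASCII hyphens and `+-` are accepted in place of
#' the typeset minus and plus-minus signs, and footnote markers
#' (daggers, stars, crosses) are stripped before parsing. No unit
#' conversion is performed: the fields are returned exactly as printed.
#'
#' @param text A single character string (one table cell).
#' @return A [quantity()]. Stripped footnote markers, if any, are kept in
#'   the `"markers"` attribute.
#' @export
#' @examples
#' parse_quantity("24.1 ± 10 (14.2 − 60)")
#' parse_quantity("(2 − 7)")
#' parse_quantity("max35")
parse_quantity <- function(text) {
  if (length(text) != 1L || !is.character(text))
    stop("parse_quantity expects a single character string", call. = FALSE)
  raw <- text
  s <- text
  # superscripted markers appear as ^...^ runs in extracted tables
  s <- gsub("\\^[^^]*\\^", "", s)
  markers <- character(0)
  for (m in .qty_markers) {
    if (grepl(m, s, fixed = TRUE)) {
      markers <- c(markers, m)
      s <- gsub(m, "", s, fixed = TRUE)
    }
  }
  # normalise typeset symbols to ASCII
  s <- gsub("\u2212|\u2013|\u2014", "-", s)
  s <- gsub("\u00b1", "+-", s)
  s <- gsub("[[:space:]]+", " ", trimws(s))

  num <- "[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?"
  range_re <- paste0("\\( ?(", num, ") ?- ?(", num, ") ?\\)")
  max_re <- paste0("\\(? ?max ?(", num, ") ?\\)?")
  pm_re <- paste0("^(", num, ")(?: ?\\+- ?(", num, "))?")

  point <- NA_real_; sd <- NA_real_; lo <- NA_real_; hi <- NA_real_
  bound_only <- FALSE
  rest <- s

  m <- regexec(pm_re, rest)
  if (m[[1]][1] == 1L) {
    g <- regmatches(rest, m)[[1]]
    point <- as.numeric(g[2])
    if (g[3] != "") sd <- as.numeric(g[3])
    rest <- trimws(sub(pm_re, "", rest))
  }

  if (grepl(range_re, rest)) {
    g <- regmatches(rest, regexec(range_re, rest))[[1]]
    lo <- as.numeric(g[2]); hi <- as.numeric(g[3])
    rest <- trimws(sub(range_re, "", rest))
  } else if (grepl(max_re, rest)) {
    g <- regmatches(rest, regexec(max_re, rest))[[1]]
    hi <- as.numeric(g[2])
    bound_only <- is.na(point)  # a lone "max b" carries only the bound
    rest <- trimws(sub(max_re, "", rest))
  }

  if (nzchar(rest) || (is.na(point) && is.na(lo) && is.na(hi))) {
    cnd <- structure(
      class = c("microswim_parse_error", "error", "condition"),
      list(message = sprintf("cannot parse quantity cell: '%s'", raw),
           call = NULL, text = raw))
    stop(cnd)
  }
  q <- quantity(point = point, sd = sd, lo = lo, hi = hi,
                bound_only = bound_only)
  if (length(markers)) attr(q, "markers") <- markers
  q
}

#' Format a [quantity()] back into its printed cell notation
#'
#' Inverse of [parse_quantity()] on the canonical spelling of the grammar
#' (single spaces, typeset plus-minus and minus signs).
#'
#' @param q A [quantity()].
#' @return A character string.
#' @export
format_quantity <- function(q) {
  stopifnot(is_quantity(q))
  parts <- character(0)
  if (!is.na(q$point)) {
    p <- format(q$point, scientific = FALSE, trim = TRUE)
    if (!is.na(q$sd))
      p <- paste0(p, " \u00b1 ", format(q$sd, scientific = FALSE, trim = TRUE))
    parts <- p
  }
  if (!is.na(q$lo) && !is.na(q$hi)) {
    parts <- c(parts, paste0("(", format(q$lo, scientific = FALSE, trim = TRUE),
                             " \u2212 ",
                             format(q$hi, scientific = FALSE, trim = TRUE), ")"))
  } else if (!is.na(q$hi) && is.na(q$point)) {
    parts <- c(parts, paste0("max ", format(q$hi, scientific = FALSE,
                                            trim = TRUE)))
  } else if (!is.na(q$hi)) {
    parts <- c(parts, paste0("(max ", format(q$hi, scientific = FALSE,
                                             trim = TRUE), ")"))
  }
  paste(parts, collapse = " ")
}

#' Precedence policy for collapsing a quantity to one number
#'
#' Published per-species figures are built from one number per cell, but the
#' sources never state which value inside a printed range was used. The
#' collapse policy makes that choice explicit and auditable: the default
#' takes the printed mean when present, otherwise the midpoint of the range,
#' and falls back on the upper bound only when nothing else exists.
#'
#' @param order Character vector, a precedence list over
#'   `"point"`, `"midpoint"`, `"hi"`.
#' @return An object of class `"collapse_policy"`.
#' @export
collapse_policy <- function(order = c("point", "midpoint", "hi")) {
  order <- match.arg(order, c("point", "midpoint", "hi"),
                     several.ok = TRUE)
  if (!length(order)) stop("collapse_policy: empty precedence list",
                           call. = FALSE)
  structure(list(order = order), class = "collapse_policy")
}

#' Collapse a [quantity()] to a single number under a policy
#'
#' @param q A [quantity()] (or a bare number, returned unchanged).
#' @param policy A [collapse_policy()].
#' @return A numeric scalar with attributes `"rule"` (which precedence rule
#'   fired) and `"bound"` (`TRUE` if the value is only an upper bound).
#' @export
#' @examples
#' collapse_quantity(quantity(lo = 2, hi = 7))  # midpoint 4.5
collapse_quantity <- function(q, policy = collapse_policy()) {
  if (is.numeric(q) && length(q) == 1L)
    return(structure(as.numeric(q), rule = "point", bound = FALSE))
  stopifnot(is_quantity(q), inherits(policy, "collapse_policy"))
  for (rule in policy$order) {
    val <- switch(rule,
      point = q$point,
      midpoint = if (!is.na(q$lo) && !is.na(q$hi)) (q$lo + q$hi) / 2
                 else NA_real_,
      hi = q$hi)
    if (!is.na(val))
      return(structure(val, rule = rule,
                       bound = rule == "hi" && q$bound_only))
  }
  stop("collapse_quantity: no rule in the policy applies", call. = FALSE)
}

# scale a quantity by a positive constant (used in tests for equivariance)
#' @export
`*.quantity` <- function(e1, e2) {
  if (is_quantity(e1)) { q <- e1; c0 <- e2 } else { q <- e2; c0 <- e1 }
  stopifnot(is.numeric(c0), length(c0) == 1L, c0 > 0)
  quantity(point = q$point * c0, sd = if (is.na(q$sd)) NA_real_ else q$sd * c0,
           lo = q$lo * c0, hi = q$hi * c0, bound_only = q$bound_only)
}
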