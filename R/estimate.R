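#' Result of a per-organism dynamic estimate
#'
#' Container for one inferred dynamic quantity (Reynolds number, motor
#' torque, predicted speed, surface stress, per-cilium force, or effective
#' surface velocity) together with the collapsed inputs and the imputations
#' that produced it. Exactly one of `value` / `skip_reason` is present:
#' records lacking the inputs a model needs are skipped, not guessed.
#'
#' @param species Species name.
#' @param kind One of `"Re"`, `"Re_omega"`, `"Tm"`, `"U_pred"`, `"tau"`,
#'   `"F"`, `"u_hat"`.
#' @param value Numeric value, or `NULL` when skipped.
#' @param units Unit string (e.g. `"pN nm"`).
#' @param inputs Named numeric vector of the collapsed inputs used.
#' @param imputations Character vector describing defaulted or inverted
#'   parameters (empty when all inputs were measured).
#' @param skip_reason Why no value could be computed, or `NULL`.
#' @return An object of class `"estimate_result"`.
#' @export
estimate_result <- function(species, kind, value = NULL, units = "",
                            inputs = numeric(0),
                            imputations = character(0),
                            skip_reason = NULL) {
  kinds <- c("Re", "Re_omega", "Tm", "U_pred", "tau", "F", "u_hat")
  kind <- match.arg(kind, kinds)
  if (is.null(value) == is.null(skip_reason))
    stop("estimate_result: exactly one of value/skip_reason must be given",
         call. = FALSE)
  structure(
    list(species = species, kind = kind,
         value = if (is.null(value)) NULL else as.numeric(value),
         units = units, inputs = inputs,
         imputations = as.character(imputations),
         skip_reason = skip_reason),
    class = "estimate_result")
}

#' @rdname estimate_result
#' @param x An object.
#' @export
is_skipped <- function(x) {
  stopifnot(inherits(x, "estimate_result"))
  !is.null(x$skip_reason)
}

#' @export
print.estimate_result <- function(x, ...) {
  if (is_skipped(x)) {
    cat(sprintf("<estimate> %s %s: skipped (%s)\n",
                x$species, x$kind, x$skip_reason))
  } else {
    cat(sprintf("<estimate> %s %s = %.6g %s\n",
                x$species, x$kind, x$value, x$units))
    if (length(x$imputations))
      cat("  imputed:", paste(x$imputations, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.estimate_result <- function(x, ...) {
  data.frame(species = x$species, kind = x$kind,
             value = if (is_skipped(x)) NA_real_ else x$value,
             units = x$units,
             imputations = paste(x$imputations, collapse = "; "),
             skip_reason = if (is_skipped(x)) x$skip_reason else "",
             stringsAsFactors = FALSE)
}
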