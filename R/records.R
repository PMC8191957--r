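#' Organism record: one species' geometry, kinematics and provenance
#'
#' One row of a motility compilation: the species name, its taxonomic group,
#' and the measured geometric/kinematic quantities. All quantity fields take
#' a [quantity()], a printed cell string (parsed on the fly), or a bare
#' number (treated as a point value).
#'
#' @param species Species name (non-empty).
#' @param group One of `"bacteria"`, `"spirochaete"`, `"spiroplasma"`,
#'   `"archaea"`, `"flagellate"`, `"spermatozoon"`, `"ciliate"`.
#' @param B Body length (um). Mandatory.
#' @param W Body width/diameter (um).
#' @param U Swimming speed (um/s).
#' @param N Number of flagella or cilia.
#' @param L Flagellum length (um).
#' @param lam Wavelength of the flagellar wave or helix pitch (um).
#' @param h Wave amplitude or helix radius (um).
#' @param n_w Number of complete waves on the flagellum.
#' @param f Beat/rotation frequency in cycles per second. Frequencies are
#'   stored as cycles/s throughout; models convert to angular rates via an
#'   explicit `2 * pi`.
#' @param ell Cilium length (um).
#' @param d Inter-cilium spacing (um).
#' @param kappa Cilia per unit area (um^-2).
#' @param notes,refs Free-text provenance.
#' @return An object of class `"organism_record"`. Validation diagnostics
#'   (e.g. an aspect ratio above 1) are attached as the `"diagnostics"`
#'   attribute rather than rejected: such rows do occur in real tables.
#' @export
#' @examples
#' organism_record("Escherichia coli", "bacteria",
#'                 B = "2.5 ± 0.6", U = "24.1 ± 10 (14.2 − 60)")
organism_record <- function(species, group,
                            B, W = NULL, U = NULL, N = NULL, L = NULL,
                            lam = NULL, h = NULL, n_w = NULL, f = NULL,
                            ell = NULL, d = NULL, kappa = NULL,
                            notes = "", refs = "") {
  if (!is.character(species) || !nzchar(trimws(species)))
    stop("organism_record: species must be a non-empty string", call. = FALSE)
  group <- match.arg(group, organism_groups())
  as_q <- function(x, name) {
    if (is.null(x) || (is.character(x) && !nzchar(trimws(x)))) return(NULL)
    if (is_quantity(x)) return(x)
    if (is.character(x)) return(parse_quantity(x))
    if (is.numeric(x) && length(x) == 1L && !is.na(x))
      return(quantity(point = x))
    stop(sprintf("organism_record: field '%s' is not quantity-like", name),
         call. = FALSE)
  }
  rec <- structure(
    list(species = species, group = group,
         B = as_q(B, "B"), W = as_q(W, "W"), U = as_q(U, "U"),
         N = as_q(N, "N"), L = as_q(L, "L"), lam = as_q(lam, "lam"),
         h = as_q(h, "h"), n_w = as_q(n_w, "n_w"), f = as_q(f, "f"),
         ell = as_q(ell, "ell"), d = as_q(d, "d"),
         kappa = as_q(kappa, "kappa"),
         notes = as.character(notes), refs = as.character(refs)),
    class = "organism_record")
  if (is.null(rec$B))
    stop("organism_record: B (body length) is mandatory", call. = FALSE)
  diagnostics <- validate_record(rec)
  if (length(diagnostics)) attr(rec, "diagnostics") <- diagnostics
  rec
}

#' @rdname organism_record
#' @export
organism_groups <- function() {
  c("bacteria", "spirochaete", "spiroplasma", "archaea",
    "flagellate", "spermatozoon", "ciliate")
}

# returns a character vector of per-record diagnostics (empty when clean)
validate_record <- function(rec) {
  out <- character(0)
  pol <- collapse_policy()
  lengths <- c("B", "W", "L", "lam", "h", "ell", "d")
  for (fld in lengths) {
    q <- rec[[fld]]
    if (!is.null(q)) {
      v <- collapse_quantity(q, pol)
      if (v <= 0)
        out <- c(out, sprintf("%s: %s must be > 0", rec$species, fld))
    }
  }
  if (!is.null(rec$W)) {
    w <- collapse_quantity(rec$W, pol)
    b <- collapse_quantity(rec$B, pol)
    if (w > b)
      out <- c(out, sprintf("%s: aspect ratio W/B = %.3g exceeds 1 (oblate?)",
                            rec$species, w / b))
  }
  out
}

#' @export
print.organism_record <- function(x, ...) {
  cat(sprintf("<organism_record> %s [%s]\n", x$species, x$group))
  for (fld in c("B", "W", "U", "N", "L", "lam", "h", "n_w", "f",
                "ell", "d", "kappa")) {
    if (!is.null(x[[fld]]))
      cat(sprintf("  %-5s %s\n", fld, format_quantity(x[[fld]])))
  }
  invisible(x)
}

.record_qty_fields <- c("B", "W", "U", "N", "L", "lam", "h", "n_w", "f",
                        "ell", "d", "kappa")

#' Read organism records from a CSV or JSON file
#'
#' CSV files carry one record per row with the quantity columns holding
#' printed cells in the value grammar of [parse_quantity()] (quoted when
#' they contain commas). JSON files carry an array of objects whose quantity
#' fields are `{point, sd, lo, hi, bound_only}` objects; this form
#' round-trips bit-identically through [write_records()].
#'
#' @param path File path; format inferred from the extension unless `format`
#'   is given.
#' @param format `"csv"` or `"json"`.
#' @return A list of [organism_record()]s, in file order, with a
#'   `"diagnostics"` attribute (data frame: row, species, message) collecting
#'   per-row validation messages.
#' @export
read_records <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
    mandatory <- c("species", "group", "B")
    missing_cols <- setdiff(mandatory, names(df))
    if (length(missing_cols))
      stop("read_records: missing mandatory columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  } else {
    objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- lapply(objs, function(o) {
      for (fld in .record_qty_fields) {
        if (!is.null(o[[fld]])) {
          qq <- o[[fld]]
          o[[fld]] <- quantity(
            point = if (is.null(qq$point)) NA_real_ else qq$point,
            sd = if (is.null(qq$sd)) NA_real_ else qq$sd,
            lo = if (is.null(qq$lo)) NA_real_ else qq$lo,
            hi = if (is.null(qq$hi)) NA_real_ else qq$hi,
            bound_only = isTRUE(qq$bound_only))
        }
      }
      o
    })
  }
  diags <- list()
  records <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    args <- row[intersect(names(row),
                          c("species", "group", .record_qty_fields,
                            "notes", "refs"))]
    rec <- withCallingHandlers(
      do.call(organism_record, args),
      warning = function(w) {
        diags[[length(diags) + 1L]] <<-
          data.frame(row = i, species = as.character(row$species),
                     message = conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    d <- attr(rec, "diagnostics")
    if (length(d))
      diags[[length(diags) + 1L]] <-
        data.frame(row = i, species = rec$species, message = d)
    records[[i]] <- rec
  }
  attr(records, "diagnostics") <-
    if (length(diags)) do.call(rbind, diags)
    else data.frame(row = integer(0), species = character(0),
                    message = character(0))
  records
}

#' Write organism records to CSV or JSON
#'
#' @param records List of [organism_record()]s.
#' @param path Output file path.
#' @param format `"csv"` (cells formatted back into the printed grammar) or
#'   `"json"` (structured quantity objects; lossless round trip).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  if (format == "csv") {
    df <- do.call(rbind, lapply(records, function(r) {
      vals <- vapply(.record_qty_fields, function(fld) {
        if (is.null(r[[fld]])) "" else format_quantity(r[[fld]])
      }, character(1))
      as.data.frame(c(list(species = r$species, group = r$group),
                      as.list(vals),
                      list(notes = r$notes, refs = r$refs)))
    }))
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    objs <- lapply(records, function(r) {
      o <- list(species = r$species, group = r$group)
      for (fld in .record_qty_fields) {
        q <- r[[fld]]
        if (!is.null(q)) {
          qq <- list()
          if (!is.na(q$point)) qq$point <- q$point
          if (!is.na(q$sd)) qq$sd <- q$sd
          if (!is.na(q$lo)) qq$lo <- q$lo
          if (!is.na(q$hi)) qq$hi <- q$hi
          if (q$bound_only) qq$bound_only <- TRUE
          o[[fld]] <- qq
        }
      }
      o$notes <- r$notes
      o$refs <- r$refs
      o
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Collapse one field of a record to a single number
#'
#' @param rec An [organism_record()].
#' @param fld Field name (e.g. `"B"`, `"U"`).
#' @param policy A [collapse_policy()].
#' @return The collapsed numeric value, or `NA` when the field is absent.
#' @export
field_value <- function(rec, fld, policy = collapse_policy()) {
  q <- rec[[fld]]
  if (is.null(q)) return(NA_real_)
  as.numeric(collapse_quantity(q, policy))
}
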