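#' Run a propulsion-model estimation over a set of organism records
#'
#' Applies the chosen model's per-record estimator to every record, collects
#' the results in a table, and computes the min/max envelope over the
#' non-skipped estimates — the cohort bounds that published
#' speed-versus-morphology plots display as a shaded band between parallel
#' lines.
#'
#' @param records List of [organism_record()]s (one taxonomic group).
#' @param model `"rft_torque"` ([estimate_motor_torque()]), `"stress"`
#'   ([estimate_tau()]), `"force"` ([estimate_force_per_cilium()]),
#'   `"surface"` ([estimate_surface_speed()]), or `"speed"`
#'   ([predict_speed()]).
#' @param fluid A [fluid_medium()].
#' @param policy A [collapse_policy()].
#' @param mode Passed to [predict_speed()] when `model = "speed"`.
#' @return A data frame (one row per record: species, kind, value, units,
#'   imputations, skip_reason) with attributes `"bounds"` (list: min, max,
#'   argmin, argmax), `"results"` (the raw [estimate_result()] list) and
#'   `"log"` (run provenance: fluid, policy, skip count).
#' @export
#' @examples
#' path <- system.file("extdata", "torque_bound_records.csv",
#'                     package = "microswim")
#' est <- run_estimation(read_records(path), "rft_torque")
#' attr(est, "bounds")[c("min", "max")]
run_estimation <- function(records,
                           model = c("rft_torque", "stress", "force",
                                     "surface", "speed"),
                           fluid = fluid_medium(),
                           policy = collapse_policy(),
                           mode = c("exact", "approx")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  estimator <- switch(model,
    rft_torque = function(r) estimate_motor_torque(r, fluid, policy),
    stress = function(r) estimate_tau(r, fluid, policy),
    force = function(r) estimate_force_per_cilium(r, fluid, policy),
    surface = function(r) estimate_surface_speed(r, policy),
    speed = function(r) predict_speed(r, mode, fluid, policy))
  results <- lapply(records, estimator)
  tab <- do.call(rbind, lapply(results, as.data.frame))
  ok <- !vapply(results, is_skipped, logical(1))
  if (!any(ok))
    stop("run_estimation: no record had the inputs the model needs",
         call. = FALSE)
  vals <- tab$value[ok]
  sp <- tab$species[ok]
  bounds <- list(min = min(vals), max = max(vals),
                 argmin = sp[which.min(vals)], argmax = sp[which.max(vals)])
  attr(tab, "bounds") <- bounds
  attr(tab, "results") <- results
  attr(tab, "log") <- list(model = model, rho = fluid$rho, eta = fluid$eta,
                           policy = policy$order,
                           n = length(records), n_skipped = sum(!ok),
                           skipped = tab$species[!ok])
  tab
}

#' Summarise one field over a group of records
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and count
#' of non-missing values after range collapse — the format of published
#' histogram captions.
#'
#' @param records List of [organism_record()]s.
#' @param field Field name (e.g. `"B"`, `"U"`).
#' @param policy A [collapse_policy()].
#' @return A list with `mean`, `sd`, `n` (`mean`/`sd` are `NA` when n = 0;
#'   `sd` is 0 for a single value by convention of the reported captions).
#' @export
summarize_group <- function(records, field, policy = collapse_policy()) {
  vals <- vapply(records, function(r) field_value(r, field, policy),
                 numeric(1))
  vals <- vals[!is.na(vals)]
  n <- length(vals)
  if (n == 0) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(vals),
       sd = if (n > 1) stats::sd(vals) else 0,
       n = n)
}

#' Reynolds-number table for a set of records
#'
#' Computes the steady (`Re = rho U B / eta`) and oscillatory
#' (`Re_omega = rho omega ell^2 / eta`) Reynolds numbers per record, with
#' the angular rate obtained from the stored cycle frequency as
#' `omega = 2 pi f`. Records lacking the needed kinematics are dropped and
#' listed in the `"skipped"` attribute.
#'
#' @param records List of [organism_record()]s.
#' @param fluid A [fluid_medium()].
#' @param policy A [collapse_policy()].
#' @return A data frame with columns species, B, U, omega, ell, Re,
#'   Re_omega.
#' @export
#' @examples
#' path <- system.file("extdata", "table1_organisms.csv",
#'                     package = "microswim")
#' reynolds_table(read_records(path))
reynolds_table <- function(records, fluid = fluid_medium(),
                           policy = collapse_policy()) {
  rows <- list()
  skipped <- character(0)
  for (rec in records) {
    B <- field_value(rec, "B", policy)
    U <- field_value(rec, "U", policy)
    f <- field_value(rec, "f", policy)
    ell <- field_value(rec, "ell", policy)
    if (is.na(ell)) ell <- field_value(rec, "L", policy)
    if (anyNA(c(B, U, f, ell))) {
      skipped <- c(skipped, rec$species)
      next
    }
    omega <- 2 * pi * f
    rows[[length(rows) + 1L]] <- data.frame(
      species = rec$species, B = B, U = U, omega = omega, ell = ell,
      Re = reynolds_steady(fluid, U, B),
      Re_omega = reynolds_oscillatory(fluid, omega, ell))
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(species = character(0), B = numeric(0),
                         U = numeric(0), omega = numeric(0),
                         ell = numeric(0), Re = numeric(0),
                         Re_omega = numeric(0))
  attr(tab, "skipped") <- skipped
  tab
}
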