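#' Fluid medium
#'
#' Density and dynamic viscosity of the swimming medium. The defaults are
#' water at 25 degrees C (rho = 997 kg m^-3, eta = 0.89 mPa s), the medium
#' assumed whenever a study does not report the viscosity.
#'
#' @param rho Mass density in kg m^-3.
#' @param eta Dynamic viscosity in mPa s (1 mPa s = 1e-3 Pa s).
#' @return An object of class `"fluid_medium"`.
#' @export
#' @examples
#' water <- fluid_medium()     # water at 25 C
fluid_medium <- function(rho = 997, eta = 0.89) {
  stopifnot(is.numeric(rho), rho > 0, is.numeric(eta), eta > 0)
  structure(list(rho = rho, eta = eta), class = "fluid_medium")
}

#' @export
print.fluid_medium <- function(x, ...) {
  cat(sprintf("<fluid_medium> rho = %g kg m^-3, eta = %g mPa s\n",
              x$rho, x$eta))
  invisible(x)
}

# dynamic viscosity in SI (Pa s)
eta_si <- function(fluid) fluid$eta * 1e-3

#' Steady Reynolds number of a swimmer
#'
#' `Re = rho * U * B / eta`, the ratio of inertial to viscous forces for a
#' cell of size `B` moving at speed `U`. Microswimmers live at `Re << 1`.
#'
#' @param fluid A [fluid_medium()].
#' @param U Swimming speed in um/s (`U >= 0`).
#' @param B Body length in um (`B > 0`).
#' @return Dimensionless Reynolds number.
#' @export
#' @examples
#' reynolds_steady(fluid_medium(), U = 24.1, B = 2.5)  # ~6.75e-5
reynolds_steady <- function(fluid, U, B) {
  stopifnot(inherits(fluid, "fluid_medium"))
  if (any(B <= 0)) stop("reynolds_steady: B must be > 0", call. = FALSE)
  if (any(U < 0)) stop("reynolds_steady: U must be >= 0", call. = FALSE)
  fluid$rho * (U * 1e-6) * (B * 1e-6) / eta_si(fluid)
}

#' Oscillatory Reynolds number of a beating appendage
#'
#' `Re_omega = rho * omega * ell^2 / eta`, built on the appendage's angular
#' beat rate and length.
#'
#' @param fluid A [fluid_medium()].
#' @param omega Angular rate in rad/s (`omega >= 0`). Note: record tables
#'   store frequencies in cycles/s; convert with `2 * pi`.
#' @param ell Appendage length in um (`ell > 0`).
#' @return Dimensionless oscillatory Reynolds number.
#' @export
#' @examples
#' reynolds_oscillatory(fluid_medium(), omega = 823.1, ell = 8.3)  # ~6.35e-2
reynolds_oscillatory <- function(fluid, omega, ell) {
  stopifnot(inherits(fluid, "fluid_medium"))
  if (any(ell <= 0))
    stop("reynolds_oscillatory: ell must be > 0", call. = FALSE)
  if (any(omega < 0))
    stop("reynolds_oscillatory: omega must be >= 0", call. = FALSE)
  fluid$rho * omega * (ell * 1e-6)^2 / eta_si(fluid)
}
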