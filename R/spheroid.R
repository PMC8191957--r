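#' Prolate spheroid cell body
#'
#' Cell bodies are modelled as prolate spheroids of length `B` (major axis)
#' and diameter `W` (minor axis), with eccentricity
#' `e = sqrt(1 - (W/B)^2)`.
#'
#' @param B Body length in um.
#' @param W Body diameter in um, `0 < W <= B`.
#' @return An object of class `"spheroid_body"` with fields `B`, `W` and the
#'   derived eccentricity `e`.
#' @export
#' @examples
#' spheroid_body(B = 2.5, W = 0.88)
spheroid_body <- function(B, W) {
  stopifnot(is.numeric(B), length(B) == 1L, is.numeric(W), length(W) == 1L)
  if (!(B > 0) || !(W > 0))
    stop("spheroid_body: B and W must be > 0", call. = FALSE)
  if (W > B)
    stop("spheroid_body: prolate only (W must not exceed B)", call. = FALSE)
  e <- sqrt(max(0, 1 - (W / B)^2))
  # keep the log and 1/e expressions finite for needle-like bodies
  e <- min(e, 1 - 1e-12)
  structure(list(B = B, W = W, e = e), class = "spheroid_body")
}

#' @export
print.spheroid_body <- function(x, ...) {
  cat(sprintf("<spheroid_body> B = %g um, W = %g um (e = %.6g)\n",
              x$B, x$W, x$e))
  invisible(x)
}

#' Translational drag correction factor of a prolate spheroid
#'
#' The Stokes drag on a prolate spheroid moving along its long axis is
#' `3 * pi * eta * B * C_FB`, where
#' `C_FB = (8/3) e^3 / (-2 e + (1 + e^2) log((1 + e)/(1 - e)))`.
#' `C_FB` decreases from 1 (sphere) towards 0 as the body becomes more
#' slender. For `e < 5e-3` the 0/0 form (which loses ~10 digits to
#' cancellation there) is replaced by its series
#' `1 / (1 + (2/5) e^2 + (9/35) e^4)`.
#'
#' @param body A [spheroid_body()].
#' @return `C_FB`, a number in (0, 1].
#' @export
#' @examples
#' drag_correction_cfb(spheroid_body(2.6, 0.43))  # ~0.3265
drag_correction_cfb <- function(body) {
  stopifnot(inherits(body, "spheroid_body"))
  e <- body$e
  if (e < 5e-3) return(1 / (1 + (2 / 5) * e^2 + (9 / 35) * e^4))
  (8 / 3) * e^3 / (-2 * e + (1 + e^2) * log((1 + e) / (1 - e)))
}

#' Translational and rotational body drag coefficients
#'
#' `body_translational_drag()` returns `b11 = 3 pi eta B C_FB` (axial
#' translation); `body_rotational_drag()` returns `b22`, the torque
#' coefficient for rotation about the long axis,
#' `(32/3) pi eta a^3 e^3 (1 - e^2) / (2 e - (1 - e^2) log((1+e)/(1-e)))`
#' with `a = B/2`, reducing to the classical `8 pi eta R^3` for a sphere.
#' Both are in SI units (N s m^-1 and N s m).
#'
#' @param body A [spheroid_body()].
#' @param fluid A [fluid_medium()].
#' @return Drag coefficient in SI units.
#' @export
body_translational_drag <- function(body, fluid) {
  3 * pi * eta_si(fluid) * (body$B * 1e-6) * drag_correction_cfb(body)
}

#' @rdname body_translational_drag
#' @export
body_rotational_drag <- function(body, fluid) {
  e <- body$e
  a <- body$B / 2 * 1e-6
  if (e < 1e-4) return(8 * pi * eta_si(fluid) * a^3 / (1 + 0.9 * e^2))
  (32 / 3) * pi * eta_si(fluid) * a^3 * e^3 * (1 - e^2) /
    (2 * e - (1 - e^2) * log((1 + e) / (1 - e)))
}

#' Resistive-force-theory drag coefficients of a slender filament
#'
#' Per-unit-length viscous drag coefficients for motion normal
#' (`c_perp`) and tangential (`c_par`) to a slender rod of length `L` and
#' radius `b`:
#' `c_perp = 4 pi eta / (log(L/b) + 1/2)`,
#' `c_par  = 2 pi eta / (log(L/b) - 1/2)`.
#' For large aspect ratios `c_par / c_perp -> 1/2`.
#'
#' @param L Filament length in um.
#' @param b Filament radius in um, `b < L`.
#' @param fluid A [fluid_medium()].
#' @return A list with `c_perp` and `c_par` in SI units (Pa s).
#' @export
#' @examples
#' slender_drag_coeffs(L = 4.3, b = 0.01, fluid_medium())
slender_drag_coeffs <- function(L, b, fluid) {
  stopifnot(is.numeric(L), is.numeric(b))
  if (!(b > 0) || b >= L)
    stop("slender_drag_coeffs: need 0 < b < L", call. = FALSE)
  lg <- log(L / b)
  if (lg <= 0.5)
    stop("slender_drag_coeffs: aspect ratio too small for the slender limit",
         call. = FALSE)
  list(c_perp = 4 * pi * eta_si(fluid) / (lg + 0.5),
       c_par = 2 * pi * eta_si(fluid) / (lg - 0.5))
}

#' Polar radius of a prolate spheroid
#'
#' `r(theta) = (W/2) / sqrt(1 - (e cos(theta))^2)` with the origin midway
#' between the foci; `r(0) = B/2` and `r(pi/2) = W/2`.
#'
#' @param theta Polar angle(s) in `[0, pi]`.
#' @param body A [spheroid_body()].
#' @return Radius in um (vectorised over `theta`).
#' @export
spheroid_radius <- function(theta, body) {
  stopifnot(inherits(body, "spheroid_body"))
  (body$W / 2) / sqrt(1 - (body$e * cos(theta))^2)
}

# d r / d theta, used by the surface integrals
spheroid_radius_prime <- function(theta, body) {
  e <- body$e
  -(body$W / 2) * e^2 * cos(theta) * sin(theta) /
    (1 - (e * cos(theta))^2)^1.5
}

#' Surface area of a prolate spheroid
#'
#' `S = (pi W^2 / 2) * (1 + asin(e) / (e sqrt(1 - e^2)))`, reducing to
#' `pi W^2` for a sphere of diameter `W`. A series replaces the 0/0 form
#' for `e < 1e-6`.
#'
#' @param body A [spheroid_body()].
#' @return Surface area in um^2.
#' @export
#' @examples
#' surface_area(spheroid_body(70, 27.5))  # ~5.03e3 um^2
surface_area <- function(body) {
  stopifnot(inherits(body, "spheroid_body"))
  e <- body$e
  W <- body$W
  if (e < 1e-6) return(pi * W^2 * (1 + e^2 / 3))
  (pi * W^2 / 2) * (1 + asin(e) / (e * sqrt(1 - e^2)))
}

#' Tangential geometric moment of a prolate spheroid
#'
#' The purely geometric factor
#' `I_t = 2 pi * integral(0..pi) [(r sin(theta))^2 -
#'   r r' sin(theta) cos(theta)] d theta`
#' that converts a uniform tangential surface stress into a net propulsive
#' force. For a sphere of radius `R`, `I_t = pi^2 R^2`.
#'
#' @param body A [spheroid_body()].
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#' @return `I_t` in um^2.
#' @export
tangential_moment <- function(body, rel_tol = 1e-10) {
  stopifnot(inherits(body, "spheroid_body"))
  f <- function(th) {
    r <- spheroid_radius(th, body)
    rp <- spheroid_radius_prime(th, body)
    (r * sin(th))^2 - r * rp * sin(th) * cos(th)
  }
  res <- stats::integrate(f, 0, pi, rel.tol = rel_tol, abs.tol = 1e-10,
                          subdivisions = 400L)
  if (res$message != "OK")
    stop("tangential_moment: quadrature did not converge (", res$message,
         ")", call. = FALSE)
  2 * pi * res$value
}
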