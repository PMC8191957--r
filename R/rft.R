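#' Helical flagellar filament
#'
#' A prokaryotic flagellar filament idealised as a rigid helix of contour
#' length `L`, pitch `lam`, helix radius `h` and filament radius `b`. The
#' pitch angle is `theta = atan(2 pi h / lam)`.
#'
#' @param L Contour length in um.
#' @param lam Helix pitch (wavelength) in um.
#' @param h Helix radius in um.
#' @param b Filament radius in um (default 0.01, i.e. a 0.02 um thick
#'   filament, the typical value for prokaryotes; thicker values mimic a
#'   flagellar bundle).
#' @return An object of class `"helical_flagellum"` with derived `theta`.
#' @export
#' @examples
#' helical_flagellum(L = 8.3, lam = 2.37, h = 0.38)
helical_flagellum <- function(L, lam, h, b = 0.01) {
  stopifnot(L > 0, lam > 0, h > 0, b > 0)
  theta <- atan(2 * pi * h / lam)
  structure(list(L = L, lam = lam, h = h, b = b, theta = theta),
            class = "helical_flagellum")
}

#' Resistance coefficients of a rotating helical filament
#'
#' Resistive-force theory for a rigid helix moving axially at speed `U` and
#' rotating at rate `omega` about its axis gives a symmetric 2x2 resistance
#' matrix with entries
#' `f11 = (c_par cos^2 theta + c_perp sin^2 theta) L`,
#' `f12 = (c_perp - c_par) sin(theta) cos(theta) h L`,
#' `f22 = (c_perp cos^2 theta + c_par sin^2 theta) h^2 L`.
#' Axial thrust and torque are `-(f11 U + f12 w)` and `-(f12 U + f22 w)`
#' where `w` is the rotation rate relative to the fluid.
#'
#' @param flag A [helical_flagellum()].
#' @param fluid A [fluid_medium()].
#' @param theta Pitch angle override in rad (defaults to the helix's own).
#' @return A list with `f11` (N s/m), `f12` (N s), `f22` (N s m), all SI.
#' @export
filament_resistance <- function(flag, fluid, theta = flag$theta) {
  stopifnot(inherits(flag, "helical_flagellum"))
  cc <- slender_drag_coeffs(flag$L, flag$b, fluid)
  L <- flag$L * 1e-6
  h <- flag$h * 1e-6
  st <- sin(theta); ct <- cos(theta)
  list(f11 = (cc$c_par * ct^2 + cc$c_perp * st^2) * L,
       f12 = (cc$c_perp - cc$c_par) * st * ct * h * L,
       f22 = (cc$c_perp * ct^2 + cc$c_par * st^2) * h^2 * L)
}

#' Thrust-torque coupling ratio of a helix
#'
#' The dimensionless ratio `f12^2 / (f11 f22)` as a function of the pitch
#' angle `theta` and the drag anisotropy `gamma = c_par / c_perp`:
#' `(1 - gamma)^2 sin^2 cos^2 / ((gamma cos^2 + sin^2)(gamma sin^2 + cos^2))`.
#' It is maximised at `theta = pi/4`, where it equals
#' `((1 - gamma) / (1 + gamma))^2` — at the customary `gamma = 1/2`, the
#' bound is 1/9.
#'
#' @param theta Pitch angle(s) in `[0, pi/2]` (rad).
#' @param gamma Drag ratio `c_par / c_perp` in (0, 1].
#' @return The coupling ratio (vectorised over `theta`).
#' @export
#' @examples
#' coupling_ratio(pi / 4, 0.5)      # = 1/9
#' coupling_ratio_max(0.5)          # = 1/9
coupling_ratio <- function(theta, gamma) {
  stopifnot(all(theta >= 0), all(theta <= pi / 2), gamma > 0, gamma <= 1)
  s2 <- sin(theta)^2
  c2 <- cos(theta)^2
  (1 - gamma)^2 * s2 * c2 / ((gamma * c2 + s2) * (gamma * s2 + c2))
}

#' @rdname coupling_ratio
#' @export
coupling_ratio_max <- function(gamma) ((1 - gamma) / (1 + gamma))^2

#' Solve the swimming problem for a flagellated prokaryote
#'
#' Force and torque balance for a cell body (drag coefficients `b11`, `b22`)
#' rotating a helical filament (resistances `f11`, `f12`, `f22`) at angular
#' rate `omega` relative to the body gives a 2x2 linear system whose
#' solution is the swimming speed `U` and the body counter-rotation `Omega`;
#' the motor torque is `Tm = f12 U + f22 (Omega + omega)`. The returned
#' values are signed exactly as the balance equations dictate (the speed is
#' negative for the chosen axis orientation); magnitudes are what published
#' plots show.
#'
#' @param omega Filament rotation rate relative to the body, rad/s.
#' @param fil List with `f11`, `f12`, `f22` (SI), from
#'   [filament_resistance()].
#' @param body_coeffs Numeric vector `c(b11, b22)` in SI, e.g. from
#'   [body_translational_drag()] and [body_rotational_drag()].
#' @return A list of class `"swim_solution"` with `U` (m/s), `Omega`
#'   (rad/s), `Tm` (N m).
#' @export
solve_swimming <- function(omega, fil, body_coeffs) {
  b11 <- body_coeffs[[1]]
  b22 <- body_coeffs[[2]]
  stopifnot(b11 > 0, b22 > 0, fil$f11 > 0, fil$f22 > 0)
  if (omega == 0)
    return(structure(list(U = 0, Omega = 0, Tm = 0),
                     class = "swim_solution"))
  A <- matrix(c(b11 + fil$f11, fil$f12,
                fil$f12, b22 + fil$f22), 2, 2, byrow = TRUE)
  d <- det(A)
  if (!is.finite(d) || abs(d) < .Machine$double.xmin * 1e4)
    stop("solve_swimming: singular resistance system", call. = FALSE)
  sol <- solve(A, -c(fil$f12, fil$f22) * omega)
  U <- sol[1]
  Omega <- sol[2]
  Tm <- fil$f12 * U + fil$f22 * (Omega + omega)
  structure(list(U = U, Omega = Omega, Tm = Tm), class = "swim_solution")
}

#' Speed per unit motor torque
#'
#' `speed_per_torque_exact()` is the closed form
#' `U / Tm = f12 / (f12^2 - f22 (b11 + f11))` — independent of the body's
#' rotational drag `b22`. `speed_per_torque_simplified()` drops the `f12^2`
#' term (justified by the 1/9 coupling bound), giving
#' `|U / Tm| ~ f12 / (f22 (b11 + f11))`; it under-estimates the exact
#' magnitude by at most a factor `1 / (1 - 1/9) = 1.125` when
#' `c_par/c_perp = 1/2`.
#'
#' @param fil Filament resistances (SI), from [filament_resistance()].
#' @param b11 Body translational drag (SI).
#' @return `U/Tm` in SI ((m/s) / (N m)); the exact form is signed, the
#'   simplified form is a magnitude.
#' @export
speed_per_torque_exact <- function(fil, b11) {
  fil$f12 / (fil$f12^2 - fil$f22 * (b11 + fil$f11))
}

#' @rdname speed_per_torque_exact
#' @export
speed_per_torque_simplified <- function(fil, b11) {
  fil$f12 / (fil$f22 * (b11 + fil$f11))
}

#' Morphological factor linking speed to motor torque
#'
#' With the pitch angle fixed at `pi/4` and slender-filament drag
#' coefficients, the speed-torque relation collapses to `U = Tm / (eta
#' xi^2)` with the geometry-only factor
#' `xi^2 = 9 pi h (B C_FB(W/B) + L / (log(L/b) + 1/2))`.
#' The `+ 1/2` offset comes from writing the tangential coefficient as
#' `c_perp / 2`; deriving via `c_par` directly would give `- 1/2`
#' (`variant = "parallel"`), a documented alternative that changes the
#' result only logarithmically.
#'
#' @param body A [spheroid_body()].
#' @param flag A [helical_flagellum()] (only `L`, `h`, `b` are used; the
#'   pitch angle is fixed at pi/4 in this reduction).
#' @param variant `"perpendicular"` (the printed form, log + 1/2) or
#'   `"parallel"` (log - 1/2).
#' @return `xi^2` in um^2.
#' @export
#' @examples
#' morphological_factor(spheroid_body(2.6, 0.43),
#'                      helical_flagellum(4.3, 2.1, 0.22))  # ~9.36 um^2
morphological_factor <- function(body, flag,
                                 variant = c("perpendicular", "parallel")) {
  variant <- match.arg(variant)
  off <- if (variant == "perpendicular") 0.5 else -0.5
  lg <- log(flag$L / flag$b)
  if (lg + off <= 0)
    stop("morphological_factor: filament not slender enough", call. = FALSE)
  9 * pi * flag$h *
    (body$B * drag_correction_cfb(body) + flag$L / (lg + off))
}

#' Estimate the flagellar motor torque of a prokaryote record
#'
#' Inverts the speed-torque relation `U = Tm / (eta xi^2)`: the effective
#' motor torque is `Tm = U * eta * xi^2`, which in the working units
#' (um/s, mPa s, um^2) lands directly in pN nm. Records missing any of
#' B, W, L, h, U are skipped with a structured reason, mirroring how
#' published speed-versus-morphology plots include only complete species.
#' Multi-flagellated cells are treated as one effective helix (bundling),
#' so N is not consulted.
#'
#' @param rec An [organism_record()].
#' @param fluid A [fluid_medium()].
#' @param policy A [collapse_policy()].
#' @param b Filament radius in um; 0.01 um (2b = 0.02 um) unless overridden.
#' @return An [estimate_result()] with kind `"Tm"` in pN nm.
#' @export
estimate_motor_torque <- function(rec, fluid = fluid_medium(),
                                  policy = collapse_policy(), b = 0.01) {
  needed <- c("B", "W", "L", "h", "U")
  miss <- needed[vapply(needed, function(f) is.null(rec[[f]]), logical(1))]
  if (length(miss))
    return(estimate_result(rec$species, "Tm", units = "pN nm",
                           skip_reason = paste("missing:",
                                               paste(miss, collapse = ", "))))
  v <- vapply(needed, function(f) field_value(rec, f, policy), numeric(1))
  lam <- if (is.null(rec$lam)) 4 * pi * v[["h"]]  # placeholder: theta = pi/4
         else field_value(rec, "lam", policy)
  body <- spheroid_body(v[["B"]], v[["W"]])
  flag <- helical_flagellum(v[["L"]], lam, v[["h"]], b = b)
  xi_sq <- morphological_factor(body, flag)
  Tm <- v[["U"]] * fluid$eta * xi_sq
  imput <- character(0)
  for (f in needed) {
    rule <- attr(collapse_quantity(rec[[f]], policy), "rule")
    if (rule != "point") imput <- c(imput, sprintf("%s collapsed by %s", f, rule))
  }
  estimate_result(rec$species, "Tm", value = Tm, units = "pN nm",
                  inputs = c(v, xi_sq_um2 = xi_sq, eta = fluid$eta),
                  imputations = imput)
}
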