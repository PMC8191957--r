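#' Ciliary array of a ciliate
#'
#' How densely a ciliate is covered in cilia, specified by any one of: the
#' total count `N`, the areal density `kappa` (um^-2), or the
#' nearest-neighbour spacing `d` (um, with `kappa ~ 1/d^2`). When both `N`
#' and `kappa` are given, consistency `N = kappa * S` is checked against the
#' body surface area and a warning is emitted on disagreement.
#'
#' @param N Total cilia count.
#' @param kappa Cilia per unit area, um^-2.
#' @param d Inter-cilium spacing, um.
#' @param ell Cilium length, um (informational).
#' @return An object of class `"ciliary_array"`.
#' @export
ciliary_array <- function(N = NULL, kappa = NULL, d = NULL, ell = NULL) {
  for (v in list(N, kappa, d, ell))
    if (!is.null(v) && v <= 0)
      stop("ciliary_array: all fields must be positive when present",
           call. = FALSE)
  structure(list(N = N, kappa = kappa, d = d, ell = ell),
            class = "ciliary_array")
}

#' Number of cilia on a cell
#'
#' Resolves the cilia count from whichever field is available: `N` directly,
#' `kappa * S`, or `S / d^2` (the spacing rule `kappa ~ 1/d^2`). The route
#' used is recorded for provenance. Precedence: N, then kappa, then d.
#'
#' @param array A [ciliary_array()].
#' @param S Body surface area in um^2, from [surface_area()].
#' @return A list with `N` and `route` (one of `"N"`, `"kappa"`, `"d"`), or
#'   `NULL` when the array carries no information.
#' @export
#' @examples
#' cilia_count(ciliary_array(d = 2), S = 100)  # N = 25
cilia_count <- function(array, S) {
  stopifnot(inherits(array, "ciliary_array"), S > 0)
  if (!is.null(array$N)) {
    if (!is.null(array$kappa) &&
        abs(array$N - array$kappa * S) > 0.5 * array$N)
      warning("cilia_count: N and kappa*S disagree by more than 50%",
              call. = FALSE)
    return(list(N = array$N, route = "N"))
  }
  if (!is.null(array$kappa)) return(list(N = array$kappa * S,
                                         route = "kappa"))
  if (!is.null(array$d)) return(list(N = S / array$d^2, route = "d"))
  NULL
}

#' Swimming speed under constant tangential surface stress (model A)
#'
#' If the ciliary array exerts a uniform tangential stress `tau` on the
#' fluid, balancing the propulsive force `tau * I_t` against the body drag
#' `3 pi eta B C_FB U` gives `U_tau = tau I_t / (3 pi eta B C_FB)`.
#'
#' @param tau Tangential stress in mPa.
#' @param body A [spheroid_body()].
#' @param fluid A [fluid_medium()].
#' @return Speed in um/s.
#' @export
#' @examples
#' # sphere of radius 100 um, tau = 10 mPa: U = tau * pi * R / (6 eta)
#' speed_constant_stress(10, spheroid_body(200, 200 - 1e-9), fluid_medium())
speed_constant_stress <- function(tau, body, fluid = fluid_medium()) {
  stopifnot(inherits(body, "spheroid_body"))
  # mPa * um^2 / (mPa s * um) = um/s: no unit factor needed
  tau * tangential_moment(body) /
    (3 * pi * fluid$eta * body$B * drag_correction_cfb(body))
}

#' Swimming speed under constant force per cilium (model B)
#'
#' Each of `N` cilia, uniformly distributed over the surface, exerts a
#' constant tangential force `F` on the fluid; the expected total thrust is
#' `F N I_t / S` and the balance gives
#' `U_F = F N I_t / (3 pi eta B S C_FB)`. Identical to model A under
#' `tau = F N / S`.
#'
#' @param F Force per cilium in pN.
#' @param N Number of cilia.
#' @param body A [spheroid_body()].
#' @param fluid A [fluid_medium()].
#' @return Speed in um/s.
#' @export
speed_constant_force <- function(F, N, body, fluid = fluid_medium()) {
  stopifnot(inherits(body, "spheroid_body"), N >= 1)
  # pN / um^2 = Pa = 1000 mPa, hence the factor
  tau_equiv <- 1000 * F * N / surface_area(body)
  speed_constant_stress(tau_equiv, body, fluid)
}

#' Canonical near-uniform squirmer surface-velocity profile
#'
#' The tangential surface slip `u_s(zeta) = tau0 u_hat sqrt((1 - zeta^2) /
#' (tau0^2 - zeta^2))` with `zeta = cos(theta)` and `tau0 = 1/e`, oriented
#' so that positive `u_s` is rearward surface flow (which propels the cell
#' forward). Its magnitude is almost uniform over the surface, equal to
#' `u_hat` at the equator up to the `tau0` geometry factor.
#'
#' @param u_hat Characteristic surface speed in um/s.
#' @param body A [spheroid_body()] with `e > 0`.
#' @return A function of `zeta` in `[-1, 1]`.
#' @export
squirmer_profile <- function(u_hat, body) {
  stopifnot(inherits(body, "spheroid_body"))
  if (body$e <= 0) stop("squirmer_profile: requires e > 0", call. = FALSE)
  tau0 <- 1 / body$e
  function(zeta) tau0 * u_hat * sqrt((1 - zeta^2) / (tau0^2 - zeta^2))
}

#' Squirmer swimming speed from an arbitrary surface-velocity profile
#'
#' The Lorentz reciprocal theorem converts a prescribed tangential surface
#' velocity `u_s(zeta)` on a prolate spheroid into the propulsion speed:
#' `U_s = (tau0 / 2) Int_-1^1 sqrt((1 - zeta^2) / (tau0^2 - zeta^2))
#' u_s(zeta) d zeta`, with `tau0 = 1/e` and `u_s > 0` meaning rearward
#' surface flow (forward swimming positive). The integrand is bounded for
#' `e < 1` and the endpoints contribute no singularity.
#'
#' @param profile A function of `zeta` in `[-1, 1]` returning um/s
#'   (rearward positive), e.g. from [squirmer_profile()].
#' @param body A [spheroid_body()] with `e > 0`.
#' @param rel_tol Quadrature relative tolerance.
#' @return Swimming speed in um/s.
#' @export
squirmer_speed_quadrature <- function(profile, body, rel_tol = 1e-10) {
  stopifnot(is.function(profile), inherits(body, "spheroid_body"))
  if (body$e <= 0)
    stop("squirmer_speed_quadrature: requires e > 0", call. = FALSE)
  tau0 <- 1 / body$e
  f <- function(zeta) sqrt((1 - zeta^2) / (tau0^2 - zeta^2)) * profile(zeta)
  res <- stats::integrate(f, -1, 1, rel.tol = rel_tol, abs.tol = 1e-12,
                          subdivisions = 400L)
  if (res$message != "OK")
    stop("squirmer_speed_quadrature: quadrature failure (", res$message,
         ")", call. = FALSE)
  (tau0 / 2) * res$value
}

#' Squirmer speed for the near-uniform profile (model C closed form)
#'
#' For the canonical profile of [squirmer_profile()] the reciprocal-theorem
#' integral evaluates in closed form:
#' `U_s = (u_hat / e^2) (1 - ((1 - e^2) / e) atanh(e))`.
#' `U_s -> (2/3) u_hat` for a sphere (`e -> 0`) and `U_s -> u_hat` for a
#' needle (`e -> 1`).
#'
#' @param u_hat Characteristic surface speed in um/s.
#' @param e Body eccentricity in (0, 1); values below 1e-4 use the series
#'   `(2/3) + (2/15) e^2`.
#' @return Swimming speed in um/s (vectorised over `e`).
#' @export
#' @examples
#' speed_surface_velocity(1, 0.866)  # ~0.826
speed_surface_velocity <- function(u_hat, e) {
  stopifnot(all(e >= 0), all(e <= 1))
  out <- numeric(length(e))
  small <- e < 1e-4
  out[small] <- u_hat * (2 / 3 + (2 / 15) * e[small]^2)
  ee <- e[!small]
  ee <- pmin(ee, 1 - 1e-12)
  out[!small] <- (u_hat / ee^2) * (1 - ((1 - ee^2) / ee) * atanh(ee))
  out
}

# shared scaffolding for the three per-record ciliary inversions
ciliate_inputs <- function(rec, policy) {
  B <- field_value(rec, "B", policy)
  W <- field_value(rec, "W", policy)
  U <- field_value(rec, "U", policy)
  if (anyNA(c(B, W, U))) {
    miss <- c("B", "W", "U")[is.na(c(B, W, U))]
    return(list(skip = paste("missing:", paste(miss, collapse = ", "))))
  }
  list(body = spheroid_body(B, W), U = U, skip = NULL)
}

collapse_imputations <- function(rec, fields, policy) {
  out <- character(0)
  for (f in fields) {
    if (!is.null(rec[[f]])) {
      rule <- attr(collapse_quantity(rec[[f]], policy), "rule")
      if (rule != "point")
        out <- c(out, sprintf("%s collapsed by %s", f, rule))
    }
  }
  out
}

#' Invert the ciliary propulsion models for an organism record
#'
#' Given a ciliate's observed swimming speed and geometry, each model is
#' inverted for its dynamic parameter:
#' \describe{
#'   \item{`estimate_tau()`}{model A — effective tangential surface stress
#'     `tau = 3 pi eta U B C_FB / I_t`, in mPa.}
#'   \item{`estimate_force_per_cilium()`}{model B — effective force per
#'     cilium `F = 3 pi eta U B S C_FB / (N I_t)`, in pN; `N` resolved via
#'     [cilia_count()] from N, kappa or d.}
#'   \item{`estimate_surface_speed()`}{model C — effective surface speed
#'     `u_hat = U / g(e)` with `g` the closed-form speed ratio of
#'     [speed_surface_velocity()], in um/s.}
#' }
#' Records lacking the required fields are skipped with a reason; a zero
#' observed speed yields a zero estimate with a warning.
#'
#' @param rec An [organism_record()].
#' @param fluid A [fluid_medium()].
#' @param policy A [collapse_policy()].
#' @return An [estimate_result()].
#' @export
estimate_tau <- function(rec, fluid = fluid_medium(),
                         policy = collapse_policy()) {
  inp <- ciliate_inputs(rec, policy)
  if (!is.null(inp$skip))
    return(estimate_result(rec$species, "tau", units = "mPa",
                           skip_reason = inp$skip))
  if (inp$U == 0)
    warning("estimate_tau: observed speed is zero", call. = FALSE)
  tau <- 3 * pi * fluid$eta * inp$U * inp$body$B *
    drag_correction_cfb(inp$body) / tangential_moment(inp$body)
  estimate_result(rec$species, "tau", value = tau, units = "mPa",
                  inputs = c(B = inp$body$B, W = inp$body$W, U = inp$U),
                  imputations = collapse_imputations(rec, c("B", "W", "U"),
                                                     policy))
}

#' @rdname estimate_tau
#' @export
estimate_force_per_cilium <- function(rec, fluid = fluid_medium(),
                                      policy = collapse_policy()) {
  inp <- ciliate_inputs(rec, policy)
  if (!is.null(inp$skip))
    return(estimate_result(rec$species, "F", units = "pN",
                           skip_reason = inp$skip))
  arr <- ciliary_array(
    N = if (is.null(rec$N)) NULL else field_value(rec, "N", policy),
    kappa = if (is.null(rec$kappa)) NULL else field_value(rec, "kappa",
                                                          policy),
    d = if (is.null(rec$d)) NULL else field_value(rec, "d", policy))
  S <- surface_area(inp$body)
  cnt <- cilia_count(arr, S)
  if (is.null(cnt))
    return(estimate_result(rec$species, "F", units = "pN",
                           skip_reason = "missing: one of N, kappa, d"))
  if (inp$U == 0)
    warning("estimate_force_per_cilium: observed speed is zero",
            call. = FALSE)
  # inverse of model B; 1e-3 converts (mPa s * um/s * um * um^2 / um^2) to pN
  F <- 1e-3 * 3 * pi * fluid$eta * inp$U * inp$body$B * S *
    drag_correction_cfb(inp$body) / (cnt$N * tangential_moment(inp$body))
  imput <- collapse_imputations(rec, c("B", "W", "U", "N", "kappa", "d"),
                                policy)
  if (cnt$route != "N")
    imput <- c(imput, sprintf("N = %.4g (from %s)", cnt$N,
                              if (cnt$route == "kappa") "kappa * S"
                              else "S / d^2"))
  estimate_result(rec$species, "F", value = F, units = "pN",
                  inputs = c(B = inp$body$B, W = inp$body$W, U = inp$U,
                             N = cnt$N, S = S),
                  imputations = imput)
}

#' @rdname estimate_tau
#' @export
estimate_surface_speed <- function(rec, policy = collapse_policy()) {
  inp <- ciliate_inputs(rec, policy)
  if (!is.null(inp$skip))
    return(estimate_result(rec$species, "u_hat", units = "um/s",
                           skip_reason = inp$skip))
  if (inp$U == 0)
    warning("estimate_surface_speed: observed speed is zero", call. = FALSE)
  g <- speed_surface_velocity(1, inp$body$e)
  estimate_result(rec$species, "u_hat", value = inp$U / g, units = "um/s",
                  inputs = c(B = inp$body$B, W = inp$body$W, U = inp$U,
                             e = inp$body$e),
                  imputations = collapse_imputations(rec, c("B", "W", "U"),
                                                     policy))
}
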