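# Independent numerical oracles used across the suite. These deliberately
# avoid the code paths they check: closed forms, brute-force line/surface
# integrals, and (where available) pracma's special functions.

# closed forms of the period-averaged wave integrals, obtained by
# elementary integration of the defining expressions
oracle_I1 <- function(a) 1 - 1 / sqrt(1 + a^2)
oracle_I2 <- function(a) 2 - 1 / sqrt(1 + a^2)

# arc-length integral via the complete elliptic integral of the 2nd kind
oracle_Lambda_elliptic <- function(a) {
  m <- a^2 / (1 + a^2)
  (2 / pi) * sqrt(1 + a^2) * pracma::ellipke(m)$e
}

# brute-force drag on a rigid helix: integrate the local anisotropic drag
# law segment by segment for axial speed U [m/s] and rotation rate w [rad/s]
# about the helix axis; returns axial force [N] and axial torque [N m]
helix_drag_bruteforce <- function(L, lam, h, b, fluid, U, w,
                                  n_seg = 20000L) {
  cc <- slender_drag_coeffs(L, b, fluid)
  pitch_per_rad <- lam / (2 * pi) * 1e-6
  hm <- h * 1e-6
  ds_dphi <- sqrt(hm^2 + pitch_per_rad^2)
  Phi <- (L * 1e-6) / ds_dphi
  phi <- (seq_len(n_seg) - 0.5) * Phi / n_seg
  dphi <- Phi / n_seg
  tx <- pitch_per_rad / ds_dphi
  ty <- -hm * sin(phi) / ds_dphi
  tz <- hm * cos(phi) / ds_dphi
  vx <- rep(U, n_seg)
  vy <- -w * hm * sin(phi)
  vz <- w * hm * cos(phi)
  vt <- vx * tx + vy * ty + vz * tz
  fx <- -(cc$c_par * vt * tx + cc$c_perp * (vx - vt * tx))
  fy <- -(cc$c_par * vt * ty + cc$c_perp * (vy - vt * ty))
  fz <- -(cc$c_par * vt * tz + cc$c_perp * (vz - vt * tz))
  ry <- hm * cos(phi)
  rz <- hm * sin(phi)
  list(F = sum(fx) * ds_dphi * dphi,
       T = sum(ry * fz - rz * fy) * ds_dphi * dphi)
}

# brute-force thrust of one wavelength of a planar sine wave: numerical
# integration of the local force balance under the slender-limit premise
# c_perp = 2 c_par; returns pN for the whole flagellum (N flagella,
# n_w waves each)
wave_thrust_bruteforce <- function(wave, geom, fluid, U, n_seg = 20000L) {
  cc <- slender_drag_coeffs(geom$L, geom$b, fluid)
  c_par <- cc$c_par
  c_perp <- 2 * c_par
  lam <- wave$lam * 1e-6
  hm <- wave$h * 1e-6
  cw <- wave$c * 1e-6
  Um <- U * 1e-6
  x <- (seq_len(n_seg) - 0.5) * lam / n_seg
  dx <- lam / n_seg
  yx <- hm * (2 * pi / lam) * cos(2 * pi * x / lam)
  yt <- cw * yx
  dF <- ((c_perp - c_par) * yt * yx - Um * (c_par + c_perp * yx^2)) /
    (1 + yx^2)
  n_w <- if (is.null(geom$n_w)) wave_count(geom$L, wave$lam, wave$h)
         else geom$n_w
  geom$N * n_w * sum(dF) * dx * 1e12
}

# surface area and tangential moment by brute-force quadrature over the
# spheroid surface metric (independent of the closed forms in the package)
surface_area_bruteforce <- function(body) {
  f <- function(th) {
    r <- spheroid_radius(th, body)
    e <- body$e
    rp <- -(body$W / 2) * e^2 * cos(th) * sin(th) /
      (1 - (e * cos(th))^2)^1.5
    r * sin(th) * sqrt(r^2 + rp^2)
  }
  2 * pi * stats::integrate(f, 0, pi, rel.tol = 1e-12)$value
}

random_body <- function() {
  B <- stats::runif(1, 2, 300)
  spheroid_body(B, B * stats::runif(1, 0.1, 0.98))
}

random_helix <- function() {
  helical_flagellum(L = stats::runif(1, 3, 60),
                    lam = stats::runif(1, 1, 30),
                    h = stats::runif(1, 0.05, 3),
                    b = stats::runif(1, 0.005, 0.2))
}

# a random well-formed printed cell together with its quantity object
random_cell <- function() {
  point <- round(stats::runif(1, 0.1, 300), 3)
  sd <- round(stats::runif(1, 0.01, 30), 3)
  lo <- round(point * stats::runif(1, 0.3, 0.9), 3)
  hi <- round(point * stats::runif(1, 1.1, 3), 3)
  form <- sample(c("point", "pm", "range", "max", "point_range",
                   "pm_range", "point_max", "pm_max"), 1)
  q <- switch(form,
    point = quantity(point = point),
    pm = quantity(point = point, sd = sd),
    range = quantity(lo = lo, hi = hi),
    max = quantity(hi = hi, bound_only = TRUE),
    point_range = quantity(point = point, lo = lo, hi = hi),
    pm_range = quantity(point = point, sd = sd, lo = lo, hi = hi),
    point_max = quantity(point = point, hi = hi),
    pm_max = quantity(point = point, sd = sd, hi = hi))
  q
}

expect_quantity_equal <- function(a, b) {
  expect_equal(unclass(a)[c("point", "sd", "lo", "hi", "bound_only")],
               unclass(b)[c("point", "sd", "lo", "hi", "bound_only")])
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "microswim", mustWork = TRUE)
}
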