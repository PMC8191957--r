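water <- fluid_medium()

test_that("filament resistance has the straight-filament and pi/4 limits", {
  flag <- helical_flagellum(L = 10, lam = 5, h = 0.4)
  cc <- slender_drag_coeffs(10, 0.01, water)
  # theta -> 0: pure tangential drag, no coupling
  fil0 <- filament_resistance(flag, water, theta = 0)
  expect_equal(fil0$f12, 0)
  expect_equal(fil0$f11, cc$c_par * 10e-6)
  # theta = pi/4: f11 = f22 / h^2 = (c_par + c_perp) L / 2
  fil4 <- filament_resistance(flag, water, theta = pi / 4)
  expect_equal(fil4$f11, (cc$c_par + cc$c_perp) * 10e-6 / 2)
  expect_equal(fil4$f11, fil4$f22 / (0.4e-6)^2)
  expect_true(fil4$f12 > 0)
})

test_that("resistance matrix agrees with segment-by-segment integration", {
  set.seed(404)
  for (i in 1:5) {
    flag <- random_helix()
    fil <- filament_resistance(flag, water)
    # extract each coefficient from brute-force force/torque evaluations
    tr <- helix_drag_bruteforce(flag$L, flag$lam, flag$h, flag$b, water,
                                U = 1e-6, w = 0, n_seg = 200000L)
    rot <- helix_drag_bruteforce(flag$L, flag$lam, flag$h, flag$b, water,
                                 U = 0, w = 1, n_seg = 200000L)
    expect_equal(abs(tr$F), fil$f11 * 1e-6, tolerance = 1e-6)
    expect_equal(abs(tr$T), fil$f12 * 1e-6, tolerance = 1e-6)
    expect_equal(abs(rot$F), fil$f12, tolerance = 1e-6)
    expect_equal(abs(rot$T), fil$f22, tolerance = 1e-6)
  }
})

test_that("coupling ratio is bounded by ((1-gamma)/(1+gamma))^2 at pi/4", {
  expect_equal(coupling_ratio(0, 0.5), 0)
  expect_equal(coupling_ratio(pi / 2, 0.5), 0)
  expect_equal(coupling_ratio(pi / 4, 0.5), 1 / 9)
  expect_equal(coupling_ratio_max(0.5), 1 / 9)
  # numeric maximisation agrees with the closed form for other anisotropies
  for (gamma in c(0.3, 0.5, 0.7, 0.9)) {
    opt <- stats::optimize(coupling_ratio, c(0, pi / 2), gamma = gamma,
                           maximum = TRUE)
    expect_equal(opt$objective, coupling_ratio_max(gamma), tolerance = 1e-8)
    expect_equal(opt$maximum, pi / 4, tolerance = 1e-4)
  }
  # the Eq-2 coefficients reproduce the closed-form ratio
  set.seed(405)
  for (i in 1:20) {
    flag <- random_helix()
    fil <- filament_resistance(flag, water)
    cc <- slender_drag_coeffs(flag$L, flag$b, water)
    ratio <- fil$f12^2 / (fil$f11 * fil$f22)
    expect_equal(ratio, coupling_ratio(flag$theta, cc$c_par / cc$c_perp),
                 tolerance = 1e-12)
    expect_lt(ratio, 1)
  }
})

test_that("the swimming solution closes force and torque balances", {
  set.seed(406)
  for (i in 1:20) {
    flag <- random_helix()
    body <- random_body()
    fil <- filament_resistance(flag, water)
    bc <- c(body_translational_drag(body, water),
            body_rotational_drag(body, water))
    omega <- stats::runif(1, 10, 1000)
    s <- solve_swimming(omega, fil, bc)
    # total force and torque on the swimmer vanish
    F_flag <- -(fil$f11 * s$U + fil$f12 * (s$Omega + omega))
    F_body <- -bc[1] * s$U
    T_flag <- -(fil$f12 * s$U + fil$f22 * (s$Omega + omega))
    T_body <- -bc[2] * s$Omega
    expect_equal(F_flag + F_body, 0,
                 tolerance = 1e-12 * abs(fil$f11 * s$U))
    expect_equal(T_flag + T_body, 0, tolerance = 1e-12 * abs(s$Tm))
    # the motor torque identity holds by construction
    expect_equal(s$Tm, fil$f12 * s$U + fil$f22 * (s$Omega + omega))
  }
  z <- solve_swimming(0, filament_resistance(random_helix(), water),
                      c(1e-8, 1e-20))
  expect_equal(c(z$U, z$Omega, z$Tm), c(0, 0, 0))
})

test_that("U/Tm matches the closed form and is independent of b22", {
  set.seed(407)
  for (i in 1:100) {
    flag <- random_helix()
    body <- random_body()
    fil <- filament_resistance(flag, water)
    b11 <- body_translational_drag(body, water)
    omega <- stats::runif(1, 10, 1000)
    ratio_ref <- speed_per_torque_exact(fil, b11)
    for (b22 in c(1e-22, 1e-20, 1e-18)) {
      s <- solve_swimming(omega, fil, c(b11, b22))
      expect_equal(s$U / s$Tm, ratio_ref, tolerance = 1e-10)
    }
  }
})

test_that("the simplified speed-per-torque under-estimates by at most 12.5%
           at the customary drag anisotropy", {
  # enforce c_par/c_perp = 1/2 exactly, as in the coupling bound
  set.seed(408)
  for (i in 1:50) {
    theta <- stats::runif(1, 0.05, pi / 2 - 0.05)
    h <- stats::runif(1, 0.05, 3) * 1e-6
    L <- stats::runif(1, 3, 60) * 1e-6
    c_perp <- 2e-3
    c_par <- 1e-3
    fil <- list(
      f11 = (c_par * cos(theta)^2 + c_perp * sin(theta)^2) * L,
      f12 = (c_perp - c_par) * sin(theta) * cos(theta) * h * L,
      f22 = (c_perp * cos(theta)^2 + c_par * sin(theta)^2) * h^2 * L)
    b11 <- stats::runif(1, 1e-9, 1e-7)
    exact <- abs(speed_per_torque_exact(fil, b11))
    simplified <- speed_per_torque_simplified(fil, b11)
    expect_gte(exact / simplified, 1)
    expect_lte(exact / simplified, 1 / (1 - 1 / 9) + 1e-12)
  }
})

test_that("the morphological factor has the printed form and limits", {
  body <- spheroid_body(2.6, 0.43)
  flag <- helical_flagellum(4.3, 2.1, 0.22)
  expect_equal(morphological_factor(body, flag), 9.355607,
               tolerance = 1e-6)
  # h -> 0 kills the factor
  expect_lt(morphological_factor(body, helical_flagellum(4.3, 2.1, 1e-12)),
            1e-10)
  # vanishing filament on a sphere: 9 pi h B (C_FB = 1)
  sphere <- spheroid_body(3, 3)
  tiny <- helical_flagellum(1e-4, 2.1, 0.22, b = 1e-9)
  expect_equal(morphological_factor(sphere, tiny), 9 * pi * 0.22 * 3,
               tolerance = 1e-3)
  # the parallel-coefficient variant shifts only the log offset
  v1 <- morphological_factor(body, flag, "perpendicular")
  v2 <- morphological_factor(body, flag, "parallel")
  expect_gt(v2, v1)
})

test_that("motor torque estimates reproduce the envelope species", {
  recs <- read_records(fixture_path("torque_bound_records.csv"))
  est <- lapply(recs, estimate_motor_torque)
  expect_equal(round(est[[1]]$value, 2), 27.48)
  expect_equal(signif(est[[2]]$value, 4), 1907)
  # linear in U and eta
  hs <- recs[[1]]
  hs$U <- quantity(point = 6.6)
  expect_equal(estimate_motor_torque(hs)$value, 2 * est[[1]]$value)
  thick <- fluid_medium(eta = 1.78)
  expect_equal(estimate_motor_torque(recs[[1]], thick)$value,
               2 * est[[1]]$value)
  # zero speed, zero torque
  hs$U <- quantity(point = 0)
  expect_equal(estimate_motor_torque(hs)$value, 0)
  # incomplete records are skipped with a reason, as in the published plots
  nog <- organism_record("mystery rod", "bacteria", B = 2, U = 20)
  res <- estimate_motor_torque(nog)
  expect_true(is_skipped(res))
  expect_match(res$skip_reason, "W")
})
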