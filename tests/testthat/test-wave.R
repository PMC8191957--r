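water <- fluid_medium()

test_that("wave integrals match their independent closed-form oracles", {
  z <- wave_integrals(0)
  expect_equal(unlist(z), c(Lambda = 1, I1 = 0, I2 = 1))
  for (a in c(0.5, 1, 2 * pi)) {
    w <- wave_integrals(a)
    expect_equal(w$I1, oracle_I1(a), tolerance = 1e-8)
    expect_equal(w$I2, oracle_I2(a), tolerance = 1e-8)
    expect_true(w$Lambda >= 1 && w$I1 >= 0 && w$I1 < 1 &&
                w$I2 >= 1 && w$I2 < 2)
  }
  expect_equal(wave_integrals(2 * pi)$I1, 0.8428, tolerance = 1e-4)
})

test_that("arc-length integral matches the elliptic-integral oracle", {
  for (a in c(0.25, 0.5, 1, 2, pi, 2 * pi))
    expect_equal(wave_integrals(a)$Lambda, oracle_Lambda_elliptic(a),
                 tolerance = 1e-8)
})

test_that("closed-form approximations behave as documented", {
  z <- wave_integrals_approx(0)
  expect_equal(unlist(z), c(Lambda = 1, I1 = 0, I2 = 1))
  ag <- seq(1e-3, 2 * pi, length.out = 500)
  ap <- wave_integrals_approx(ag)
  errL <- abs(ap$Lambda - vapply(ag, function(a) wave_integrals(a)$Lambda,
                                 numeric(1))) /
    vapply(ag, function(a) wave_integrals(a)$Lambda, numeric(1))
  err1 <- abs(ap$I1 - oracle_I1(ag)) / oracle_I1(ag)
  err2 <- abs(ap$I2 - oracle_I2(ag)) / oracle_I2(ag)
  # Lambda and I2 stay below 9%; I1 peaks at ~20.7% at a ~ 2.2 and is
  # ~12.9% at the a = 2 pi endpoint; the speed-relevant ratio I1/I2 stays
  # within 12.5% (worst at a = sqrt(3))
  expect_lt(max(errL), 0.09)
  expect_lt(max(err2), 0.081)
  expect_equal(max(err1), 0.2071, tolerance = 1e-2)
  expect_equal(err1[length(err1)], 0.1293, tolerance = 1e-2)
  ratio_err <- abs(ap$I1 / ap$I2 - oracle_I1(ag) / oracle_I2(ag)) /
    (oracle_I1(ag) / oracle_I2(ag))
  expect_lte(max(ratio_err), 0.125 + 1e-6)
})

test_that("wave count follows arc-length conservation", {
  expect_equal(wave_count(40, 8, 0), 5)
  expect_equal(wave_count(40, 24, 4), 1.350342, tolerance = 1e-6)
  # inverse round trips recover each parameter
  n_w <- wave_count(40, 24, 4)
  expect_equal(impute_wave_parameter(L = 40, n_w = n_w, h = 4)$value, 24,
               tolerance = 1e-7)
  expect_equal(impute_wave_parameter(L = 40, n_w = n_w, lam = 24)$value, 4,
               tolerance = 1e-7)
  expect_equal(impute_wave_parameter(L = 40, lam = 24, h = 4)$value, n_w)
})

test_that("impute_wave_parameter handles degenerate and impossible cases", {
  # n_w = L / lam forces a flat wave
  expect_equal(impute_wave_parameter(L = 40, n_w = 40 / 24, lam = 24)$value,
               0, tolerance = 1e-6)
  # too many waves for the available arc length: no physical amplitude
  expect_error(impute_wave_parameter(L = 40, n_w = 5, lam = 24),
               class = "microswim_impute_error")
  expect_error(impute_wave_parameter(L = 40, lam = 24, h = 4, n_w = 1),
               "exactly one")
})

test_that("net thrust matches brute-force integration and balances", {
  body <- spheroid_body(10, 6)
  geom <- flagellate_geometry(body, N = 2, L = 40, b = 0.2)
  wave <- planar_wave(lam = 24, h = 4, f = 35)
  for (U in c(0, 60, 150)) {
    expect_equal(net_thrust(wave, geom, water, U),
                 wave_thrust_bruteforce(wave, geom, water, U),
                 tolerance = 1e-8)
  }
  # positive at rest, zero at the body-free balance speed
  expect_gt(net_thrust(wave, geom, water, 0), 0)
  ints <- wave_integrals(wave$a)
  U_free <- wave$c * ints$I1 / ints$I2
  expect_equal(net_thrust(wave, geom, water, U_free), 0,
               tolerance = 1e-10)
})

test_that("predicted speed balances thrust against body drag", {
  rec <- organism_record("model flagellate", "flagellate",
                         B = 10, W = 2, N = 1, L = 40, lam = 24, h = 4,
                         f = 35)
  est <- predict_speed(rec, "exact")
  U <- est$value
  body <- spheroid_body(10, 2)
  geom <- flagellate_geometry(body, N = 1, L = 40, b = 0.2)
  wave <- planar_wave(24, 4, 35)
  drag_pN <- 3 * pi * water$eta * U * 10 *
    drag_correction_cfb(body) * 1e-3
  expect_equal(net_thrust(wave, geom, water, U), drag_pN,
               tolerance = 1e-8)
})

test_that("the printed closed-form speed reproduces its worked value", {
  rec <- organism_record("model flagellate", "flagellate",
                         B = 10, W = 2, N = 1, L = 40, lam = 24, h = 4,
                         f = 35)
  expect_equal(predict_speed(rec, "approx")$value, 149.0, tolerance = 1e-3)
  expect_equal(predict_speed(rec, "exact")$value, 123.63, tolerance = 1e-4)
  # flat wave produces no motion
  flat <- organism_record("flat", "flagellate", B = 10, W = 2, N = 1,
                          L = 40, lam = 24, h = 1e-9, f = 35)
  expect_lt(predict_speed(flat, "approx")$value, 1e-10)
  # body-free limit: U -> lam f I1 / I2
  tiny_body <- organism_record("tiny", "flagellate", B = 1e-4, W = 1e-5,
                               N = 1, L = 40, lam = 24, h = 4, f = 35)
  ints <- wave_integrals(2 * pi * 4 / 24)
  expect_equal(predict_speed(tiny_body, "exact")$value,
               24 * 35 * ints$I1 / ints$I2, tolerance = 1e-4)
  a <- 2 * pi * 4 / 24
  expect_equal(predict_speed(tiny_body, "approx")$value,
               (2 * pi^2 * 16 * 35 / 24) / (1 + 4 * pi^2 * 16 / 576),
               tolerance = 1e-4)
})

test_that("predicted speed stays below the wave speed and is monotone", {
  set.seed(409)
  for (i in 1:20) {
    lam <- stats::runif(1, 5, 50)
    h <- stats::runif(1, 0.05, 0.95) * lam / (2 * pi) * stats::runif(1, 0.5, 6)
    h <- min(h, 0.99 * lam)  # keep h/lam < 1
    f <- stats::runif(1, 5, 80)
    B <- stats::runif(1, 3, 60)
    rec <- organism_record("r", "flagellate", B = B, W = 0.5 * B, N = 2,
                           L = stats::runif(1, 20, 80), lam = lam, h = h,
                           f = f)
    for (mode in c("exact", "approx")) {
      U <- suppressWarnings(predict_speed(rec, mode)$value)
      expect_lt(U, lam * f)
      expect_gt(U, 0)
    }
  }
  # more flagella swim faster; bigger bodies swim slower (fixed aspect)
  base <- function(N, B) {
    rec <- organism_record("r", "flagellate", B = B, W = 0.5 * B, N = N,
                           L = 40, lam = 24, h = 4, f = 35)
    predict_speed(rec, "exact")$value
  }
  expect_gt(base(4, 10), base(1, 10))
  expect_gt(base(1, 5), base(1, 20))
})

test_that("exact and approximate modes agree within the propagated budget", {
  # the approximation overshoots I1 (<= 20.8%), undershoots I2, and drops
  # the arc-length factor Lambda from the body term, so the ratio
  # approx/exact lies in [1, 1.208 * Lambda(a)]
  set.seed(410)
  for (i in 1:20) {
    lam <- stats::runif(1, 10, 40)
    h <- stats::runif(1, 0.02, 0.3) * lam
    rec <- organism_record("r", "flagellate", B = stats::runif(1, 5, 30),
                           W = NULL, N = 1, L = stats::runif(1, 30, 80),
                           lam = lam, h = h, f = 30)
    ratio <- predict_speed(rec, "approx")$value /
      predict_speed(rec, "exact")$value
    Lam <- wave_integrals(2 * pi * h / lam)$Lambda
    expect_gte(ratio, 1 - 1e-10)
    expect_lte(ratio, 1.208 * Lam)
  }
})

test_that("spermatozoon records use single-flagellum defaults", {
  # a bull-like sperm: W and N forced by group conventions when absent
  rec <- organism_record("sperm x", "spermatozoon", B = 8.87,
                         L = 54, lam = 35, h = 8, f = 20.57)
  est <- predict_speed(rec, "exact")
  expect_false(is_skipped(est))
  expect_match(paste(est$imputations, collapse = " "), "0.47")
  expect_equal(est$inputs[["N"]], 1)
  expect_equal(est$inputs[["W"]], 0.47 * 8.87)
  # prediction lands in the physiological range (tens of um/s)
  expect_gt(est$value, 10)
  expect_lt(est$value, 700)
  # one missing wave parameter is recovered through the wave-count relation
  rec2 <- organism_record("sperm y", "spermatozoon", B = 8.87, W = 4.74,
                          L = 54, h = 8, n_w = 1, f = 20.57)
  est2 <- predict_speed(rec2, "exact")
  expect_false(is_skipped(est2))
  expect_match(paste(est2$imputations, collapse = " "), "lam")
  # under-determined wave: skipped with a reason
  rec3 <- organism_record("sperm z", "spermatozoon", B = 8.87, W = 4.74,
                          L = 54, h = 8, f = 20.57)
  expect_true(is_skipped(predict_speed(rec3, "exact")))
})
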