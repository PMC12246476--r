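test_that("signal-to-concentration conversion is linear and flags excursions", {
  cur <- progress_curve(times = 0:4, signal = c(100, 150, 200, 250, 300),
                        substrate_0 = 250, enzyme_0 = 0.5,
                        condition_label = "pH7.5")
  cal <- calibration_line(slope = 2, intercept = 100,
                          valid_range = c(0, 150), condition_label = "pH7.5")
  conv <- signal_to_concentration(cur, cal)
  expect_equal(conv$signal, c(0, 25, 50, 75, 100))
  expect_equal(conv$units, "uM")
  expect_false(any(conv$flagged))

  # condition mismatch refused
  other <- calibration_line(2, 100, condition_label = "pH6.0")
  expect_error(signal_to_concentration(cur, other), "does not match")

  # signal below the intercept maps to negative concentration, flagged
  low <- progress_curve(0:4, c(90, 95, 100, 105, 110), 250, 0.5, "pH7.5")
  conv2 <- signal_to_concentration(low, cal)
  expect_lt(conv2$signal[1], 0)
  expect_true(conv2$flagged[1])
})

test_that("initial rate of an exact line is the slope with zero SE", {
  tt <- seq(0, 40, by = 5)
  cur <- progress_curve(tt, 0.5 * tt, substrate_0 = 1000, enzyme_0 = 0.5,
                        units = "uM")
  r <- initial_rate(cur)
  expect_equal(r$rate, 0.5, tolerance = 1e-12)
  expect_equal(r$se, 0, tolerance = 1e-10)
})

test_that("initial rate from a noiseless depletion curve matches the
           windowed-regression oracle", {
  mm <- mm_params(2.1, 713, 0.5)
  cal <- calibration_line(2, 100, c(0, 400), "pH7.5")
  cur <- gen_progress_curves(mm, 250, cal, dead_time = 25, interval = 5)[[1]]
  r <- initial_rate(signal_to_concentration(cur, cal))

  # oracle: independent RK4 integration of the depletion ODE, same window
  # policy applied by hand
  tt <- 25 + 5 * (0:59)
  P_oracle <- rk4_mm_product(2.1, 713, 250, tt, dt = 0.005)
  inside <- P_oracle <= 0.1 * 250
  slope_oracle <- unname(coef(lm(P_oracle[inside] ~ tt[inside]))[2])
  expect_equal(r$rate, slope_oracle, tolerance = 1e-4)

  # curvature bound: the window-average slope lies between the
  # instantaneous rates at the window ends
  v <- function(S) 2.1 * S / (713 + S)
  expect_gt(r$rate, v(250 - max(P_oracle[inside])))
  expect_lt(r$rate, v(250))
  # and is close to the rate at the window midpoint substrate level
  S_mid <- 250 - mean(range(P_oracle[inside]))
  expect_equal(r$rate, v(S_mid), tolerance = 0.01)
})

test_that("initial rate under 1% noise stays within a few SE of the
           noiseless estimate", {
  mm <- mm_params(2.1, 713, 0.5)
  cal <- calibration_line(2, 100, c(0, 400), "pH7.5")
  clean <- gen_progress_curves(mm, 250, cal)[[1]]
  r0 <- initial_rate(signal_to_concentration(clean, cal))
  noisy <- gen_progress_curves(
    mm, 250, cal,
    noise = noise_model("multiplicative_gaussian", 0.01, seed = 11))[[1]]
  r1 <- initial_rate(signal_to_concentration(noisy, cal))
  expect_lt(abs(r1$rate - r0$rate), 4 * r1$se)
  expect_gt(r1$se, 0)
})

test_that("initial rate guards its window and flags non-monotone signal", {
  cur <- progress_curve(seq(0, 45, 5), seq(0, 90, 10), 100, 0.5,
                        units = "uM")
  # only the first few points stay under 10% of 100 uM
  expect_error(initial_rate(cur), "window")
  # gross negative trend triggers the warning flag
  dec <- progress_curve(seq(0, 45, 5), seq(90, 0, -10), 1000, 0.5,
                        units = "uM")
  expect_warning(r <- initial_rate(dec), "non-monotone")
  expect_true(attr(r, "nonmonotone"))
  # uncalibrated input refused
  raw <- progress_curve(0:9, 1:10, 100, 0.5)
  expect_error(initial_rate(raw), "calibrated")
})

test_that("Michaelis-Menten rate law: half-saturation, origin, monotone
           concave saturation", {
  p <- mm_params(2.1, 713, 0.5)
  expect_equal(mm_rate(p, 713), 1.05)
  expect_equal(mm_rate(p, 0), 0)
  expect_equal(mm_rate(p, 250), 0.5451713396, tolerance = 1e-9)
  S <- seq(0, 5000, length.out = 200)
  v <- mm_rate(p, S)
  expect_true(all(diff(v) > 0))          # strictly increasing
  expect_true(all(diff(diff(v)) < 0))    # concave
  expect_equal(mm_rate(p, 1e9), p$v_max, tolerance = 1e-5)
})

test_that("turnover number is v_max over total enzyme", {
  expect_equal(kcat_from_vmax(3.8, 0.5), 7.6)
  # printed homogeneous k_cat 4.3 reflects unrounded v_max; arithmetic
  # from the rounded value gives 4.2, within 5%
  expect_equal(kcat_from_vmax(2.1, 0.5), 4.2)
  expect_equal(kcat_from_vmax(2.1, 0.5), 4.3, tolerance = 0.05)
  expect_equal(kcat_from_vmax(0, 2), 0)
  expect_error(kcat_from_vmax(2.1, 0), "positive")
})

test_that("Michaelis-Menten fit recovers noiseless parameters and flags
           degenerate designs", {
  truth <- mm_params(3.8, 388, 0.5)
  d <- data.frame(S_uM = S_series, rate = mm_rate(truth, S_series))
  f <- fit_michaelis_menten(d, 0.5)
  expect_equal(f$v_max, 3.8, tolerance = 1e-3)
  expect_equal(f$K_M, 388, tolerance = 1e-3)
  expect_equal(f$k_cat, f$v_max / 0.5, tolerance = 1e-9)
  expect_true(attr(f, "beyond_data"))  # max(S) = 250 < K_M

  # random-parameter noiseless recovery (oracle equivalence)
  set.seed(21)
  for (i in 1:10) {
    vt <- runif(1, 0.5, 10); Kt <- runif(1, 20, 300)
    S <- c(10, 25, 60, 150, 400, 1000)
    d <- data.frame(S_uM = S, rate = vt * S / (Kt + S))
    f <- fit_michaelis_menten(d, 0.5)
    expect_equal(f$v_max, vt, tolerance = 1e-3)
    expect_equal(f$K_M, Kt, tolerance = 1e-3)
  }

  # saturated design: rates flat at v_max, K_M collapses to the boundary
  flat <- data.frame(S_uM = c(100, 200, 400), rate = rep(2, 3))
  expect_warning(fb <- fit_michaelis_menten(flat, 0.5), "boundary|identifiable")
  expect_true(attr(fb, "boundary"))

  expect_error(fit_michaelis_menten(
    data.frame(S_uM = c(1, 2), rate = c(0.1, 0.2)), 0.5), "3 distinct")
})

test_that("replicate pooling produces means, SEMs and counts", {
  rates <- data.frame(S_uM = rep(c(10, 20), each = 3),
                      rate = c(1, 1.2, 1.1, 2, 2.2, 2.1))
  p <- pool_rates(rates)
  expect_equal(p$S_uM, c(10, 20))
  expect_equal(p$rate, c(1.1, 2.1), tolerance = 1e-12)
  expect_equal(p$n, c(3L, 3L))
  expect_equal(p$rate_se[1], sd(c(1, 1.2, 1.1)) / sqrt(3), tolerance = 1e-12)
})

test_that("rate measurements can feed the fit directly", {
  truth <- mm_params(2, 100, 0.5)
  ms <- lapply(c(20, 50, 150, 400), function(S)
    rate_measurement(S, mm_rate(truth, S)))
  f <- fit_michaelis_menten(ms, 0.5)
  expect_equal(f$v_max, 2, tolerance = 1e-3)
  expect_equal(f$K_M, 100, tolerance = 1e-3)
})
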