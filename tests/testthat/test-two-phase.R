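ref <- btl2_reference_params()

test_that("rate ratio: degenerate phases give exactly 1, reference set
           gives ~2.5 at 250 uM", {
  # no dense phase
  p0 <- two_phase_params(0, 73000, 4.3, 713, 6.9, 334)
  expect_equal(rate_ratio(p0, c(0, 50, 250, 1e4)), rep(1, 4),
               tolerance = 1e-12)
  # indistinguishable phases
  pid <- two_phase_params(0.2, 1, 4.3, 713, 4.3, 713)
  expect_equal(rate_ratio(pid, c(0, 50, 250, 1e4)), rep(1, 4),
               tolerance = 1e-12)
  # reference parameter set at 250 uM substrate: ~2.5-fold enhancement
  expect_equal(rate_ratio(ref, 250), 2.52329897, tolerance = 1e-8)
})

test_that("rate ratio is monotone in kcat_II, K_E and KM_eff_II", {
  S <- 100
  r_k <- vapply(seq(1, 20, length.out = 15), function(k)
    rate_ratio(two_phase_params(1e-4, 1e4, 4.3, 713, k, 334), S), 0)
  expect_true(all(diff(r_k) > 0))
  r_E <- vapply(10^seq(2, 5, length.out = 15), function(KE)
    rate_ratio(two_phase_params(1e-4, KE, 4.3, 713, 6.9, 334), S), 0)
  expect_true(all(diff(r_E) > 0))
  r_K <- vapply(seq(50, 2000, length.out = 15), function(K)
    rate_ratio(two_phase_params(1e-4, 1e4, 4.3, 713, 6.9, K), S), 0)
  expect_true(all(diff(r_K) < 0))
})

test_that("dense/dilute term structure of the rate ratio matches the
           product-partition equation", {
  set.seed(33)
  for (i in 1:20) {
    p <- two_phase_params(
      phi_D = 10^runif(1, -5, -1), K_E = 10^runif(1, 0, 5),
      kcat_I = runif(1, 0.5, 10), KM_I = runif(1, 100, 1000),
      kcat_II = runif(1, 0.5, 20), KM_II = runif(1, 50, 800))
    S <- runif(1, 0, 1000)
    xi <- xi_dilution(p$K_E, p$phi_D)
    dilute_term <- xi * (1 - p$phi_D)
    dense_term <- rate_ratio(p, S) - dilute_term
    expect_equal(dense_term / dilute_term, product_partition_ratio(p, S),
                 tolerance = 1e-9)
  }
})

test_that("product partitioning: limits, reference values, monotone
           fraction", {
  p0 <- two_phase_params(1e-12, 73000, 4.3, 713, 6.9, 334)
  expect_lt(product_partition_ratio(p0, 100), 1e-5)
  expect_equal(product_partition_ratio(ref, Inf), 19.91710684,
               tolerance = 1e-8)
  expect_equal(fraction_product_dense(ref, Inf), 0.9521922411,
               tolerance = 1e-8)
  expect_equal(product_partition_ratio(ref, 250), 32.8427635,
               tolerance = 1e-7)
  expect_equal(fraction_product_dense(ref, 250), 0.9704515856,
               tolerance = 1e-8)
  # symmetric phases: dense fraction reduces to the volume fraction
  psym <- two_phase_params(0.3, 1, 4.3, 713, 4.3, 713)
  expect_equal(fraction_product_dense(psym, 100), 0.3, tolerance = 1e-12)
  # monotone increasing in K_E and phi_D
  f_E <- vapply(10^seq(1, 5, length.out = 12), function(KE)
    fraction_product_dense(
      two_phase_params(1e-4, KE, 4.3, 713, 6.9, 334), 100), 0)
  expect_true(all(diff(f_E) > 0))
  f_phi <- vapply(10^seq(-6, -1, length.out = 12), function(ph)
    fraction_product_dense(
      two_phase_params(ph, 1e3, 4.3, 713, 6.9, 334), 100), 0)
  expect_true(all(diff(f_phi) > 0))
  expect_true(all(f_E > 0 & f_E < 1))
})

test_that("heterogeneous rate composes the ratio with the homogeneous law", {
  hom <- mm_params(2.15, 713, 0.5)  # k_cat = 4.3 = ref kcat_I
  expect_equal(heterogeneous_rate(ref, 250, hom),
               rate_ratio(ref, 250) * mm_rate(hom, 250), tolerance = 1e-12)
  expect_equal(heterogeneous_rate(ref, 0, hom), 0)
  p0 <- two_phase_params(0, 73000, 4.3, 713, 6.9, 334)
  expect_equal(heterogeneous_rate(p0, 100, hom), mm_rate(hom, 100),
               tolerance = 1e-12)
  bad <- mm_params(3, 500, 0.5)
  expect_error(heterogeneous_rate(ref, 250, bad), "disagree")
})

test_that("dense-phase constants are recovered exactly from noiseless
           ratios", {
  rt <- gen_ratio_dataset(ref, S_series)
  f <- fit_dense_phase_constants(rt, ref$phi_D, ref$K_E, ref$kcat_I,
                                 ref$KM_I)
  expect_equal(f$kcat_II, 6.9, tolerance = 1e-3)
  expect_equal(f$KM_eff_II, 334, tolerance = 1e-3)
  expect_true(f$converged)
  expect_false(f$exact_interpolation)

  # random-truth recovery (oracle-exact inverse of rate_ratio)
  set.seed(55)
  for (i in 1:10) {
    p <- two_phase_params(1.7e-4, 73000, 4.3, 713,
                          kcat_II = runif(1, 2, 20),
                          KM_II = runif(1, 100, 900))
    rt <- gen_ratio_dataset(p, c(S_series, 500, 1000))
    f <- fit_dense_phase_constants(rt, p$phi_D, p$K_E, p$kcat_I, p$KM_I)
    expect_equal(f$kcat_II, p$kcat_II, tolerance = 1e-3)
    expect_equal(f$KM_eff_II, p$KM_eff_II, tolerance = 1e-3)
  }
})

test_that("two-point fits interpolate exactly but are flagged; vanishing
           dense phase is non-identifiable", {
  rt2 <- gen_ratio_dataset(ref, c(62.5, 250))
  expect_warning(f2 <- fit_dense_phase_constants(
    rt2, ref$phi_D, ref$K_E, ref$kcat_I, ref$KM_I), "interpolation")
  expect_true(f2$exact_interpolation)
  expect_lt(max(abs(f2$residuals)), 1e-6)

  p0 <- two_phase_params(1e-15, 1, 4.3, 713, 6.9, 334)
  rt0 <- gen_ratio_dataset(p0, S_series)
  expect_true(all(abs(rt0$ratio - 1) < 1e-10))
  expect_warning(f0 <- fit_dense_phase_constants(
    rt0, 1e-15, 1, 4.3, 713), "identifiable")
  expect_true(f0$non_identifiable)
  expect_true(is.na(f0$kcat_II))
})

test_that("equilibrium closure ties the activity coefficient to the
           substrate partition coefficient", {
  p <- two_phase_params(1e-4, 1e4, 4.3, 713, 6.9, 334, K_S = 2.5)
  expect_equal(p$gamma_S_II * p$K_S, 1, tolerance = 1e-12)
  expect_equal(p$KM_eff_II, p$KM_II)  # K_S cancels under the closure
  expect_error(
    two_phase_params(1e-4, 1e4, 4.3, 713, 6.9, 334, K_S = 2,
                     gamma_S_II = 1, use_equilibrium_closure = TRUE),
    "closure")
  # explicit override: gamma and K_S supplied separately
  po <- two_phase_params(1e-4, 1e4, 4.3, 713, 6.9, 334, K_S = 2,
                         gamma_S_II = 1, use_equilibrium_closure = FALSE)
  expect_equal(po$KM_eff_II, 334 / 2)
})

test_that("transport diagnostics compare diffusion and reaction
           timescales", {
  td <- transport_diagnostics(D = 1.015, diameter = 1, kcat_II = 6.9)
  expect_equal(td$tau_diff, 0.9852216749, tolerance = 1e-9)   # 985 ms
  expect_equal(td$t_react, 0.1449275362, tolerance = 1e-9)    # 145 ms
  expect_match(td$verdict, "same order")
  expect_equal(td$damkohler_like_ratio, td$tau_diff / td$t_react)

  balanced <- transport_diagnostics(D = 4 * 2, diameter = 2, kcat_II = 2)
  expect_equal(balanced$damkohler_like_ratio, 1)

  fast <- transport_diagnostics(D = 4.06, diameter = 1, kcat_II = 6.9)
  expect_equal(fast$tau_diff, 0.2463054187, tolerance = 1e-9)
})
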