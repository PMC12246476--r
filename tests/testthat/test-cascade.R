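test_that("activity profiles validate, interpolate and clamp", {
  expect_error(activity_profile(c(6, 7), c(0.5, 0.9)), "optimum")
  expect_error(activity_profile(c(6, 7), c(0.5, 1.2)), "\\[0, 1\\]")
  prof <- activity_profile(c(6, 7, 8), c(0.4, 1, 0.8))
  expect_equal(eval_activity(prof, 6.5), 0.7)  # linear interpolation
  expect_equal(eval_activity(prof, 7), 1)
  expect_warning(v <- eval_activity(prof, 5), "clamped")
  expect_equal(v, 0.4)
})

test_that("effective constants reduce to raw kcat under flat profiles and
           a homogeneous pH", {
  flat <- activity_profile(c(5, 9), c(1, 1))
  spec <- cascade_spec(btl2_reference_params(), lipase_conc = 0.5,
                       aaox_kcat = 3, aaox_KM = 50, aaox_conc = 0.5,
                       aaox_Kp = 156, solution_pH = 7.5, dense_pH = 7.5,
                       lipase_profile = flat, aaox_profile = flat)
  eff <- effective_rate_constants(spec)
  expect_equal(eff$lipase$kcat_dilute, 4.3)
  expect_equal(eff$lipase$kcat_dense, 6.9)
  expect_equal(eff$aaox$kcat_dilute, 3)
  # enzyme amounts follow the partitioning mass balance
  expect_equal(eff$lipase$conc_dilute, 0.5 * xi_dilution(73000, 1.7e-4),
               tolerance = 1e-12)
  expect_equal(eff$lipase$conc_dense / eff$lipase$conc_dilute, 73000,
               tolerance = 1e-12)
  expect_equal(eff$aaox$conc_dilute * (1 - 1.7e-4) / 0.5,
               client_fraction_dilute(156, 1.7e-4), tolerance = 1e-12)
})

test_that("phase-specific pH attenuates each enzyme's kcat via its
           profile", {
  lip <- activity_profile(c(6, 8), c(0.4, 1))
  spec <- cascade_spec(btl2_reference_params(), lipase_conc = 0.5,
                       aaox_kcat = 3, aaox_KM = 50, aaox_conc = 0.5,
                       aaox_Kp = 156, solution_pH = 6, dense_pH = 8,
                       lipase_profile = lip,
                       aaox_profile = activity_profile(c(6, 8), c(1, 0.3)))
  eff <- effective_rate_constants(spec)
  expect_equal(eff$lipase$kcat_dense, 6.9)        # unattenuated at pH 8
  expect_equal(eff$lipase$kcat_dilute, 4.3 * 0.4) # attenuated at pH 6
  expect_equal(eff$aaox$kcat_dilute, 3)           # oxidase optimum at 6
  expect_equal(eff$aaox$kcat_dense, 3 * 0.3)
})

test_that("cascade simulation conserves moles and honors degenerate
           limits", {
  spec <- mimic_cascade_spec(6)
  tr <- simulate_cascade(spec, CB_0 = 500, t_grid = seq(0, 600, 10))
  tot <- tr$CB_uM + tr$CAlc_uM + tr$CAld_uM
  expect_lt(max(abs(tot - 500)) / 500, 1e-6)
  expect_true(all(as.matrix(tr[, -1]) >= -1e-9))

  # no oxidase: no aldehyde, ester + alcohol conserved
  s0 <- mimic_cascade_spec(6)
  s0$aaox_conc <- 0
  tr0 <- simulate_cascade(s0, 500, seq(0, 300, 10))
  expect_true(all(abs(tr0$CAld_uM) < 1e-9))
  expect_lt(max(abs(tr0$CB_uM + tr0$CAlc_uM - 500)) / 500, 1e-6)

  # both enzymes fast, long horizon: complete conversion to aldehyde
  fast <- mimic_cascade_spec(7.5)
  fast$lipase_conc <- 50
  fast$aaox_conc <- 50
  trf <- simulate_cascade(fast, 100, seq(0, 5000, 100))
  expect_equal(trf$CAld_uM[nrow(trf)], 100, tolerance = 1e-3)
})

test_that("simulator agrees with a brute-force fixed-step integrator", {
  # homogeneous limit, flat profiles: plain two-step MM cascade
  flat <- activity_profile(c(5, 9), c(1, 1))
  spec <- cascade_spec(two_phase_params(0, 1, 4.3, 713, 4.3, 713),
                       lipase_conc = 0.5, aaox_kcat = 3, aaox_KM = 50,
                       aaox_conc = 0.5, aaox_Kp = 1, solution_pH = 7,
                       dense_pH = 7, lipase_profile = flat,
                       aaox_profile = flat)
  tr <- simulate_cascade(spec, 200, seq(0, 100, 20))
  y_rk4 <- rk4_cascade(spec, 200, 100, dt = 0.005)
  expect_equal(unlist(tr[nrow(tr), c("CB_uM", "CAlc_uM", "CAld_uM")],
                      use.names = FALSE),
               y_rk4, tolerance = 1e-5)

  # full two-phase spec against the same oracle
  spec2 <- mimic_cascade_spec(6)
  tr2 <- simulate_cascade(spec2, 200, seq(0, 100, 20))
  y2 <- rk4_cascade(spec2, 200, 100, dt = 0.005)
  expect_equal(unlist(tr2[nrow(tr2), c("CB_uM", "CAlc_uM", "CAld_uM")],
                      use.names = FALSE),
               y2, tolerance = 1e-5)
})

test_that("output is invariant to time-grid refinement", {
  spec <- mimic_cascade_spec(7.5)
  coarse <- simulate_cascade(spec, 300, seq(0, 400, 100))
  fine <- simulate_cascade(spec, 300, seq(0, 400, 5))
  expect_equal(coarse$CAld_uM[nrow(coarse)], fine$CAld_uM[nrow(fine)],
               tolerance = 1e-6)
})

test_that("condition comparison reproduces the pH-compartmentalization
           orderings", {
  specs <- list(
    het_pH6 = mimic_cascade_spec(6, heterogeneous = TRUE),
    het_pH75 = mimic_cascade_spec(7.5, heterogeneous = TRUE),
    hom_pH6 = mimic_cascade_spec(6, heterogeneous = FALSE),
    hom_pH75 = mimic_cascade_spec(7.5, heterogeneous = FALSE))
  cmp <- compare_conditions(specs, CB_0 = 500, t_ref = 600)
  prod <- setNames(cmp$CAld_uM, cmp$condition)
  # condensates invert the pH preference: faster at pH 6 with condensates,
  # faster at pH 7.5 without
  expect_gt(prod[["het_pH6"]], prod[["het_pH75"]])
  expect_gt(prod[["hom_pH75"]], prod[["hom_pH6"]])
  expect_false(any(cmp$tied))

  # identical conditions tie; a single condition ranks trivially
  tie <- compare_conditions(list(a = specs$het_pH6, b = specs$het_pH6),
                            500, 100)
  expect_true(all(tie$tied))
  expect_equal(tie$rank, c(1L, 1L))
  one <- compare_conditions(list(only = specs$hom_pH6), 500, 100)
  expect_equal(one$rank, 1L)
})
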