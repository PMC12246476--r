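# Shared fixtures and independent oracles for the test suite.

# Characterized lipase-condensate composition (worked-example inputs)
table1_inputs <- list(c_tot = 0.5, c_dil = 0.036, phi = 1.7e-4)

# Substrate dilution series used across kinetics fixtures (uM)
S_series <- c(15.6, 31.25, 62.5, 125, 250)

# Brute-force fixed-step RK4 integrator for the two-compartment cascade.
# Independent of deSolve and of the package's RHS assembly: recomputes the
# per-phase Michaelis-Menten rates from the cascade spec directly.
rk4_cascade <- function(spec, CB_0, t_end, dt = 0.01) {
  eff <- effective_rate_constants(spec)
  phi <- spec$two_phase$phi_D
  Ksp <- spec$species_partition
  split2 <- function(total, K) {
    dil <- total / (1 - phi + K * phi)
    c(dil, K * dil)
  }
  deriv <- function(y) {
    CB <- split2(max(y[1], 0), Ksp[["CB"]])
    CA <- split2(max(y[2], 0), Ksp[["CAlc"]])
    vlip <- c(
      eff$lipase$kcat_dilute * eff$lipase$conc_dilute * CB[1] /
        (eff$lipase$KM_dilute + CB[1]),
      eff$lipase$kcat_dense * eff$lipase$conc_dense * CB[2] /
        (eff$lipase$KM_dense + CB[2]))
    vox <- c(
      eff$aaox$kcat_dilute * eff$aaox$conc_dilute * CA[1] /
        (eff$aaox$KM_dilute + CA[1]),
      eff$aaox$kcat_dense * eff$aaox$conc_dense * CA[2] /
        (eff$aaox$KM_dense + CA[2]))
    w <- c(1 - phi, phi)
    lip <- sum(w * vlip); ox <- sum(w * vox)
    c(-lip, lip - ox, ox)
  }
  y <- c(CB_0, 0, 0)
  t <- 0
  n <- ceiling(t_end / dt)
  for (i in seq_len(n)) {
    h <- min(dt, t_end - t)
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# Independent substrate-depletion oracle: RK4 on dS/dt = -vmax S/(Km + S),
# avoiding the package's Lambert-W closed form.
rk4_mm_product <- function(v_max, K_M, S0, times, dt = 0.01) {
  f <- function(S) -v_max * S / (K_M + S)
  out <- numeric(length(times))
  S <- S0; t <- 0
  for (j in seq_along(times)) {
    while (t < times[j] - 1e-12) {
      h <- min(dt, times[j] - t)
      k1 <- f(S); k2 <- f(S + h / 2 * k1)
      k3 <- f(S + h / 2 * k2); k4 <- f(S + h * k3)
      S <- S + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[j] <- S0 - S
  }
  out
}

# Fig. 4 mimic cascade specs: heterogeneous/homogeneous at a given bulk pH
mimic_cascade_spec <- function(pH, heterogeneous = TRUE) {
  tp <- if (heterogeneous) btl2_reference_params()
        else two_phase_params(phi_D = 0, K_E = 73000, kcat_I = 4.3,
                              KM_I = 713, kcat_II = 6.9, KM_II = 334)
  cascade_spec(
    two_phase = tp, lipase_conc = 0.5,
    aaox_kcat = 3, aaox_KM = 50, aaox_conc = 0.5,
    aaox_Kp = if (pH <= 6) 156 else 168,
    solution_pH = pH,
    dense_pH = if (heterogeneous) pH + 0.5 else pH)
}
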