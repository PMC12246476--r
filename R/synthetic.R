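#' Noise model for synthetic data
#'
#' @param kind `"multiplicative_gaussian"` (signal times `1 + N(0, scale)`)
#'   or `"additive_gaussian"` (signal plus `N(0, scale)` in signal units).
#' @param scale noise scale, >= 0. Default 0.05 (5% multiplicative), a
#'   stand-in matching the visual scatter of typical plate-reader
#'   replicate error bars.
#' @param seed integer seed; identical seeds reproduce identical draws.
#' @return A `noise_model` object.
#' @export
noise_model <- function(kind = c("multiplicative_gaussian",
                                 "additive_gaussian"),
                        scale = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(scale >= 0)
  structure(list(kind = kind, scale = scale, seed = as.integer(seed)),
            class = "noise_model")
}

# draw noise for x using the current RNG stream (seeding is done once per
# generator call, so multi-draw generators stay reproducible)
.apply_noise <- function(x, noise) {
  if (noise$scale == 0) return(x)
  eps <- stats::rnorm(length(x), 0, noise$scale)
  switch(noise$kind,
         multiplicative_gaussian = x * (1 + eps),
         additive_gaussian = x + eps)
}

#' Closed-form substrate depletion under Michaelis-Menten kinetics
#'
#' Product concentration at time `t` for a single-phase reaction with
#' initial substrate `S0`, from the Lambert-W solution of the integrated
#' rate law: `S(t) = K_M W((S0/K_M) exp((S0 - v_max t)/K_M))`,
#' `P(t) = S0 - S(t)`. Serves as the exact oracle behind the progress-curve
#' generator.
#'
#' @param mm an [mm_params()] object.
#' @param S0 initial substrate concentration (uM).
#' @param t time(s) in seconds.
#' @return Product concentration(s) in uM.
#' @export
mm_product_at <- function(mm, S0, t) {
  K <- mm$K_M; v <- mm$v_max
  # evaluate W on the log scale to avoid overflow for S0/K * exp(S0/K)
  lw <- function(logx) {
    # Lambert W0 for argument exp(logx); Newton on w + log w = logx
    w <- ifelse(logx > 1, logx - log(pmax(logx, 1e-12)), exp(logx))
    for (i in 1:50) {
      w <- pmax(w, 1e-300)
      f <- w + log(w) - logx
      w <- w - f * w / (w + 1)
    }
    w
  }
  logx <- log(S0 / K) + (S0 - v * t) / K
  S <- K * lw(logx)
  pmin(pmax(S0 - S, 0), S0)
}

#' Generate synthetic plate-reader progress curves
#'
#' Emulates fluorogenic substrate-hydrolysis kinetics: single-phase
#' Michaelis-Menten substrate depletion (exact integrated rate law, see
#' [mm_product_at()]), mapped through a linear calibration to raw signal,
#' with replicate noise. The sampling structure mirrors plate-reader
#' acquisition: readings every `interval` seconds with the first reading
#' `dead_time` seconds after mixing.
#'
#' @param mm an [mm_params()] object (ground truth).
#' @param S_levels initial substrate concentrations (uM).
#' @param cal a [calibration_line()] mapping product (uM) to signal.
#' @param n_reps replicates per substrate level.
#' @param noise a [noise_model()]; its seed drives all randomness here.
#' @param dead_time first-reading delay (s), default 25.
#' @param interval sampling interval (s), default 5.
#' @param n_points readings per curve, default 60.
#' @return A list of raw [progress_curve()]s; ground truth (`mm`, `cal`)
#'   attached as attributes `truth_mm` and `truth_cal`.
#' @export
gen_progress_curves <- function(mm, S_levels, cal, n_reps = 1L,
                                noise = noise_model(scale = 0),
                                dead_time = 25, interval = 5,
                                n_points = 60L) {
  stopifnot(inherits(mm, "mm_params"), inherits(cal, "calibration_line"),
            all(S_levels > 0), n_reps >= 1, n_points >= 5)
  set.seed(noise$seed)
  times <- dead_time + interval * (seq_len(n_points) - 1)
  curves <- list()
  for (S0 in S_levels) {
    P <- mm_product_at(mm, S0, times)
    signal_clean <- cal$intercept + cal$slope * P
    for (r in seq_len(n_reps)) {
      curves[[length(curves) + 1L]] <- progress_curve(
        times = times, signal = .apply_noise(signal_clean, noise),
        substrate_0 = S0, enzyme_0 = mm$enzyme_0,
        condition_label = cal$condition_label,
        replicate_id = sprintf("S%g_rep%d", S0, r))
    }
  }
  attr(curves, "truth_mm") <- mm
  attr(curves, "truth_cal") <- cal
  curves
}

#' Generate a synthetic rate-ratio dataset
#'
#' Evaluates the two-phase [rate_ratio()] at each substrate level, draws
#' `n_reps` noisy replicates, and returns the replicate means with
#' standard errors -- the shape consumed by
#' [fit_dense_phase_constants()].
#'
#' @param params a [two_phase_params()] ground truth.
#' @param S_levels substrate concentrations (uM).
#' @param n_reps replicates per level.
#' @param noise a [noise_model()].
#' @return data.frame with columns `S_uM`, `ratio`, `ratio_se`, `n`; the
#'   generating parameters attached as attribute `truth`.
#' @export
gen_ratio_dataset <- function(params, S_levels, n_reps = 1L,
                              noise = noise_model(scale = 0)) {
  stopifnot(inherits(params, "two_phase_params"), all(S_levels >= 0),
            n_reps >= 1)
  set.seed(noise$seed)
  rows <- lapply(S_levels, function(S) {
    r_true <- rate_ratio(params, S)
    reps <- .apply_noise(rep(r_true, n_reps), noise)
    data.frame(
      S_uM = S, ratio = mean(reps),
      ratio_se = if (n_reps > 1) stats::sd(reps) / sqrt(n_reps) else NA_real_,
      n = n_reps)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- params
  out
}

#' Generate a synthetic SNARF-1 measurement table
#'
#' Dilute-phase intensity ratios at each nominal solution pH and
#' dense-phase ratios at `pH + dense_shift`, both through
#' [snarf_forward()] plus replicate noise.
#'
#' @param cal a [snarf_calibration()] ground truth.
#' @param ph_levels nominal solution pH values.
#' @param dense_shift dense-phase pH shift (pH units), e.g. +0.5.
#' @param n_reps replicates per level and phase.
#' @param noise a [noise_model()].
#' @return data.frame with columns `pH_nominal`, `phase`, `replicate_id`,
#'   `ratio`; ground truth attached as attributes `truth_cal` and
#'   `truth_shift`.
#' @export
gen_snarf_dataset <- function(cal, ph_levels, dense_shift = 0,
                              n_reps = 1L, noise = noise_model(scale = 0)) {
  stopifnot(inherits(cal, "snarf_calibration"), n_reps >= 1)
  set.seed(noise$seed)
  rows <- list()
  for (ph in ph_levels) {
    for (phase in c("dilute", "dense")) {
      true_ph <- if (phase == "dense") ph + dense_shift else ph
      r_true <- snarf_forward(cal, true_ph)
      reps <- .apply_noise(rep(r_true, n_reps), noise)
      rows[[length(rows) + 1L]] <- data.frame(
        pH_nominal = ph, phase = phase,
        replicate_id = sprintf("%s_pH%g_r%d", phase, ph, seq_len(n_reps)),
        ratio = reps, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth_cal") <- cal
  attr(out, "truth_shift") <- dense_shift
  out
}

#' Generate a self-consistent phase composition
#'
#' Solves the mass balance for the dilute- and dense-phase concentrations
#' given total concentration, partition coefficient and volume fraction:
#' `c_dil = c_tot / (1 - phi + K_E phi)`, `c_dense = K_E c_dil`. The
#' result satisfies the [phase_composition()] invariants by construction.
#'
#' @param c_tot total protein concentration (uM).
#' @param K_E enzyme partition coefficient.
#' @param phi dense-phase volume fraction in `[0, 1)`.
#' @return A [phase_composition()] object.
#' @examples
#' gen_phase_composition(0.5, 73000, 1.7e-4)  # c_dil ~0.037, 93% recruited
#' @export
gen_phase_composition <- function(c_tot, K_E, phi) {
  stopifnot(c_tot > 0, K_E > 0, phi >= 0, phi < 1)
  c_dil <- c_tot / (1 - phi + K_E * phi)
  phase_composition(c_tot = c_tot, c_dil = c_dil, phi = phi)
}

#' Generate a synthetic SNARF calibration table
#'
#' Buffer-series calibration data (one row per replicate and pH level)
#' from a known calibration, for testing [fit_snarf_calibration()].
#'
#' @inheritParams gen_snarf_dataset
#' @return data.frame with columns `pH`, `ratio`; truth attached as
#'   attribute `truth_cal`.
#' @export
gen_snarf_calibration_table <- function(cal,
                                        ph_levels = seq(6, 9, by = 0.5),
                                        n_reps = 1L,
                                        noise = noise_model(scale = 0)) {
  stopifnot(inherits(cal, "snarf_calibration"), n_reps >= 1)
  set.seed(noise$seed)
  out <- do.call(rbind, lapply(ph_levels, function(ph) {
    data.frame(pH = ph,
               ratio = .apply_noise(rep(snarf_forward(cal, ph), n_reps),
                                    noise))
  }))
  rownames(out) <- NULL
  attr(out, "truth_cal") <- cal
  out
}
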