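#' Progress curve of a fluorogenic/chromogenic enzymatic reaction
#'
#' The unit of kinetic raw data: a time series of plate-reader signal (or,
#' after calibration, product concentration) for one well.
#'
#' @param times sampling times (s), strictly increasing, length >= 5.
#' @param signal raw signal (fluorescence/absorbance) or product
#'   concentration (uM) when `units = "uM"`.
#' @param substrate_0 initial substrate concentration (uM), > 0.
#' @param enzyme_0 total enzyme concentration (uM), >= 0.
#' @param condition_label free-text condition (buffer, pH, salt); used to
#'   match calibration lines.
#' @param replicate_id replicate identifier.
#' @param units `"signal"` (raw) or `"uM"` (calibrated product).
#' @return A `progress_curve` object.
#' @export
progress_curve <- function(times, signal, substrate_0, enzyme_0,
                           condition_label = "default",
                           replicate_id = "r1",
                           units = c("signal", "uM")) {
  units <- match.arg(units)
  stopifnot(is.numeric(times), is.numeric(signal),
            length(times) == length(signal))
  if (length(times) < 5L)
    stop("a progress curve needs at least 5 samples", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  stopifnot(substrate_0 > 0, enzyme_0 >= 0)
  structure(
    list(times = times, signal = signal, substrate_0 = substrate_0,
         enzyme_0 = enzyme_0, condition_label = condition_label,
         replicate_id = replicate_id, units = units),
    class = "progress_curve")
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf(
    "Progress curve [%s/%s]: %d samples, t = %g..%g s, S0 = %g uM, E0 = %g uM (%s)\n",
    x$condition_label, x$replicate_id, length(x$times),
    min(x$times), max(x$times), x$substrate_0, x$enzyme_0, x$units))
  invisible(x)
}

#' Linear signal-to-concentration calibration
#'
#' One calibration line per buffer condition, as constructed from a product
#' standard series (e.g. methylumbelliferone in each reaction buffer).
#'
#' @param slope signal per uM, > 0.
#' @param intercept signal at zero product.
#' @param valid_range concentration interval (uM) covered by the standards.
#' @param condition_label condition the line applies to.
#' @return A `calibration_line` object.
#' @export
calibration_line <- function(slope, intercept = 0,
                             valid_range = c(0, Inf),
                             condition_label = "default") {
  stopifnot(slope > 0, length(valid_range) == 2L,
            valid_range[1] < valid_range[2])
  structure(
    list(slope = slope, intercept = intercept, valid_range = valid_range,
         condition_label = condition_label),
    class = "calibration_line")
}

#' Convert a raw progress curve to product-concentration units
#'
#' Applies `conc = (signal - intercept)/slope`. Samples falling outside the
#' calibration's valid concentration range (including negative
#' concentrations from signal below the intercept) are flagged in the
#' returned curve's `flagged` field, never dropped.
#'
#' @param curve a raw `progress_curve` (`units = "signal"`).
#' @param cal a [calibration_line()] whose `condition_label` matches the
#'   curve's.
#' @return A `progress_curve` in uM with a logical `flagged` vector.
#' @export
signal_to_concentration <- function(curve, cal) {
  stopifnot(inherits(curve, "progress_curve"),
            inherits(cal, "calibration_line"))
  if (curve$units != "signal")
    stop("curve is already in concentration units", call. = FALSE)
  if (!identical(curve$condition_label, cal$condition_label))
    stop("calibration condition '", cal$condition_label,
         "' does not match curve condition '", curve$condition_label,
         "'; calibrations are buffer-specific", call. = FALSE)
  conc <- (curve$signal - cal$intercept) / cal$slope
  out <- curve
  out$signal <- conc
  out$units <- "uM"
  out$flagged <- conc < cal$valid_range[1] | conc > cal$valid_range[2]
  out
}

#' A single initial-rate measurement
#'
#' @param substrate_0 initial substrate concentration (uM).
#' @param rate initial rate (uM/s), >= 0 up to noise.
#' @param se standard error of the rate (uM/s).
#' @param n_replicates number of replicate wells behind the value.
#' @param system `"homogeneous"` or `"heterogeneous"`.
#' @return A `rate_measurement` object.
#' @export
rate_measurement <- function(substrate_0, rate, se = NA_real_,
                             n_replicates = 1L,
                             system = c("homogeneous", "heterogeneous")) {
  system <- match.arg(system)
  stopifnot(substrate_0 > 0, n_replicates >= 1)
  structure(
    list(substrate_0 = substrate_0, rate = rate, se = se,
         n_replicates = as.integer(n_replicates), system = system),
    class = "rate_measurement")
}

#' Extract the initial rate from a calibrated progress curve
#'
#' Ordinary least squares of product concentration on time, restricted to
#' the low-conversion window: all points with product below
#' `max_conversion` of the initial substrate. A free intercept absorbs the
#' instrument dead time (typical plate-reader runs start ~25 s after
#' mixing, with signal already accumulated).
#'
#' @param curve a `progress_curve` in uM (see [signal_to_concentration()]).
#' @param max_conversion window bound as a fraction of `substrate_0`
#'   converted; default 0.1 (10% conversion).
#' @param min_points minimum number of in-window samples (default 5).
#' @return A [rate_measurement()] with the regression slope and its standard
#'   error; attributes `conversion` (fraction of substrate converted inside
#'   the window) and `nonmonotone` (TRUE when the fitted slope is negative
#'   beyond 2 SE, indicating a gross signal problem).
#' @export
initial_rate <- function(curve, max_conversion = 0.1, min_points = 5L) {
  stopifnot(inherits(curve, "progress_curve"))
  if (curve$units != "uM")
    stop("initial_rate needs a calibrated curve in uM; run ",
         "signal_to_concentration() first", call. = FALSE)
  product <- curve$signal  # absolute product concentration after calibration
  inside <- product <= max_conversion * curve$substrate_0
  if (sum(inside) < min_points)
    stop("fewer than ", min_points, " samples inside the ",
         100 * max_conversion, "% conversion window", call. = FALSE)
  tt <- curve$times[inside]
  pp <- curve$signal[inside]
  fit <- stats::lm(pp ~ tt)
  # noiseless synthetic curves fit perfectly; that is expected, not a problem
  est <- withCallingHandlers(
    stats::coef(summary(fit)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  slope <- est["tt", "Estimate"]
  se <- est["tt", "Std. Error"]
  nonmono <- is.finite(se) && se > 0 && slope < -2 * se
  if (nonmono)
    warning("fitted slope is negative beyond 2 SE: non-monotone signal",
            call. = FALSE)
  out <- rate_measurement(curve$substrate_0, slope, se, 1L)
  attr(out, "conversion") <- max(product[inside]) / curve$substrate_0
  attr(out, "nonmonotone") <- nonmono
  attr(out, "n_points") <- sum(inside)
  out
}

#' Michaelis-Menten parameter set for one phase/system
#'
#' @param v_max maximal rate (uM/s), > 0.
#' @param K_M Michaelis constant (uM), > 0. Apparent when the system is
#'   heterogeneous.
#' @param enzyme_0 total enzyme concentration (uM), > 0; `k_cat` is derived
#'   as `v_max/enzyme_0`.
#' @param v_max_se,K_M_se optional standard errors.
#' @return An `mm_params` object with fields `v_max`, `K_M`, `k_cat`,
#'   `enzyme_0` and the standard errors (`k_cat_se` propagated from
#'   `v_max_se`).
#' @export
mm_params <- function(v_max, K_M, enzyme_0,
                      v_max_se = NA_real_, K_M_se = NA_real_) {
  stopifnot(v_max > 0, K_M > 0, enzyme_0 > 0)
  structure(
    list(v_max = v_max, K_M = K_M, enzyme_0 = enzyme_0,
         k_cat = v_max / enzyme_0,
         v_max_se = v_max_se, K_M_se = K_M_se,
         k_cat_se = v_max_se / enzyme_0),
    class = "mm_params")
}

#' @export
print.mm_params <- function(x, ...) {
  fmt <- function(v, s) if (is.na(s)) sprintf("%.4g", v)
         else sprintf("%.4g +/- %.2g", v, s)
  cat("Michaelis-Menten parameters\n")
  cat("  v_max :", fmt(x$v_max, x$v_max_se), "uM/s\n")
  cat("  K_M   :", fmt(x$K_M, x$K_M_se), "uM\n")
  cat("  k_cat :", fmt(x$k_cat, x$k_cat_se), "1/s  (E0 =", x$enzyme_0, "uM)\n")
  if (isTRUE(attr(x, "beyond_data")))
    cat("  note  : fitted K_M exceeds the largest measured [S];",
        "apparent constants extrapolate beyond the data\n")
  invisible(x)
}

#' Michaelis-Menten rate law
#'
#' \deqn{v = v_{max} [S] / (K_M + [S])}
#'
#' @param params an [mm_params()] object (or any list with `v_max`, `K_M`).
#' @param S substrate concentration(s), uM, >= 0.
#' @return Rate(s) in uM/s.
#' @examples
#' p <- mm_params(v_max = 2.1, K_M = 713, enzyme_0 = 0.5)
#' mm_rate(p, 250)  # ~0.545 uM/s
#' @export
mm_rate <- function(params, S) {
  stopifnot(all(S >= 0))
  params$v_max * S / (params$K_M + S)
}

#' Turnover number from maximal rate
#'
#' @param v_max maximal rate (uM/s).
#' @param enzyme_0 total enzyme concentration (uM), > 0.
#' @return k_cat in 1/s.
#' @examples
#' kcat_from_vmax(3.8, 0.5)  # 7.6
#' @export
kcat_from_vmax <- function(v_max, enzyme_0) {
  if (any(enzyme_0 <= 0))
    stop("enzyme_0 must be positive", call. = FALSE)
  v_max / enzyme_0
}

#' Fit the Michaelis-Menten model to initial-rate data
#'
#' Nonlinear least squares of [mm_rate()] against a table of initial rates
#' at several substrate concentrations. When replicate standard errors are
#' present for at least 3 substrate levels, the fit is weighted by
#' `1/se^2`; otherwise unweighted. Start values are data-driven
#' (`v_max0 = max(rate)`, `K_M0` = S at half of `v_max0`, interpolated) and
#' both parameters are bounded below by zero, so the fit is deterministic.
#'
#' A warning attribute `beyond_data` is set when the fitted `K_M` exceeds
#' the largest measured substrate concentration (limited-solubility regime:
#' the apparent constants extrapolate beyond the data). A `boundary`
#' attribute is set when `K_M` collapses towards zero (rates flat at
#' `v_max`, a degenerate design).
#'
#' @param data data.frame with columns `S_uM` and `rate` (uM/s), optionally
#'   `rate_se` and `n`; or a list of [rate_measurement()] objects.
#' @param enzyme_0 total enzyme concentration (uM) for `k_cat`.
#' @return An [mm_params()] object with standard errors from the fit
#'   covariance; the `nls` fit is attached as attribute `fit`.
#' @export
fit_michaelis_menten <- function(data, enzyme_0) {
  data <- as_rate_table(data)
  if (length(unique(data$S_uM)) < 3L)
    stop("need at least 3 distinct substrate concentrations", call. = FALSE)
  v0 <- max(data$rate)
  if (v0 <= 0) stop("all rates non-positive; nothing to fit", call. = FALSE)
  K0 <- .half_saturation_guess(data$S_uM, data$rate, v0)
  use_w <- !is.null(data$rate_se) && sum(is.finite(data$rate_se) &
                                           data$rate_se > 0) >= 3
  w <- if (use_w) 1 / data$rate_se^2 else rep(1, nrow(data))
  w[!is.finite(w)] <- max(w[is.finite(w)], 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ vmax * S_uM / (Km + S_uM), data = data,
      start = list(vmax = v0, Km = K0),
      lower = c(vmax = 0, Km = 0), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(vmax = NA_real_, Km = NA_real_))
  if (cf[["Km"]] < 1e-6 * max(data$S_uM)) {
    warning("fitted K_M collapsed to the zero boundary (rates flat at ",
            "v_max); K_M is not identifiable from this design",
            call. = FALSE)
    # keep the boundary value but mark it
    out <- mm_params(max(cf[["vmax"]], .Machine$double.eps),
                     max(cf[["Km"]], .Machine$double.xmin),
                     enzyme_0, se[["vmax"]], se[["Km"]])
    attr(out, "boundary") <- TRUE
  } else {
    out <- mm_params(cf[["vmax"]], cf[["Km"]], enzyme_0,
                     se[["vmax"]], se[["Km"]])
    attr(out, "boundary") <- FALSE
  }
  attr(out, "beyond_data") <- out$K_M > max(data$S_uM)
  attr(out, "fit") <- fit
  out
}

# interpolated S at half-maximal observed rate; fallback to median S
.half_saturation_guess <- function(S, rate, v0) {
  o <- order(S)
  S <- S[o]; rate <- rate[o]
  half <- v0 / 2
  K0 <- tryCatch(stats::approx(rate, S, xout = half, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(K0) || K0 <= 0) K0 <- stats::median(S)
  K0
}

# Accept a data.frame or a list of rate_measurement objects.
as_rate_table <- function(data) {
  if (is.data.frame(data)) {
    if (!all(c("S_uM", "rate") %in% names(data)))
      stop("rate table needs columns S_uM and rate", call. = FALSE)
    return(data)
  }
  if (is.list(data) && all(vapply(data, inherits, TRUE, "rate_measurement"))) {
    return(data.frame(
      S_uM = vapply(data, `[[`, 0, "substrate_0"),
      rate = vapply(data, `[[`, 0, "rate"),
      rate_se = vapply(data, `[[`, 0, "se"),
      n = vapply(data, `[[`, 0L, "n_replicates")))
  }
  stop("data must be a data.frame or a list of rate_measurement objects",
       call. = FALSE)
}

#' Pool replicate initial rates per substrate level
#'
#' Collapses per-well rates to one row per substrate concentration with the
#' replicate mean, the standard error of the mean and the replicate count --
#' the form consumed by [fit_michaelis_menten()].
#'
#' @param rates data.frame with columns `S_uM` and `rate` (one row per well).
#' @return data.frame with columns `S_uM`, `rate`, `rate_se`, `n`.
#' @export
pool_rates <- function(rates) {
  stopifnot(is.data.frame(rates), all(c("S_uM", "rate") %in% names(rates)))
  sp <- split(rates$rate, rates$S_uM)
  data.frame(
    S_uM = as.numeric(names(sp)),
    rate = vapply(sp, mean, 0),
    rate_se = vapply(sp, function(x)
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_, 0),
    n = vapply(sp, length, 0L),
    row.names = NULL)
}
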