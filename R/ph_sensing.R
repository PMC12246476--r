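#' Ratiometric SNARF-1 calibration
#'
#' Parameters of the single-site ratiometric Henderson-Hasselbalch model
#' linking the dual-emission intensity ratio of SNARF-1 (acidic ~580 nm
#' band over basic ~640 nm band) to pH:
#' \deqn{R(pH) = R_{acid} + \frac{R_{base} - R_{acid}}{1 + 10^{pK_a - pH}}.}
#' The curve is strictly monotone in pH and analytically invertible.
#'
#' @param pKa_app apparent pKa of the dye in the calibration buffer series.
#' @param R_acid limiting intensity ratio at low pH.
#' @param R_base limiting intensity ratio at high pH; must differ from
#'   `R_acid`.
#' @param valid_range pH interval covered by the calibration buffers
#'   (default `c(6, 9)`, the dye's usable dynamic range).
#' @return A `snarf_calibration` object.
#' @export
snarf_calibration <- function(pKa_app, R_acid, R_base,
                              valid_range = c(6, 9)) {
  stopifnot(is.numeric(pKa_app), length(valid_range) == 2L,
            valid_range[1] < valid_range[2])
  if (R_acid == R_base)
    stop("R_acid must differ from R_base (flat curve carries no pH ",
         "information)", call. = FALSE)
  structure(
    list(pKa_app = pKa_app, R_acid = R_acid, R_base = R_base,
         valid_range = valid_range),
    class = "snarf_calibration")
}

#' @export
print.snarf_calibration <- function(x, ...) {
  cat(sprintf(
    "SNARF-1 ratiometric calibration: pKa_app = %.2f, R_acid = %.3g, R_base = %.3g, valid pH %.1f-%.1f\n",
    x$pKa_app, x$R_acid, x$R_base, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Forward SNARF-1 calibration curve: pH to intensity ratio
#'
#' @param cal a [snarf_calibration()].
#' @param pH pH value(s); extrapolation beyond `valid_range` is allowed.
#' @return Predicted intensity ratio(s).
#' @examples
#' cal <- snarf_calibration(pKa_app = 7.5, R_acid = 2, R_base = 0.5)
#' snarf_forward(cal, 7.5)  # midpoint (R_acid + R_base)/2 = 1.25
#' @export
snarf_forward <- function(cal, pH) {
  stopifnot(inherits(cal, "snarf_calibration"))
  cal$R_acid + (cal$R_base - cal$R_acid) / (1 + 10^(cal$pKa_app - pH))
}

#' A dual-channel intensity ratio measurement
#'
#' @param I_ch1 intensity in the acidic emission band (570-590 nm).
#' @param I_ch2 intensity in the basic emission band (630-650 nm).
#' @param phase `"dense"` or `"dilute"`.
#' @param replicate_id replicate identifier.
#' @return A `ratio_measurement` object with `ratio = I_ch1/I_ch2`.
#' @export
ratio_measurement <- function(I_ch1, I_ch2, phase = c("dilute", "dense"),
                              replicate_id = "r1") {
  phase <- match.arg(phase)
  stopifnot(I_ch1 > 0, I_ch2 > 0)
  structure(
    list(I_ch1 = I_ch1, I_ch2 = I_ch2, ratio = I_ch1 / I_ch2,
         phase = phase, replicate_id = replicate_id),
    class = "ratio_measurement")
}

#' Invert an intensity ratio to apparent pH
#'
#' Analytic inverse of [snarf_forward()]. Ratios outside the open interval
#' between `R_acid` and `R_base` cannot be inverted (the sigmoid never
#' reaches them): the result is `NA` with flag `"unresolvable"`. Ratios
#' that invert to a pH outside the calibration's `valid_range` -- beyond the
#' dye's characterized dynamic range -- are returned with flag
#' `"out_of_range"`, not suppressed.
#'
#' @param cal a [snarf_calibration()].
#' @param m a [ratio_measurement()] or a numeric intensity ratio (vector).
#' @return data.frame with columns `pH` and `flag`
#'   (`"ok"`/`"out_of_range"`/`"unresolvable"`).
#' @export
ratio_to_ph <- function(cal, m) {
  stopifnot(inherits(cal, "snarf_calibration"))
  r <- if (inherits(m, "ratio_measurement")) m$ratio else as.numeric(m)
  f <- (r - cal$R_acid) / (cal$R_base - cal$R_acid)
  pH <- ifelse(f > 0 & f < 1,
               cal$pKa_app + log10(f / (1 - f)),
               NA_real_)
  tol <- 1e-9  # round-trip slack at the range boundaries
  flag <- ifelse(is.na(pH), "unresolvable",
                 ifelse(pH < cal$valid_range[1] - tol |
                          pH > cal$valid_range[2] + tol,
                        "out_of_range", "ok"))
  data.frame(pH = pH, flag = flag, stringsAsFactors = FALSE)
}

#' Fit the ratiometric calibration to a buffer series
#'
#' Least-squares fit of [snarf_forward()] to measured (pH, ratio) pairs,
#' e.g. buffers from pH 6.0 to 9.0 at 0.5-unit intervals. Start values are
#' data-driven: the limiting ratios from the extreme pH levels and the pKa
#' from the mid-span. The calibration's `valid_range` is set to the span of
#' the calibration pH values.
#'
#' @param data data.frame with columns `pH` and `ratio`, optionally
#'   `ratio_se` (used as `1/se^2` weights when all finite and positive).
#' @return A [snarf_calibration()] with standard errors in attribute `se`
#'   and the `nls` fit in attribute `fit`.
#' @export
fit_snarf_calibration <- function(data) {
  stopifnot(is.data.frame(data), all(c("pH", "ratio") %in% names(data)))
  levels_pH <- sort(unique(data$pH))
  if (length(levels_pH) < 4L)
    stop("need at least 4 distinct pH levels (3-parameter sigmoid)",
         call. = FALSE)
  if (diff(range(levels_pH)) <= 1)
    stop("calibration pH levels must span more than 1 pH unit",
         call. = FALSE)
  means <- vapply(split(data$ratio, data$pH), mean, 0)
  dmeans <- diff(means[order(as.numeric(names(means)))])
  if (any(dmeans > 0) && any(dmeans < 0))
    warning("mean ratios are not monotone in pH; calibration data may be ",
            "noisy or corrupted", call. = FALSE)
  o <- order(data$pH)
  R_a0 <- mean(data$ratio[data$pH == min(levels_pH)])
  R_b0 <- mean(data$ratio[data$pH == max(levels_pH)])
  pKa0 <- stats::median(levels_pH)
  use_w <- !is.null(data$ratio_se) && all(is.finite(data$ratio_se)) &&
    all(data$ratio_se > 0)
  w <- if (use_w) 1 / data$ratio_se^2 else rep(1, nrow(data))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ratio ~ Ra + (Rb - Ra) / (1 + 10^(pKa - pH)), data = data,
      start = list(Ra = R_a0, Rb = R_b0, pKa = pKa0), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("SNARF calibration fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) stats::setNames(rep(NA_real_, 3),
                                                     names(cf)))
  out <- snarf_calibration(pKa_app = cf[["pKa"]], R_acid = cf[["Ra"]],
                           R_base = cf[["Rb"]],
                           valid_range = range(levels_pH))
  attr(out, "se") <- c(pKa_app = se[["pKa"]], R_acid = se[["Ra"]],
                       R_base = se[["Rb"]])
  attr(out, "fit") <- fit
  out
}

#' Dense-minus-dilute apparent pH shift
#'
#' Mean apparent pH in the dense phase minus mean in the dilute phase, with
#' the standard error propagated from the two standard errors of the mean
#' (a single-replicate group contributes zero).
#'
#' @param dense,dilute numeric vectors of per-replicate apparent pH values.
#' @return list with `shift`, `se`, `n_dense`, `n_dilute`.
#' @examples
#' ph_shift(dense = c(8.0, 8.0), dilute = c(7.5, 7.5))$shift  # +0.5
#' @export
ph_shift <- function(dense, dilute) {
  dense <- dense[is.finite(dense)]
  dilute <- dilute[is.finite(dilute)]
  if (length(dense) < 1L || length(dilute) < 1L)
    stop("need at least one finite pH value per phase", call. = FALSE)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  list(shift = mean(dense) - mean(dilute),
       se = sqrt(sem(dense)^2 + sem(dilute)^2),
       n_dense = length(dense), n_dilute = length(dilute))
}
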