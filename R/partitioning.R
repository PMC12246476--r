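#' Phase composition of a two-phase (condensate-containing) system
#'
#' Bundles the measured composition of a phase-separated sample -- total
#' protein concentration, dilute-phase concentration and dense-phase volume
#' fraction -- with the quantities derived from the mass balance
#' \deqn{c_{tot} = \phi\, c_{dense} + (1-\phi)\, c_{dil}:}
#' the dense-phase concentration, the enzyme partition coefficient
#' \eqn{K_E = c_{dense}/c_{dil}} and the fraction of protein recruited into
#' the dense phase.
#'
#' All concentrations are in micromolar; volume fractions are plain fractions
#' (0.00017, never percent). Use [parse_volume_fraction()] to convert
#' "%"-suffixed text input.
#'
#' @param c_tot total protein concentration (uM).
#' @param c_dil dilute-phase concentration (uM); must satisfy
#'   `c_dil <= c_tot`.
#' @param phi dense-phase volume fraction in `[0, 1)`.
#' @return An object of class `phase_composition`: a list with fields
#'   `c_tot`, `c_dil`, `c_dense`, `phi`, `K_E`, `fraction_dense`.
#' @examples
#' comp <- phase_composition(c_tot = 0.5, c_dil = 0.036, phi = 1.7e-4)
#' comp$c_dense        # ~2729 uM, i.e. ~2.7 mM
#' comp$fraction_dense # ~0.93
#' @export
phase_composition <- function(c_tot, c_dil, phi) {
  stopifnot(is.numeric(c_tot), is.numeric(c_dil), is.numeric(phi),
            length(c_tot) == 1L, length(c_dil) == 1L, length(phi) == 1L)
  if (phi < 0 || phi >= 1)
    stop("phi must lie in [0, 1); got ", phi, call. = FALSE)
  if (c_dil > c_tot)
    stop("c_dil (", c_dil, ") exceeds c_tot (", c_tot,
         "): no dense-phase enrichment", call. = FALSE)
  if (phi == 0 || c_dil == c_tot) {
    c_dense <- c_tot
    K_E <- 1
    fraction_dense <- phi
  } else {
    c_dense <- dense_concentration(c_tot, c_dil, phi)
    K_E <- partition_coefficient(c_dense, c_dil)
    fraction_dense <- phi * c_dense / c_tot
  }
  out <- structure(
    list(c_tot = c_tot, c_dil = c_dil, c_dense = c_dense, phi = phi,
         K_E = K_E, fraction_dense = fraction_dense),
    class = "phase_composition")
  validate_phase_composition(out)
  out
}

validate_phase_composition <- function(x) {
  # mass balance must close to 1e-9 relative
  recon <- x$phi * x$c_dense + (1 - x$phi) * x$c_dil
  if (abs(recon - x$c_tot) > 1e-9 * max(1, abs(x$c_tot)))
    stop("mass balance violated: phi*c_dense + (1-phi)*c_dil = ", recon,
         " but c_tot = ", x$c_tot, call. = FALSE)
  invisible(x)
}

#' @export
print.phase_composition <- function(x, ...) {
  cat("Two-phase composition (mass balance)\n")
  cat(sprintf("  c_tot   : %g uM\n", x$c_tot))
  cat(sprintf("  c_dil   : %g uM\n", x$c_dil))
  cat(sprintf("  c_dense : %g uM (%.2g mM)\n", x$c_dense, x$c_dense / 1000))
  cat(sprintf("  phi     : %g (%.3g%%)\n", x$phi, 100 * x$phi))
  cat(sprintf("  K_E     : %g\n", x$K_E))
  cat(sprintf("  protein in dense phase: %.1f%%\n", 100 * x$fraction_dense))
  invisible(x)
}

#' Dense-phase concentration from the mass balance
#'
#' Inverts the mass balance \eqn{\phi = (c_{tot}-c_{dil})/(c_{dense}-c_{dil})}
#' for the dense-phase concentration:
#' \eqn{c_{dense} = c_{dil} + (c_{tot}-c_{dil})/\phi}.
#'
#' @param c_tot,c_dil total and dilute-phase concentrations (uM).
#' @param phi dense-phase volume fraction, strictly inside (0, 1).
#' @return Dense-phase concentration (uM).
#' @examples
#' dense_concentration(0.5, 0.036, 1.7e-4)  # ~2729 uM ~ 2.7 mM
#' @export
dense_concentration <- function(c_tot, c_dil, phi) {
  if (any(phi <= 0) || any(phi >= 1))
    stop("phi must lie strictly inside (0, 1); got ", phi[1], call. = FALSE)
  if (any(c_dil >= c_tot))
    stop("c_dil >= c_tot: no dense-phase enrichment", call. = FALSE)
  c_dil + (c_tot - c_dil) / phi
}

#' Dense-phase volume fraction from the mass balance
#'
#' @param c_tot,c_dil,c_dense concentrations (uM) with
#'   `c_dil <= c_tot <= c_dense` (strict in the interior).
#' @return Volume fraction \eqn{(c_{tot}-c_{dil})/(c_{dense}-c_{dil})}.
#' @examples
#' volume_fraction(0.5, 0.036, 2729.4)  # ~1.7e-4
#' @export
volume_fraction <- function(c_tot, c_dil, c_dense) {
  if (any(c_dil > c_tot))
    stop("ordering violated: c_dil > c_tot", call. = FALSE)
  if (any(c_tot > c_dense))
    stop("ordering violated: c_tot > c_dense", call. = FALSE)
  if (any(c_dense == c_dil))
    stop("ordering violated: c_dense = c_dil (phases indistinct)",
         call. = FALSE)
  (c_tot - c_dil) / (c_dense - c_dil)
}

#' Partition coefficient between dense and dilute phase
#'
#' @param c_dense,c_dil concentrations of a species in the dense and dilute
#'   phase (same units).
#' @return The dimensionless ratio `c_dense/c_dil`.
#' @examples
#' partition_coefficient(2729.4, 0.036)  # ~7.6e4
#' @export
partition_coefficient <- function(c_dense, c_dil) {
  if (any(c_dense <= 0))
    stop("c_dense must be positive", call. = FALSE)
  if (any(c_dil <= 0))
    stop("c_dil = 0: partitioning unbounded", call. = FALSE)
  c_dense / c_dil
}

#' Fraction of a species recruited into the dense phase
#'
#' For a self-consistent [phase_composition()], returns
#' \eqn{\phi\, c_{dense}/c_{tot}}, identically equal to
#' \eqn{1 - (1-\phi)\, c_{dil}/c_{tot}}.
#'
#' @param comp a `phase_composition` object.
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
fraction_in_dense <- function(comp) {
  stopifnot(inherits(comp, "phase_composition"))
  comp$phi * comp$c_dense / comp$c_tot
}

#' Dilute-phase enzyme dilution factor xi
#'
#' The factor by which condensate formation depletes the dilute-phase enzyme
#' concentration at fixed total enzyme:
#' \deqn{\xi = \frac{[E]_0^{I,het}}{[E]_0^{hom}} = \frac{1}{K_E \phi + 1 - \phi}.}
#'
#' @param K_E enzyme partition coefficient (>= 0).
#' @param phi dense-phase volume fraction in `[0, 1)`.
#' @return Dimensionless xi; equals 1 when `phi = 0` or `K_E = 1`.
#' @examples
#' xi_dilution(73000, 1.7e-4)  # ~0.0746
#' @export
xi_dilution <- function(K_E, phi) {
  stopifnot(all(K_E >= 0), all(phi >= 0), all(phi < 1))
  1 / (K_E * phi + 1 - phi)
}

#' Dilute-phase fraction of a partitioning client
#'
#' Fraction of a client species (e.g. an added enzyme) remaining in the
#' dilute phase given its partition coefficient:
#' \eqn{(1-\phi) / ((1-\phi) + K_p \phi)}.
#'
#' @param K_p client partition coefficient (> 0).
#' @param phi dense-phase volume fraction in `[0, 1)`.
#' @return Dimensionless fraction in `(0, 1]`.
#' @examples
#' client_fraction_dilute(156, 1.7e-4)  # ~0.974: client stays dilute
#' @export
client_fraction_dilute <- function(K_p, phi) {
  stopifnot(all(K_p > 0), all(phi >= 0), all(phi < 1))
  (1 - phi) / ((1 - phi) + K_p * phi)
}

#' Client partitioning summary
#'
#' @param K_p client partition coefficient (> 0).
#' @param phi dense-phase volume fraction.
#' @return A `client_partition` list with `K_p`, `phi` and `fraction_dilute`.
#' @export
client_partition <- function(K_p, phi) {
  structure(
    list(K_p = K_p, phi = phi,
         fraction_dilute = client_fraction_dilute(K_p, phi)),
    class = "client_partition")
}

#' @export
print.client_partition <- function(x, ...) {
  cat(sprintf("Client partitioning: K_p = %g, phi = %g -> %.1f%% dilute\n",
              x$K_p, x$phi, 100 * x$fraction_dilute))
  invisible(x)
}
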