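# Instrument-level observable formulas: IRGA gas exchange, PAM fluorometry,
# leaf absorption, and the goodness-of-fit statistic used on parity plots.

#' Carbon assimilation from IRGA readings
#'
#' Net CO2 uptake from the open-path gas-exchange balance
#' \deqn{A = \mu_0 [c_0 - c_a (1 - w_0)/(1 - w_a)] / s}
#' where the water-dilution factor corrects the outgoing CO2 concentration
#' for transpiration.
#'
#' @param mu0 air flow entering the chamber, umol air s-1 (> 0).
#' @param s_area leaf area, m2 (> 0).
#' @param c0,ca CO2 concentration entering/exiting, umol mol-1.
#' @param w0,wa H2O mole fraction entering/exiting, mol mol-1 in [0, 1). If
#'   given in mmol mol-1 (values > 1), they are converted.
#' @return A, umol CO2 m-2 s-1.
#' @examples
#' assimilation_from_irga(500e-6, 6e-4, 400, 380, 0.02, 0.02)
#' @export
assimilation_from_irga <- function(mu0, s_area, c0, ca, w0 = 0, wa = 0) {
  stopifnot(mu0 > 0, s_area > 0)
  # accept mmol mol-1 (the instrument's H2O unit) and convert
  if (any(w0 > 1)) w0 <- w0 / 1000
  if (any(wa > 1)) wa <- wa / 1000
  stopifnot(all(w0 >= 0), all(w0 < 1), all(wa >= 0), all(wa < 1))
  mu0 * (c0 - ca * (1 - w0) / (1 - wa)) / s_area
}

#' PSII operating efficiency
#'
#' \eqn{\Phi_{PSII} = (F_m' - F_s) / F_m'} from light-adapted maximal
#' (\code{fm_prime}) and steady-state (\code{fs}) fluorescence.
#'
#' @param fm_prime maximal fluorescence in the light (> 0).
#' @param fs steady-state fluorescence.
#' @return dimensionless efficiency in [0, 1).
#' @export
phi_psii <- function(fm_prime, fs) {
  if (any(fm_prime <= 0)) stop("fm_prime must be positive")
  (fm_prime - fs) / fm_prime
}

#' Stern-Volmer non-photochemical quenching
#'
#' \eqn{NPQ = (F_m - F_m') / F_m'} from dark-adapted (\code{fm}) and
#' light-adapted (\code{fm_prime}) maximal fluorescence.
#'
#' @param fm dark-adapted maximal fluorescence.
#' @param fm_prime light-adapted maximal fluorescence (> 0).
#' @return dimensionless NPQ (>= 0 when \code{fm >= fm_prime}).
#' @export
npq_stern_volmer <- function(fm, fm_prime) {
  if (any(fm_prime <= 0)) stop("fm_prime must be positive")
  (fm - fm_prime) / fm_prime
}

#' Electron transport rate from fluorescence
#'
#' \eqn{ETR = I \cdot \alpha \cdot fraction_{PSII} \cdot \Phi_{PSII}}.
#' The PSII fraction of absorbed light is conventionally 0.5; the absorbance
#' \code{alpha} used with this formula was 0.78 for Eiko and 0.55 for
#' MinnGold (the calibrated preset carries MinnGold's canopy-absorption value
#' 0.54; the small discrepancy between the two published MinnGold values is
#' retained as-is).
#'
#' @param i incident light, umol m-2 s-1.
#' @param alpha leaf absorbance in (0, 1].
#' @param phi_psii PSII operating efficiency ([phi_psii()]).
#' @param fraction_psii fraction of absorbed light reaching PSII, in [0, 1].
#' @return ETR, umol m-2 s-1.
#' @export
etr_from_fluorescence <- function(i, alpha, phi_psii, fraction_psii = 0.5) {
  stopifnot(all(fraction_psii >= 0), all(fraction_psii <= 1))
  i * alpha * fraction_psii * phi_psii
}

#' Leaf/canopy absorption coefficient from light balance
#'
#' Absorbed light is incident minus reflected minus transmitted:
#' \code{aPPFD = PPFD - PPFD * albedo - tPPFD}, and
#' \code{alpha = aPPFD / PPFD}.
#'
#' @param ppfd incident light, umol m-2 s-1 (> 0).
#' @param tppfd transmitted light, umol m-2 s-1, in [0, ppfd].
#' @param albedo reflected fraction, in [0, 1).
#' @return dimensionless absorption coefficient.
#' @examples
#' absorption_coefficient(1000, 160, 0.06)  # 0.78
#' @export
absorption_coefficient <- function(ppfd, tppfd, albedo) {
  stopifnot(all(ppfd > 0), all(albedo >= 0), all(albedo < 1),
            all(tppfd >= 0), all(tppfd <= ppfd))
  a <- (ppfd - ppfd * albedo - tppfd) / ppfd
  if (any(a < 0))
    stop("inconsistent readings: reflected plus transmitted exceeds incident")
  a
}

#' Coefficient of determination on parity pairs
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with residuals simulated minus observed
#' and total sum of squares about the observed mean — the parity-plot
#' statistic. Note this is not the squared Pearson correlation (it penalizes
#' bias); set \code{verbose = TRUE} to also get the squared correlation.
#'
#' @param observed,simulated numeric vectors of equal length (>= 2);
#'   \code{observed} must not be constant.
#' @param verbose if \code{TRUE}, return both definitions.
#' @return a number, or if \code{verbose} a named vector
#'   \code{c(R2 = , pearson_sq = )}.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(observed, simulated, verbose = FALSE) {
  stopifnot(length(observed) == length(simulated), length(observed) >= 2)
  ok <- stats::complete.cases(observed, simulated)
  observed <- observed[ok]; simulated <- simulated[ok]
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed series is constant; R^2 undefined")
  r2 <- 1 - sum((simulated - observed)^2) / ss_tot
  if (!verbose) return(r2)
  c(R2 = r2, pearson_sq = stats::cor(observed, simulated)^2)
}
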