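# Theoretical light-regime sweeps: how steady-state ETR, A and NPQ respond to
# the period and amplitude of square-wave light fluctuations, against a
# constant-light baseline delivering the same time-averaged PAR.

# Steady-state window for a fluctuation period P (s): whole-cycle averaging
# starting at the first whole-period boundary at or after 40 min. For periods
# up to 10 min this is exactly [2400, 3600] s (2400 is a whole multiple of
# every grid period); longer periods get a window of two whole cycles.
.steady_window <- function(period) {
  if (is.null(period) || period <= 0) return(c(2400, 3600))
  if (period <= 600) {
    start <- ceiling(2400 / period) * period
    c(start, max(start + 2 * period, 3600))
  } else {
    start <- ceiling(2400 / period) * period
    c(start, start + 2 * period)
  }
}

.sweep_point <- function(params, protocol, period, rtol, atol) {
  win <- .steady_window(period)
  sim <- simulate_leaf(params, protocol, duration = win[2],
                       output_step = 1, rtol = rtol, atol = atol)
  s <- steady_state_summary(sim, win[1], win[2])
  stats::setNames(s$mean, s$flux)
}

#' Sweep the fluctuation period of a square-wave light regime
#'
#' For each period, simulates the model under a square wave between
#' \code{high} and \code{low} (same time-averaged PAR as the constant
#' baseline) until an entrained steady state, then records the time-averaged
#' ETR, A and NPQ over a whole-cycle steady-state window starting at or after
#' 40 min. The constant-light baseline (the "period zero" regime) is included
#' as a row with \code{period_s = 0}.
#'
#' @param params a [leaf_params()] set.
#' @param periods fluctuation periods, s.
#' @param high,low square-wave levels, umol m-2 s-1.
#' @param duty duty cycle (default 0.5).
#' @param rtol,atol solver tolerances passed to [simulate_leaf()].
#' @return A data.frame of class \code{"light_sweep"} with columns
#'   \code{period_s}, \code{cum_ETR}, \code{cum_A}, \code{cum_NPQ} (means
#'   over the steady-state window, umol m-2 s-1) and \code{baseline}
#'   (logical).
#' @examples
#' \donttest{
#' sw <- period_sweep(leaf_params("eiko"), c(60, 300, 1200))
#' optimal_period(sw, "A")
#' }
#' @export
period_sweep <- function(params,
                         periods = 60 * c(0.5, 1, 2, 4, 5, 10, 15, 20, 25, 30),
                         high = 780, low = 520, duty = 0.5,
                         rtol = 1e-8, atol = 1e-10) {
  if (!length(periods)) stop("empty period list")
  base_level <- high * duty + low * (1 - duty)
  rows <- lapply(periods, function(P) {
    if (P <= 0) {
      .sweep_point(params, light_constant(base_level), 0, rtol, atol)
    } else {
      .sweep_point(params, light_square(high, low, period = P, duty = duty),
                   P, rtol, atol)
    }
  })
  base <- .sweep_point(params, light_constant(base_level), 0, rtol, atol)
  m <- do.call(rbind, c(rows, list(base)))
  out <- data.frame(period_s = c(periods, 0),
                    cum_ETR = m[, "ETR"], cum_A = m[, "A"],
                    cum_NPQ = m[, "NPQ"],
                    baseline = c(rep(FALSE, length(periods)), TRUE))
  out <- out[order(out$period_s), ]
  rownames(out) <- NULL
  class(out) <- c("light_sweep", "data.frame")
  attr(out, "swept") <- "period_s"
  attr(out, "mean_level") <- base_level
  out
}

#' Sweep the fluctuation amplitude at a fixed period
#'
#' Levels are \code{mean_level * (1 +/- a)} so every point delivers the same
#' time-averaged PAR; amplitude 0 is the constant baseline.
#'
#' @inheritParams period_sweep
#' @param amplitudes fractional amplitudes in [0, 1).
#' @param period fluctuation period, s (default 60, as in the experiment).
#' @param mean_level time-averaged PAR, umol m-2 s-1 (default 650).
#' @return A \code{"light_sweep"} data.frame with column \code{amplitude} in
#'   place of \code{period_s}.
#' @export
amplitude_sweep <- function(params, amplitudes, period = 60,
                            mean_level = 650, rtol = 1e-8, atol = 1e-10) {
  if (!length(amplitudes)) stop("empty amplitude list")
  if (any(amplitudes < 0 | amplitudes >= 1))
    stop("amplitudes must lie in [0, 1)")
  rows <- lapply(amplitudes, function(a) {
    if (a == 0) {
      .sweep_point(params, light_constant(mean_level), 0, rtol, atol)
    } else {
      .sweep_point(params,
                   light_square(mean_level * (1 + a), mean_level * (1 - a),
                                period = period),
                   period, rtol, atol)
    }
  })
  base <- .sweep_point(params, light_constant(mean_level), 0, rtol, atol)
  m <- do.call(rbind, c(rows, list(base)))
  out <- data.frame(amplitude = c(amplitudes, 0),
                    cum_ETR = m[, "ETR"], cum_A = m[, "A"],
                    cum_NPQ = m[, "NPQ"],
                    baseline = c(rep(FALSE, length(amplitudes)), TRUE))
  out <- out[order(out$amplitude), ]
  rownames(out) <- NULL
  class(out) <- c("light_sweep", "data.frame")
  attr(out, "swept") <- "amplitude"
  attr(out, "mean_level") <- mean_level
  out
}

.sweep_quantity <- function(sweep, quantity) {
  quantity <- match.arg(quantity, c("A", "ETR", "NPQ"))
  paste0("cum_", quantity)
}

#' Period maximizing a steady-state flux
#'
#' @param sweep a period [period_sweep()] result.
#' @param quantity \code{"A"} or \code{"ETR"} (or \code{"NPQ"}).
#' @return the swept period (s) with the largest steady-state mean; ties go
#'   to the shorter period. The baseline row is excluded.
#' @export
optimal_period <- function(sweep, quantity = "A") {
  col <- .sweep_quantity(sweep, quantity)
  pts <- sweep[!sweep$baseline, ]
  pts <- pts[order(pts$period_s), ]
  pts$period_s[which.max(pts[[col]])]
}

#' Crossover periods against the constant-light baseline
#'
#' Locates, by linear interpolation between bracketing sweep points, the two
#' fluctuation periods where the steady-state value of a flux crosses the
#' constant-light baseline: below the low crossover and above the high
#' crossover the fluctuating regime does no better than constant light.
#'
#' @inheritParams optimal_period
#' @return named numeric vector \code{c(low = , high = )} in seconds; an end
#'   is \code{NA} when the sweep does not bracket that sign change (open
#'   interval end).
#' @export
crossover_periods <- function(sweep, quantity = "A") {
  col <- .sweep_quantity(sweep, quantity)
  base <- sweep[sweep$baseline, col][1]
  pts <- sweep[!sweep$baseline, ]
  pts <- pts[order(pts$period_s), ]
  diffs <- pts[[col]] - base
  cross <- numeric(0)
  for (i in seq_len(nrow(pts) - 1)) {
    if (diffs[i] == 0) next
    if (diffs[i] * diffs[i + 1] < 0) {
      x0 <- pts$period_s[i]; x1 <- pts$period_s[i + 1]
      cross <- c(cross, x0 + (x1 - x0) * diffs[i] / (diffs[i] - diffs[i + 1]))
    }
  }
  low <- if (length(cross) >= 1 && diffs[1] < 0) cross[1] else NA_real_
  high <- if (length(cross) >= 1 && diffs[length(diffs)] < 0)
    cross[length(cross)] else NA_real_
  c(low = low, high = high)
}
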