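# Deterministic light protocols: piecewise-constant incident PAR with exact
# switch-time enumeration so the integrator never steps across a
# discontinuity.

new_light_protocol <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "light_protocol")
}

#' Light protocols
#'
#' Deterministic mappings from time (seconds) to incident PAR
#' (umol m-2 s-1). \code{light_constant} holds one level; \code{light_square}
#' alternates between \code{high} and \code{low} with the given period and
#' duty cycle (fraction of each period spent at \code{high});
#' \code{light_dark} is constant darkness. Evaluation is piecewise constant
#' and right-continuous at switches. The measurement protocols are constant
#' 650 for 60 min, and a square wave between 780 and 520 with a 1-min period
#' (30 s high, 30 s low), starting on the high phase after dark adaptation.
#'
#' @param level,high,low light levels, umol m-2 s-1 (non-negative).
#' @param period period of the square wave, s (> 0).
#' @param duty fraction of each period at the high level, in (0, 1).
#' @param phase \code{"start_high"} (default) or \code{"start_low"}.
#' @param flash_boost if \code{TRUE}, add a uniform 20\% to the emitted PAR,
#'   approximating the average extra flux contributed by the saturating
#'   fluorometer flashes fired every 30 s. Off by default: the model is
#'   calibrated against nominal intensities.
#' @return an object of class \code{"light_protocol"}.
#' @examples
#' fl <- light_square(780, 520, period = 120)
#' par_at(fl, c(0, 30, 59.9, 60, 90))
#' @export
light_constant <- function(level, flash_boost = FALSE) {
  stopifnot(is.numeric(level), length(level) == 1, level >= 0)
  new_light_protocol("constant", list(level = level, flash_boost = flash_boost))
}

#' @rdname light_constant
#' @export
light_square <- function(high, low, period, duty = 0.5,
                         phase = c("start_high", "start_low"),
                         flash_boost = FALSE) {
  phase <- match.arg(phase)
  stopifnot(high >= 0, low >= 0, period > 0, duty > 0, duty < 1)
  new_light_protocol("square_wave",
                     list(high = high, low = low, period = period,
                          duty = duty, phase = phase,
                          flash_boost = flash_boost))
}

#' @rdname light_constant
#' @export
light_dark <- function() light_constant(0)

#' @export
print.light_protocol <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("Light protocol: constant %g umol m-2 s-1\n", x$level))
  } else {
    cat(sprintf(
      "Light protocol: square wave %g/%g umol m-2 s-1, period %g s, duty %g, %s\n",
      x$high, x$low, x$period, x$duty, x$phase))
  }
  invisible(x)
}

#' Evaluate a light protocol
#'
#' @param protocol a \code{light_protocol}.
#' @param t numeric vector of times, s (>= 0).
#' @return incident PAR at each time, umol m-2 s-1.
#' @export
par_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "light_protocol"), all(t >= 0))
  out <- if (protocol$kind == "constant") {
    rep(protocol$level, length(t))
  } else {
    frac <- (t %% protocol$period) / protocol$period
    on_first <- frac < protocol$duty
    first <- if (protocol$phase == "start_high") protocol$high else protocol$low
    second <- if (protocol$phase == "start_high") protocol$low else protocol$high
    ifelse(on_first, first, second)
  }
  if (isTRUE(protocol$flash_boost)) out <- out * 1.2
  out
}

#' Enumerate light discontinuities
#'
#' All switch times of a protocol strictly inside \code{(t0, t1)}, sorted and
#' unique; used to segment ODE integration so no solver step straddles a light
#' discontinuity.
#'
#' @param protocol a \code{light_protocol}.
#' @param t0,t1 window bounds, s, with \code{t0 < t1}.
#' @return numeric vector of times (possibly empty).
#' @examples
#' switch_times(light_square(780, 520, period = 120), 0, 240)
#' @export
switch_times <- function(protocol, t0, t1) {
  stopifnot(inherits(protocol, "light_protocol"), t0 < t1)
  if (protocol$kind == "constant") return(numeric(0))
  P <- protocol$period
  d <- protocol$duty
  k <- seq(floor(t0 / P) - 1, ceiling(t1 / P) + 1)
  cand <- sort(unique(c(k * P, k * P + d * P)))
  cand[cand > t0 & cand < t1]
}

#' Time-averaged PAR of a protocol
#'
#' Mean incident light over \code{[t0, t1]}, exact for piecewise-constant
#' protocols (integrates each constant piece).
#' @inheritParams switch_times
#' @return mean PAR, umol m-2 s-1.
#' @export
mean_par <- function(protocol, t0, t1) {
  edges <- c(t0, switch_times(protocol, t0, t1), t1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  sum(par_at(protocol, mids) * diff(edges)) / (t1 - t0)
}
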