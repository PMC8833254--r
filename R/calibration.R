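# Calibration of the 13 kinetic parameters against observed (ETR, A, NPQ)
# series: range-normalized least squares on replicate means, bound-constrained
# Levenberg-Marquardt (minpack.lm) with log-scale multistart.

# Internal parameterization: log for the 12 strictly positive calibrated
# parameters, identity for c_y (sign-unrestricted).
.to_opt <- function(p) {
  v <- unlist(p[.calibrated_names])
  v[names(v) != "c_y"] <- log(v[names(v) != "c_y"])
  v
}
.from_opt <- function(v, alpha) {
  out <- v
  out[names(out) != "c_y"] <- exp(out[names(out) != "c_y"])
  validate_leaf_params(c(alpha = alpha, out[.calibrated_names]))
}

.sim_at_data <- function(params, data) {
  proto <- attr(data, "protocol")
  if (is.null(proto)) stop("observed series carries no protocol")
  mns <- replicate_means(data)
  dur <- max(mns$time_s)
  step <- min(diff(sort(unique(mns$time_s))))
  sim <- simulate_leaf(params, proto, duration = dur, output_step = step)
  idx <- match(round(mns$time_s / step), round(sim$times / step))
  list(means = mns, sim = sim$fluxes[idx, c("ETR", "A", "NPQ")])
}

# Residual vector: per quantity, (simulated - observed mean) / range(observed
# mean) / sqrt(n), so the summed squares equal the objective below.
.residuals <- function(params, data, cache_means = NULL) {
  sa <- .sim_at_data(params, data)
  n <- nrow(sa$means)
  unlist(lapply(c("ETR", "A", "NPQ"), function(q) {
    rng <- diff(range(sa$means[[q]]))
    if (rng == 0) stop("observed ", q, " is constant; cannot normalize")
    (sa$sim[, q] - sa$means[[q]]) / rng / sqrt(n)
  }))
}

#' Calibration objective
#'
#' Sum over the three quantities of the mean squared residual between the
#' simulated flux (sampled at the data times) and the replicate-mean data,
#' each quantity normalized by the range of its observed mean so ETR (~100)
#' and NPQ (~1-3) weigh comparably. A failed simulation yields a large
#' finite penalty with a warning rather than an error, so optimizer
#' line searches can back off.
#'
#' @param candidate a [leaf_params()] set.
#' @param data an [observed_series()].
#' @return scalar >= 0.
#' @export
objective <- function(candidate, data) {
  r <- tryCatch(.residuals(candidate, data), error = function(e) {
    warning("simulation failed for candidate: ", conditionMessage(e))
    NULL
  })
  if (is.null(r)) return(1e6)
  sum(r^2)
}

#' Default calibration bounds
#'
#' Per-parameter search intervals: \code{[0.1x, 10x]} the reference value for
#' the 12 strictly positive calibrated parameters, and \code{[-10, 10]}
#' (additive) for \code{c_y} — the physically plausible regime around the
#' published values.
#'
#' @param params reference [leaf_params()] set.
#' @return list with matrices/vectors \code{lower}, \code{upper} named by
#'   calibrated parameter.
#' @export
default_bounds <- function(params) {
  params <- validate_leaf_params(params)
  v <- unlist(unclass(params))[.calibrated_names]
  lower <- v / 10; upper <- v * 10
  lower["c_y"] <- -10; upper["c_y"] <- 10
  list(lower = lower, upper = upper)
}

#' Calibrate the model to observed series
#'
#' Multi-start bound-constrained least squares: starting points are jittered
#' on the log scale (uniformly within \code{[1-jitter, 1+jitter]} factors of
#' \code{start}, or log-uniformly across the bounds when \code{start} is
#' \code{NULL}), each start refined by Levenberg-Marquardt
#' (\code{minpack.lm::nls.lm}) on the residual vector of [objective()], and
#' the best converged start returned. Deterministic given \code{seed}.
#'
#' @param data an [observed_series()] with its protocol attribute.
#' @param bounds list with \code{lower}/\code{upper} named vectors over the
#'   13 calibrated parameters (default [default_bounds()] around
#'   \code{start}).
#' @param n_starts number of starts (default 10).
#' @param seed integer seed for the start jitter.
#' @param start optional [leaf_params()] around which to start (defaults to
#'   the preset matching the series' variety attribute, else "eiko").
#' @param jitter multiplicative half-width of the start jitter (default 0.3).
#' @param alpha fixed absorption coefficient (default: from \code{start}).
#' @param maxiter per-start Levenberg-Marquardt iteration cap.
#' @return object of class \code{"leaf_fit"}: fitted parameters, objective,
#'   per-quantity parity R-squared, per-start diagnostics, the data, and the
#'   seed. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{residuals}, \code{plot}.
#' @export
calibrate <- function(data, bounds = NULL, n_starts = 10, seed = 1,
                      start = NULL, jitter = 0.3, alpha = NULL,
                      maxiter = 60) {
  stopifnot(n_starts >= 1)
  if (is.null(start)) {
    v <- attr(data, "variety")
    start <- if (!is.na(v) && v %in% names(.presets)) leaf_params(v)
    else leaf_params("eiko")
  }
  start <- validate_leaf_params(start)
  if (is.null(alpha)) alpha <- start[["alpha"]]
  if (is.null(bounds)) bounds <- default_bounds(start)
  lower <- bounds$lower[.calibrated_names]
  upper <- bounds$upper[.calibrated_names]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper")

  lo_opt <- lower; hi_opt <- upper
  pos <- .calibrated_names != "c_y"
  lo_opt[pos] <- log(lower[pos]); hi_opt[pos] <- log(upper[pos])

  starts <- .with_seed(seed, {
    lapply(seq_len(n_starts), function(k) {
      if (k == 1) return(.to_opt(unclass(start)))  # first start unjittered
      v <- .to_opt(unclass(start))
      v[pos] <- v[pos] + log(stats::runif(sum(pos), 1 - jitter, 1 + jitter))
      v["c_y"] <- v["c_y"] * stats::runif(1, 1 - jitter, 1 + jitter)
      pmin(pmax(v, lo_opt), hi_opt)
    })
  })

  fn <- function(v) {
    p <- .from_opt(v, alpha)
    tryCatch(.residuals(p, data),
             error = function(e) rep(1e3, 3 * nrow(replicate_means(data))))
  }

  fits <- lapply(starts, function(v0) {
    tryCatch(
      minpack.lm::nls.lm(par = v0, lower = lo_opt, upper = hi_opt, fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-10, ftol = 1e-12)),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all calibration starts failed")
  dev <- vapply(fits, function(f) if (is.null(f)) Inf else f$deviance,
                numeric(1))
  best <- which.min(dev)
  fitted <- .from_opt(fits[[best]]$par, alpha)

  sa <- .sim_at_data(fitted, data)
  r2 <- vapply(c("ETR", "A", "NPQ"),
               function(q) r_squared(sa$means[[q]], sa$sim[, q]), numeric(1))

  structure(list(
    params = fitted, objective = dev[best], r_squared = r2,
    data = data,
    diagnostics = data.frame(
      start = seq_along(fits),
      objective = dev,
      converged = vapply(fits, function(f)
        !is.null(f) && f$info %in% 1:4, logical(1)),
      iterations = vapply(fits, function(f)
        if (is.null(f)) NA_integer_ else f$niter, integer(1))),
    best_start = best, seed = seed, alpha = alpha),
    class = "leaf_fit")
}

#' Validate a parameter set against observed series
#'
#' Simulates under the series' protocol with fixed parameters and returns the
#' parity R-squared per quantity — the out-of-protocol test when the series
#' comes from a different light regime than the one calibrated on.
#'
#' @param params a [leaf_params()] set.
#' @param data an [observed_series()].
#' @return named numeric vector \code{c(ETR =, A =, NPQ =)}.
#' @export
validate <- function(params, data) {
  sa <- .sim_at_data(validate_leaf_params(params), data)
  vapply(c("ETR", "A", "NPQ"),
         function(q) r_squared(sa$means[[q]], sa$sim[, q]), numeric(1))
}

#' @export
print.leaf_fit <- function(x, ...) {
  cat("Calibrated chloroplast model\n")
  cat(sprintf("  objective: %.3e (best of %d starts, seed %d)\n",
              x$objective, nrow(x$diagnostics), x$seed))
  cat(sprintf("  parity R^2: ETR %.4f, A %.4f, NPQ %.4f\n",
              x$r_squared["ETR"], x$r_squared["A"], x$r_squared["NPQ"]))
  invisible(x)
}

#' @export
summary.leaf_fit <- function(object, ...) {
  cat("Calibrated chloroplast model\n\nFitted parameters:\n")
  print(unclass(object$params))
  cat(sprintf("\nObjective: %.6e\nParity R^2:\n", object$objective))
  print(object$r_squared)
  cat("\nStart diagnostics:\n")
  print(object$diagnostics)
  invisible(object)
}

#' @export
coef.leaf_fit <- function(object, ...) {
  unlist(unclass(object$params))[.calibrated_names]
}

#' @export
#' @param newprotocol optional protocol to simulate under (default: the
#'   protocol of the calibration data).
#' @param duration,output_step simulation grid for prediction.
#' @rdname calibrate
predict.leaf_fit <- function(object, newprotocol = NULL, duration = NULL,
                             output_step = 30, ...) {
  proto <- if (is.null(newprotocol)) attr(object$data, "protocol")
  else newprotocol
  if (is.null(duration)) duration <- max(object$data$time_s)
  simulate_leaf(object$params, proto, duration, output_step = output_step)
}

#' @export
residuals.leaf_fit <- function(object, ...) {
  sa <- .sim_at_data(object$params, object$data)
  data.frame(time_s = sa$means$time_s,
             ETR = sa$sim[, "ETR"] - sa$means$ETR,
             A = sa$sim[, "A"] - sa$means$A,
             NPQ = sa$sim[, "NPQ"] - sa$means$NPQ)
}

#' @export
plot.leaf_fit <- function(x, ...) {
  sa <- .sim_at_data(x$params, x$data)
  old <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (q in c("ETR", "A", "NPQ")) {
    graphics::plot(sa$means$time_s / 60, sa$means[[q]], col = "red",
                   pch = 16, cex = 0.5, xlab = "time (min)", ylab = q, ...)
    graphics::lines(sa$means$time_s / 60, sa$sim[, q])
  }
  invisible(x)
}
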