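# Local sensitivity analysis: standardized elementary effects of the 13
# calibrated parameters on the simulated ETR, A and NPQ series.

#' Default sensitivity scenario
#'
#' The 60-min fluctuating-light measurement protocol (780/520 umol m-2 s-1,
#' 1-min period, duty 0.5, starting high) sampled on a 30-s output grid
#' (121 samples per quantity).
#'
#' @return list with elements \code{protocol}, \code{duration} (s) and
#'   \code{output_step} (s).
#' @export
sensitivity_scenario <- function() {
  list(protocol = light_square(780, 520, period = 120),
       duration = 3600, output_step = 30)
}

.scenario_fluxes <- function(params, scenario, rtol, atol) {
  sim <- simulate_leaf(params, scenario$protocol, scenario$duration,
                       output_step = scenario$output_step,
                       rtol = rtol, atol = atol)
  sim$fluxes[, c("NPQ", "ETR", "A")]
}

.sens_index <- function(base, pert) {
  rng <- apply(base, 2, function(x) diff(range(x)))
  if (any(rng == 0))
    stop("degenerate normalization: a baseline output has zero range")
  n <- nrow(base)
  sum(sweep(pert - base, 2, rng, "/")^2) / (3 * n)
}

#' Standardized sensitivity index of one parameter
#'
#' Perturbs one calibrated parameter by a signed fraction \code{delta},
#' re-simulates the scenario, and aggregates the deviation of the NPQ, ETR
#' and A output series from the baseline, each sample normalized by the
#' baseline range of its quantity:
#' \deqn{SSE_{i,\Delta} = \frac{1}{3n} \sum_{j=1}^{3} \sum_{i=1}^{n}
#'   \left(\frac{X_j^{pert}(t_i) - X_j(t_i)}{\max X_j - \min X_j}\right)^2}
#' The headline scale is \code{percent_deviation = 100 * sqrt(index)}.
#'
#' @param params a [leaf_params()] set (baseline).
#' @param name one of [calibrated_parameters()].
#' @param delta signed perturbation fraction (e.g. 0.05 or -0.05).
#' @param scenario list as returned by [sensitivity_scenario()].
#' @param rtol,atol solver tolerances.
#' @return one-row data.frame: \code{parameter}, \code{delta}, \code{index},
#'   \code{percent_deviation}.
#' @export
sensitivity_index <- function(params, name, delta,
                              scenario = sensitivity_scenario(),
                              rtol = 1e-8, atol = 1e-10) {
  params <- validate_leaf_params(params)
  if (!name %in% .calibrated_names)
    stop("'", name, "' is not a calibrated parameter")
  base <- .scenario_fluxes(params, scenario, rtol, atol)
  pp <- unclass(params)
  pp[[name]] <- pp[[name]] * (1 + delta)
  pert <- .scenario_fluxes(validate_leaf_params(pp), scenario, rtol, atol)
  idx <- if (delta == 0) 0 else .sens_index(base, pert)
  data.frame(parameter = name, delta = delta, index = idx,
             percent_deviation = 100 * sqrt(idx))
}

#' Sensitivity sweep over all calibrated parameters
#'
#' Both signs of the perturbation for each of the 13 calibrated parameters
#' (26 rows). The baseline is simulated once.
#'
#' @inheritParams sensitivity_index
#' @param delta unsigned perturbation fraction (default 0.05).
#' @return data.frame with 26 rows, columns as in [sensitivity_index()].
#' @export
sensitivity_sweep <- function(params, delta = 0.05,
                              scenario = sensitivity_scenario(),
                              rtol = 1e-8, atol = 1e-10) {
  params <- validate_leaf_params(params)
  base <- .scenario_fluxes(params, scenario, rtol, atol)
  rows <- list()
  for (name in .calibrated_names) {
    for (sgn in c(1, -1)) {
      d <- sgn * delta
      pp <- unclass(params)
      pp[[name]] <- pp[[name]] * (1 + d)
      pert <- .scenario_fluxes(validate_leaf_params(pp), scenario, rtol, atol)
      idx <- if (d == 0) 0 else .sens_index(base, pert)
      rows[[length(rows) + 1]] <-
        data.frame(parameter = name, delta = d, index = idx,
                   percent_deviation = 100 * sqrt(idx))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
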