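# CSV/JSON writers and run-config handling shared by the CLI and scripts.

.write_numeric_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulation trajectory as CSV
#'
#' Columns \code{time_s, par, E_PSII, Q, P_NPQ, NADPH, NADPplus, R, ETR, A,
#' NPQ}, one header line; the run configuration (protocol, parameters,
#' solver settings) is echoed to a JSON sidecar \code{<path>.json}.
#'
#' @param sim a \code{leaf_sim} from [simulate_leaf()].
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  stopifnot(inherits(sim, "leaf_sim"))
  .write_numeric_csv(as.data.frame(sim), path)
  side <- list(protocol = unclass(sim$protocol),
               params = as.list(unclass(sim$params)),
               solver = sim$solver[c("method", "rtol", "atol")])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) utils::read.csv(path)

#' Write a sweep result as CSV
#'
#' Columns: the swept variable (\code{period_s} or \code{amplitude}),
#' \code{cum_ETR}, \code{cum_A}, \code{cum_NPQ}, \code{baseline}.
#'
#' @param sweep a \code{light_sweep} from [period_sweep()] or
#'   [amplitude_sweep()].
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  .write_numeric_csv(as.data.frame(sweep), path)
}

#' Resolve a run configuration
#'
#' Reads a JSON or YAML config of the form \code{{params: preset-or-map,
#' protocol: {kind, level | high/low/period_s/duty/phase}, duration_min,
#' output_step_s, seed, solver: {rtol, atol}}} into ready-to-use objects.
#'
#' @param path config file path (extension selects JSON or YAML).
#' @return list with \code{params}, \code{protocol}, \code{duration} (s),
#'   \code{output_step} (s), \code{seed}, \code{rtol}, \code{atol}.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  params <- if (is.character(cfg$params)) leaf_params(cfg$params)
  else validate_leaf_params(unlist(cfg$params))
  pr <- cfg$protocol
  protocol <- switch(
    pr$kind,
    constant = light_constant(pr$level),
    dark = light_dark(),
    square_wave = light_square(pr$high, pr$low, pr$period_s,
                               duty = if (is.null(pr$duty)) 0.5 else pr$duty,
                               phase = if (is.null(pr$phase)) "start_high"
                               else pr$phase),
    stop("unknown protocol kind: ", pr$kind))
  list(params = params, protocol = protocol,
       duration = (if (is.null(cfg$duration_min)) 60 else cfg$duration_min) * 60,
       output_step = if (is.null(cfg$output_step_s)) 1 else cfg$output_step_s,
       seed = if (is.null(cfg$seed)) 1 else cfg$seed,
       rtol = if (is.null(cfg$solver$rtol)) 1e-8 else cfg$solver$rtol,
       atol = if (is.null(cfg$solver$atol)) 1e-10 else cfg$solver$atol)
}
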