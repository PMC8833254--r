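# Model parameters and initial state.

# Internal ordering shared with src/leafode.c (PAR is appended as element 15
# by the simulator).
.param_names <- c("alpha", "c_in", "E_star_PSII", "v_ETR", "v_d", "Q_star",
                  "v_NPQ", "v_p", "v_C", "eta_NADPH", "eta_NADPplus",
                  "v_R", "d", "c_y")

# The 13 calibrated parameters; alpha (and PAR) are fixed by measurement.
.calibrated_names <- setdiff(.param_names, "alpha")

.state_names <- c("E_PSII", "Q", "P_NPQ", "NADPH", "NADPplus", "R")

.presets <- list(
  eiko = c(alpha = 0.78, c_in = 0.23, E_star_PSII = 157.56, v_ETR = 0.78,
           v_d = 0.08, Q_star = 0.07, v_NPQ = 70.58, v_p = 0.07,
           v_C = 11.75, eta_NADPH = 5.07, eta_NADPplus = 0.89,
           v_R = 8.9e-4, d = 8.40, c_y = -4),
  minngold = c(alpha = 0.54, c_in = 0.25, E_star_PSII = 9.98, v_ETR = 11.56,
               v_d = 7.00, Q_star = 0.03, v_NPQ = 53.87, v_p = 0.01,
               v_C = 13.04, eta_NADPH = 4.10, eta_NADPplus = 0.75,
               v_R = 14e-4, d = 3.69, c_y = 0)
)

#' Kinetic parameter set of the chloroplast model
#'
#' Constructs and validates the 14 quantities governing the six-state model:
#' the fixed light absorption coefficient \code{alpha} plus the 13 calibrated
#' kinetic parameters. Two named presets, \code{"eiko"} (green wild-type
#' soybean) and \code{"minngold"} (chlorophyll-deficient mutant), carry the
#' published calibrated values.
#'
#' @param preset \code{"eiko"}, \code{"minngold"}, or \code{NULL} to build a
#'   set from the named arguments alone.
#' @param ... named parameter overrides. Names: \code{alpha} (absorption
#'   coefficient, 0--1), \code{c_in} (energy input coefficient),
#'   \code{E_star_PSII} (PSII energy carrying capacity, umol m-2),
#'   \code{v_ETR} (velocity of linear electron transport, s-1), \code{v_d}
#'   (velocity of energy dissipation, s-1), \code{Q_star} (quenching-complex
#'   carrying capacity, umol m-2), \code{v_NPQ} (velocity of NPQ, s-1),
#'   \code{v_p} (max velocity of NPQ-protein activation, s-1), \code{v_C}
#'   (max velocity of Calvin-cycle reactions, s-1), \code{eta_NADPH} and
#'   \code{eta_NADPplus} (efficiencies, dimensionless), \code{v_R} (max
#'   velocity of Rubisco activation, s-1), \code{d} (maximum delta-pH balance
#'   value), \code{c_y} (minimum cyclic electron flow triggering NPQ-protein
#'   activation, umol m-2 s-1; may be negative).
#' @return A named numeric vector of class \code{"leaf_params"}.
#' @examples
#' p <- leaf_params("eiko")
#' p["v_ETR"]
#' leaf_params("eiko", v_C = 12)
#' @export
leaf_params <- function(preset = NULL, ...) {
  over <- unlist(list(...))
  if (is.null(preset)) {
    p <- over
  } else {
    preset <- match.arg(preset, names(.presets))
    p <- .presets[[preset]]
    if (length(over)) {
      bad <- setdiff(names(over), .param_names)
      if (length(bad))
        stop("unknown parameter(s): ", paste(bad, collapse = ", "))
      p[names(over)] <- over
    }
  }
  validate_leaf_params(p)
}

#' @rdname leaf_params
#' @param x object to validate or test.
#' @export
validate_leaf_params <- function(x) {
  x <- unclass(x)
  missing <- setdiff(.param_names, names(x))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  x <- x[.param_names]
  if (anyNA(x) || !is.numeric(x))
    stop("parameters must be numeric and non-missing")
  pos <- setdiff(.param_names, "c_y")
  if (any(x[pos] <= 0))
    stop("parameter(s) must be strictly positive: ",
         paste(pos[x[pos] <= 0], collapse = ", "))
  if (x[["alpha"]] > 1) stop("alpha must lie in (0, 1]")
  structure(x, class = "leaf_params")
}

#' @export
print.leaf_params <- function(x, ...) {
  cat("Chloroplast model parameters\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Names of the calibrated parameters
#'
#' The 13 kinetic parameters adjusted during calibration; \code{alpha} and the
#' incident light are fixed by direct measurement.
#' @return character vector of length 13.
#' @export
calibrated_parameters <- function() .calibrated_names

#' Dark-adapted initial state
#'
#' State of the model at the start of every protocol: a dark-adapted leaf with
#' no excitation energy in PSII, no quenching complex, inactive NPQ proteins,
#' balanced NADPH/NADP+ pools (5 and 5), and Rubisco nearly fully deactivated
#' (activation level 0.001).
#'
#' @return named numeric vector with elements \code{E_PSII}, \code{Q},
#'   \code{P_NPQ}, \code{NADPH}, \code{NADPplus}, \code{R}.
#' @examples
#' initial_state()
#' @export
initial_state <- function() {
  c(E_PSII = 0, Q = 0, P_NPQ = 0, NADPH = 5, NADPplus = 5, R = 0.001)
}

#' Read and write parameter sets as flat key/value configs
#'
#' Parameter sets serialize to a flat JSON or YAML mapping whose keys are
#' exactly the parameter names, so a set round-trips losslessly.
#'
#' @param params a \code{leaf_params} object.
#' @param path file path; format chosen by extension (\code{.json},
#'   \code{.yml}/\code{.yaml}).
#' @return \code{read_params} returns a \code{leaf_params};
#'   \code{write_params} returns \code{path} invisibly.
#' @export
write_params <- function(params, path) {
  params <- validate_leaf_params(params)
  lst <- as.list(unclass(params))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lapply(lst, unname), path, precision = 17)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_leaf_params(unlist(lst))
}
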