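# Right-hand side of the six-state chloroplast model and its derived fluxes,
# in plain R. The production simulator integrates the compiled C copy of the
# same equations (src/leafode.c); this R version backs the elementary
# operations, the fixed-step reference integrator, and tests.

.pool_eps <- 1e-9

.check_state <- function(state) {
  missing <- setdiff(.state_names, names(state))
  if (length(missing))
    stop("missing state variable(s): ", paste(missing, collapse = ", "))
  if (state[["NADPplus"]] < 0 || state[["NADPH"]] < 0)
    stop("degenerate pool: NADPH/NADP+ must be non-negative")
  invisible(state)
}

#' Cyclic electron flow
#'
#' The excess of the PSII energy-input term over linear electron transport:
#' \deqn{CEF = \alpha c_{in} PAR (1 - E_{PSII}/E^*_{PSII}) - v_{ETR} E_{PSII} NADP^+}
#' Positive CEF means the light reactions outrun the downstream electron sink;
#' when CEF exceeds the threshold \code{c_y} the NPQ-protein activation is
#' switched on. CEF may be negative.
#'
#' @param state named state vector (see [initial_state()]).
#' @param par incident light, umol m-2 s-1.
#' @param params a [leaf_params()] set.
#' @return flux in umol m-2 s-1.
#' @examples
#' compute_cef(initial_state(), 650, leaf_params("eiko"))
#' @export
compute_cef <- function(state, par, params) {
  params <- validate_leaf_params(params)
  .check_state(state)
  input <- params[["alpha"]] * params[["c_in"]] * par *
    (1 - state[["E_PSII"]] / params[["E_star_PSII"]])
  etr <- params[["v_ETR"]] * state[["E_PSII"]] * state[["NADPplus"]]
  unname(input - etr)
}

# Unchecked scalar RHS used in inner loops (fixed-step integration); params
# must already be validated, state ordered as .state_names.
.leaf_rhs <- function(y, par, params) {
  E <- y[[1]]; Q <- y[[2]]; P <- y[[3]]
  NADPH <- y[[4]]; NADPplus <- y[[5]]; R <- y[[6]]
  input <- params[[1]] * params[[2]] * par * (1 - E / params[[3]])
  etr  <- params[[4]] * E * NADPplus
  diss <- params[[5]] * E * P * (1 - Q / params[[6]])
  dNADPH <- etr * params[[11]] - params[[9]] * R * NADPH * params[[10]]
  c(input - etr - diss,
    diss - params[[7]] * Q,
    if (input - etr > params[[14]]) params[[8]] * (1 - P) else 0,
    dNADPH,
    -dNADPH,
    params[[12]] * (1 - R) * min(params[[13]], NADPH / max(NADPplus, .pool_eps)))
}

#' Time derivatives of the six state variables
#'
#' Evaluates the model's right-hand side at one instant. Energy enters PSII
#' logistically, leaves as linear electron transport (ETR, proportional to
#' NADP+) or as heat via the quenching complex Q; NPQ proteins activate
#' (saturating toward 1) whenever cyclic electron flow exceeds \code{c_y};
#' NADPH is produced by ETR and consumed by the Calvin cycle; Rubisco
#' activates (saturating toward 1) at a rate set by min(d, NADPH/NADP+),
#' the NADPH/NADP+ ratio standing in for the transmembrane delta-pH.
#'
#' @inheritParams compute_cef
#' @return named numeric vector of d(state)/dt, one element per state
#'   variable, in the units of the state per second.
#' @examples
#' leaf_derivs(initial_state(), 650, leaf_params("eiko"))
#' @export
leaf_derivs <- function(state, par, params) {
  params <- validate_leaf_params(params)
  .check_state(state)
  if (par < 0) stop("par must be non-negative")
  E <- state[["E_PSII"]]; Q <- state[["Q"]]; P <- state[["P_NPQ"]]
  NADPH <- state[["NADPH"]]; NADPplus <- state[["NADPplus"]]; R <- state[["R"]]

  input <- params[["alpha"]] * params[["c_in"]] * par *
    (1 - E / params[["E_star_PSII"]])
  etr  <- params[["v_ETR"]] * E * NADPplus
  diss <- params[["v_d"]] * E * P * (1 - Q / params[["Q_star"]])
  cef  <- input - etr
  dph  <- NADPH / max(NADPplus, .pool_eps)

  dNADPH <- etr * params[["eta_NADPplus"]] -
    params[["v_C"]] * R * NADPH * params[["eta_NADPH"]]

  c(E_PSII = input - etr - diss,
    Q = diss - params[["v_NPQ"]] * Q,
    P_NPQ = if (cef > params[["c_y"]]) params[["v_p"]] * (1 - P) else 0,
    NADPH = dNADPH,
    NADPplus = -dNADPH,
    R = params[["v_R"]] * (1 - R) * min(params[["d"]], dph))
}

#' Derived fluxes at one instant
#'
#' The three measurable fluxes plus the two auxiliary quantities of the model:
#' linear electron transport \code{ETR = v_ETR * E_PSII * NADP+}, heat
#' dissipation \code{NPQ = v_NPQ * Q}, carbon assimilation
#' \code{A = v_C * R * NADPH}, cyclic electron flow ([compute_cef()]), and
#' \code{delta_pH = NADPH / NADP+} (ratio guarded against a vanishing NADP+
#' pool).
#'
#' @inheritParams compute_cef
#' @return named numeric vector with elements \code{ETR}, \code{NPQ},
#'   \code{A}, \code{CEF}, \code{delta_pH}.
#' @examples
#' compute_fluxes(initial_state(), 650, leaf_params("eiko"))
#' @export
compute_fluxes <- function(state, par, params) {
  params <- validate_leaf_params(params)
  .check_state(state)
  c(ETR = params[["v_ETR"]] * state[["E_PSII"]] * state[["NADPplus"]],
    NPQ = params[["v_NPQ"]] * state[["Q"]],
    A = params[["v_C"]] * state[["R"]] * state[["NADPH"]],
    CEF = compute_cef(state, par, params),
    delta_pH = state[["NADPH"]] / max(state[["NADPplus"]], .pool_eps))
}
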