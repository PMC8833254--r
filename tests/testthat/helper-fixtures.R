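# Shared fixtures: published parameter presets, measurement protocols, and a
# generator of random-but-plausible parameter sets for property tests.

eiko <- leaf_params("eiko")
minngold <- leaf_params("minngold")
fluct_protocol <- light_square(780, 520, period = 120)
const_protocol <- light_constant(650)

# log-uniform jitter of the Eiko set within [1/f, f]; c_y uniform in [-5, 5]
random_params <- function(f = 2) {
  v <- unclass(eiko)
  pos <- names(v) != "c_y"
  v[pos] <- v[pos] * exp(runif(sum(pos), -log(f), log(f)))
  v["alpha"] <- min(v[["alpha"]], 1)
  v["c_y"] <- runif(1, -5, 5)
  validate_leaf_params(v)
}

random_square <- function() {
  low <- runif(1, 200, 600)
  light_square(high = low + runif(1, 50, 400), low = low,
               period = runif(1, 20, 600), duty = runif(1, 0.2, 0.8))
}

# random interior state respecting the invariant box
random_state <- function(params) {
  nadph <- runif(1, 0.5, 9.5)
  c(E_PSII = runif(1, 0, params[["E_star_PSII"]]),
    Q = runif(1, 0, params[["Q_star"]]),
    P_NPQ = runif(1), NADPH = nadph, NADPplus = 10 - nadph,
    R = runif(1))
}
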