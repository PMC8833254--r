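---
title: "Modelling leaf photosynthesis under fluctuating light"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling leaf photosynthesis under fluctuating light}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(photodyn)
```

## The model

`photodyn` implements a system-dynamics ("stocks and flows") model of the
light reactions of C3 photosynthesis in a single chloroplast standing in for
a whole leaf. Six state variables are tracked:

* $E_{PSII}$ — excitation energy held by photosystem II (µmol m⁻²),
* $Q$ — the quenching complex formed by activated NPQ proteins bound to
  PSII (µmol m⁻²),
* $P_{NPQ}$ — the activation level of the NPQ-related proteins (PsbS
  protonation and zeaxanthin formation combined into one variable), in
  $[0, 1]$,
* $NADPH$ and $NADP^{+}$ — the stromal redox pools (dimensionless, their
  sum is conserved),
* $R$ — Rubisco activation level in $[0, 1]$.

The dynamics are

$$
\begin{aligned}
\dot E_{PSII} &= \underbrace{\alpha\, c_{in}\, \mathrm{PAR}\,
  \bigl(1 - E_{PSII}/E^{*}_{PSII}\bigr)}_{\text{energy input}}
  - \underbrace{v_{ETR}\, E_{PSII}\, NADP^{+}}_{ETR}
  - \underbrace{v_d\, E_{PSII}\, P_{NPQ}\, (1 - Q/Q^{*})}_{\text{dissipation}} \\
\dot Q &= v_d\, E_{PSII}\, P_{NPQ}\, (1 - Q/Q^{*}) - v_{NPQ}\, Q \\
\dot P_{NPQ} &= \begin{cases}
  v_p\,(1 - P_{NPQ}) & \text{if } CEF > c_y \\
  0 & \text{otherwise}
\end{cases},
\qquad CEF = \alpha\, c_{in}\, \mathrm{PAR}\, (1 - E_{PSII}/E^{*}_{PSII})
  - v_{ETR}\, E_{PSII}\, NADP^{+} \\
\dot{NADPH} &= v_{ETR}\, E_{PSII}\, NADP^{+} \, \eta_{NADP^{+}}
  - v_C\, R\, NADPH \, \eta_{NADPH},
\qquad \dot{NADP^{+}} = -\dot{NADPH} \\
\dot R &= v_R\,(1 - R)\,\min\!\bigl(d,\ NADPH/NADP^{+}\bigr)
\end{aligned}
$$

The measurable fluxes are $ETR = v_{ETR} E_{PSII} NADP^{+}$,
$NPQ = v_{NPQ} Q$ and $A = v_C R\, NADPH$ (µmol m⁻² s⁻¹). The
$NADPH/NADP^{+}$ ratio proxies the transmembrane $\Delta$pH that drives
Rubisco activation; cyclic electron flow ($CEF$), the excess of the PSII
input over linear transport, is the trigger for NPQ-protein activation.

Two calibrated parameter presets are bundled, for the green wild-type
soybean cultivar Eiko and the chlorophyll-deficient mutant MinnGold:

```{r presets}
leaf_params("eiko")
leaf_params("minngold")
```

A dissipation-term note: the quenching-complex balance uses the saturation
factor $(1 - Q/Q^{*})$ in both the $E_{PSII}$ and $Q$ equations, so the
energy flux leaving PSII as heat equals the flux entering the quenching
complex — energy is conserved at the PSII node (tested as an identity).

Two deliberate literalisms are worth flagging. With Eiko's $c_y = -4$,
darkness satisfies $CEF = 0 > c_y$, so $P_{NPQ}$ rises even without light;
and $\Delta\mathrm{pH} = 1$ in the dark-adapted state, so $R$ creeps upward
in darkness too. Both follow the switching rule and activation law exactly
as written; neither affects the illuminated protocols, which always start
from the dark-adapted state.

## Simulation

The fast mode is the quenching complex: $v_{NPQ} \approx 70\ \mathrm{s^{-1}}$
gives $Q$ a relaxation time of about 14 ms against horizons of an hour, so
the system is stiff. `simulate_leaf()` integrates with `deSolve::lsoda`
(adaptive, switches to BDF as needed) at `rtol = 1e-8`, `atol = 1e-10`, and
restarts the integration at every light switch so no step straddles a
discontinuity — this also makes the CEF conditional in the right-hand side
benign, since PAR is constant within a segment. Refining the tolerances
tenfold changes every reported flux by well under 0.1% (tested). An
independent fixed-step classical Runge–Kutta integrator written in plain R
(`compare_to_fixed_step_oracle()`) agrees with the production solver to
better than $10^{-4}$ per state variable; the production right-hand side is
compiled C, the reference one plain R, so the two routes share no code.

States are never clipped: boundedness ($0 \le E_{PSII} \le E^{*}_{PSII}$,
$0 \le Q \le Q^{*}$, $P_{NPQ}, R \in [0,1]$), pool conservation
($NADPH + NADP^{+} = 10$ to $10^{-6}$), and the monotone growth of
$P_{NPQ}$ and $R$ are asserted in the test suite rather than silently
repaired. The only numerical guard is
$\Delta\mathrm{pH} = NADPH/\max(NADP^{+}, 10^{-9})$, which prevents
overflow; the $\min(d, \cdot)$ cap already bounds the value the model uses.

```{r sim, fig.height = 5}
eiko <- leaf_params("eiko")
fluct <- light_square(780, 520, period = 120)  # 1 min high, 1 min low
sim <- simulate_leaf(eiko, fluct, duration = 3600)
plot(sim)
```

Light protocols are piecewise constant and right-continuous; the two
measurement protocols are constant 650 µmol m⁻² s⁻¹ for 60 min, and a
square wave between 780 and 520 µmol m⁻² s⁻¹ switching every minute (both
deliver the same light dose). Fluctuations start on the high phase, matching
a dark-adapted leaf whose first illumination is the high level; this is
configurable. The saturating fluorometer flashes fired every 30 s in the
real measurements (which add roughly 20% to the delivered flux) are *not*
injected into the simulated light by default, because the parameter sets
were calibrated against nominal intensities; `flash_boost = TRUE` adds a
uniform +20% for exploring that effect.

## Observables and goodness of fit

`assimilation_from_irga()`, `phi_psii()`, `npq_stern_volmer()`,
`etr_from_fluorescence()` and `absorption_coefficient()` implement the
instrument-level formulas that turn gas-exchange and pulse-amplitude-
modulation fluorometry readings into $A$, $\Phi_{PSII}$, Stern–Volmer NPQ,
ETR and leaf absorbance. Goodness of fit is reported as the coefficient of
determination on parity pairs ($1 - SS_{res}/SS_{tot}$ about the observed
mean), not the squared Pearson correlation — the former penalizes bias,
which is what a parity plot shows; `r_squared(..., verbose = TRUE)` reports
both.

One unit subtlety is inherited from the measurement convention: the model's
NPQ is a heat flux (µmol m⁻² s⁻¹) while Stern–Volmer NPQ is dimensionless.
The two are compared directly — calibration absorbs the scale into
$v_{NPQ}$ and $Q^{*}$ — and no extra conversion factor is introduced.

## Sensitivity analysis

`sensitivity_sweep()` perturbs each of the 13 calibrated parameters by ±5%
(the fixed absorption coefficient and the light level are excluded) and
aggregates the deviation of the NPQ, ETR and A series from the baseline
60-min fluctuating-light simulation into a standardized index: the mean,
over quantities and the 121 samples of the 30-s output grid, of the squared
deviation normalized by each quantity's baseline range. The headline scale
is $100\sqrt{\text{index}}$, a percent deviation:

```{r sens}
sens <- sensitivity_sweep(eiko, delta = 0.05)
head(sens[order(-sens$index), ], 4)
```

The energy-input coefficient $c_{in}$ dominates in both varieties, the
maximum percent deviation stays at or under about 3.2% (within the 4% bound
the analysis is designed to check), and positive and negative perturbations
have near-symmetric effects. The sample count $n = 121$ is a package choice
(the sampling grid of the measurements); the index is insensitive to it
beyond discretization.

## Calibration

`calibrate()` fits the 13 kinetic parameters to replicate-resolved
(ETR, A, NPQ) series by bound-constrained least squares on replicate means,
each quantity normalized by the range of its observed mean so that ETR
(~100) and NPQ (~1) weigh comparably — no weighting scheme is given by the
measurement design, and range normalization is the simplest defensible
choice. Optimization is Levenberg–Marquardt (`minpack.lm::nls.lm`) on a log
scale for the 12 strictly positive parameters ($c_y$, which may be
negative, stays on the natural scale), with default bounds $[0.1\times,
10\times]$ the reference value ($c_y \in [-10, 10]$) and a log-uniform
multistart jitter (default 10 starts, deterministic given the seed).

Full 13-parameter point identification is *not* claimed: the least-squares
surface has local minima and parameter combinations trade off. What the
package asserts, and tests, is trajectory recovery — on noiseless synthetic
data the best-of-multistart fit drives the objective below $10^{-6}$ of the
data variance and the parity $R^2$ above 0.999 — plus point recovery of the
two most sensitive parameters ($c_{in}$, $E^{*}_{PSII}$) within 10%.
`validate()` scores a fixed parameter set against series from any protocol,
which is how a fit to fluctuating-light data is checked against
constant-light data.

## Synthetic data

No raw gas-exchange series are redistributable, so `generate_observed()`
emulates the measurement design: the model truth sampled every 30 s (the
saturating-flash schedule) over 60-min protocols, three replicates, and
independent additive Gaussian noise per sample and quantity. The default
noise SDs — ETR 5, A 1, NPQ 0.1 µmol m⁻² s⁻¹-scale units — are chosen to
mimic the visible standard-error bands of the published replicate means;
they are declared, not derived, since measured noise magnitudes are not
tabulated. The generator is deterministic given its seed and leaves the
caller's RNG stream untouched.

What the synthetic data deliberately do not contain: autocorrelated noise,
replicate-level random effects, instrument drift, or raw fluorescence
traces ($F_m'$, $F_s$) — synthesis is at the derived-quantity level. Tests
passing on these fixtures therefore demonstrate correctness of the fitting
machinery and identifiability under the stated noise model, not robustness
to every artifact of real PAM/IRGA records.

```{r synth}
obs <- generate_observed(eiko, fluct, duration = 1200, seed = 1,
                         variety = "eiko")
head(replicate_means(obs), 3)
```

## Theoretical light-regime sweeps

`period_sweep()` and `amplitude_sweep()` compare entrained steady-state
means of ETR, A and NPQ across square-wave regimes that all deliver the same
time-averaged light as a constant baseline (780/520 at duty 0.5 averages to
650). The steady-state window is the post-induction interval from 40 min;
because Rubisco activation is slow, the window is aligned to whole
fluctuation cycles (for periods up to 10 min this is exactly [40, 60] min;
longer periods get two whole cycles starting at the first whole-period
boundary at or after 40 min) and values are reported per unit time so
windows of different lengths are comparable.

```{r sweep}
am <- amplitude_sweep(eiko, c(0.2, 0.4, 0.6, 0.8), period = 60)
am
```

Two robust findings of the implemented model: stronger fluctuations
monotonically depress steady-state assimilation relative to constant light
of the same dose, and MinnGold oscillates more than Eiko in ETR but far
less in NPQ at the entrained steady state. A caution for users of
`optimal_period()` and `crossover_periods()` on period sweeps: in this
model the steady-state means under ±20% fluctuation sit uniformly about
0.5% *below* the constant baseline at every period (verified against an
independent solver), so apparent optima across long periods largely reflect
where the averaging window falls on the slow Rubisco transient, and
baseline crossings may simply not exist. The sweep machinery reports
whatever the model produces; it does not manufacture an interior optimum.

## Problem sizes and defaults

Defaults are the study conditions: 60-min protocols, 30-s sampling, 3
replicates, 780/520 and constant-650 light, solver tolerances
`1e-8`/`1e-10`, sensitivity perturbation 5%, 10 calibration starts. The test
suite exercises calibration on 20-min synthetic series (41 samples per
quantity), which preserves the induction transient that identifies the
kinetics while keeping a full multistart fit to seconds; sensitivity and
sweep tests run the full 60-min scenarios.

## Known limitations

* Stomatal conductance, Cyt b6f/PSI kinetics, ATP accounting,
  photoinhibition and the slower NPQ components (qZ, qT, qI) are outside
  the model; PsbS- and zeaxanthin-dependent quenching are merged into the
  single $P_{NPQ}$ variable, which is the model's main structural
  simplification.
* $P_{NPQ}$ and $R$ never relax (their derivatives are non-negative), so
  the model describes single dark-to-light protocols, not repeated
  light/dark cycling.
* Temperature and CO₂ are not inputs; the calibrated values embed the
  measurement conditions (400 ppm, 25 °C).
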