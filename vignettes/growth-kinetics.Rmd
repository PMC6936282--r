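---
title: "Substrate-inhibition growth kinetics and partial-denitrification metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate-inhibition growth kinetics and partial-denitrification metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denitkin)
```

## The models

Heterotrophic denitrifiers are both stimulated and inhibited by their
substrates: growth rises with nitrate-N or carbon at low concentration
(affinity, scale `Ks`) and falls again at high concentration
(inhibition, scale `Ki`). `denitkin` implements the three classical
single-substrate inhibition laws,

$$\mathrm{Andrews:}\quad \mu = \frac{\mu_{max}}{1 + K_s/S + S/K_i},
\qquad
\mathrm{Aiba:}\quad \mu = \frac{\mu_{max}\, S\, e^{-S/K_i}}{K_s + S},
\qquad
\mathrm{Edwards:}\quad \mu = \mu_{max}\left(e^{-S/K_i} - e^{-S/K_s}\right),$$

with `S` in mg l^-1 and `mu` in h^-1. All three are unimodal and vanish
as `S` grows; the Andrews optimum has the closed form
`S* = sqrt(Ks * Ki)`. Three evaluation conventions matter:

* **S = 0.** The Aiba and Edwards rates are exactly zero there; the
  Andrews expression is formally `0/0`-adjacent (`Ks/S` diverges) and is
  defined as its limit 0, so vectorized evaluation over concentration
  grids that include zero is safe.
* **Edwards validity.** `Edwards` with `Ki <= Ks` is negative for some
  `S`; such parameter sets are rejected at construction because the
  inhibition scale must exceed the affinity scale for the law to be
  physical.
* **Double-substrate interaction.** When two substrates (nitrate-N and
  the carbon source) both limit and inhibit growth, the interactive
  form multiplies normalized factors under one shared maximum:
  `mu = mu_max * f1(S1) * f2(S2)`, where `f_k` is the chosen law with
  `mu_max = 1`. A single shared `mu_max` keeps the product
  interpretable and identifiable; the factorization identity
  `mu_double(S1, S2) * mu_max = mu_single(S1) * mu_single(S2)` holds
  exactly when both factors reuse that `mu_max`.

Temperature enters through the modified Arrhenius law
`mu_max(T) = A * exp(-E/(R*T))`, log-linear in `1/T`. The gas constant
is fixed at `R = 8.314` J mol^-1 K^-1 and the activation energy `E` is
carried in kJ mol^-1 (converted internally); mixing these units is a
classic source of thousand-fold errors, so the convention is enforced
in one place. `A` — and therefore `mu_max_at_temperature()` — is
conventionally in days^-1 while batch growth rates are in h^-1; the
package never rescales silently and instead ships explicit
`per_day_to_per_hour()` / `per_hour_to_per_day()` converters.

## Fitting strategy

Parameters are estimated by unweighted least squares on the observed
growth rates (no error model for `mu` is assumed, so every observation
counts equally). The optimizer is Levenberg–Marquardt
(`minpack.lm::nls.lm`) on **log-transformed parameters**: positivity of
`mu_max`, `Ks`, `Ki` is enforced by the transform itself rather than by
box constraints, which keeps the search smooth near small values.

Substrate-inhibition objectives are multimodal, and some model/data
combinations genuinely have no good optimum, so robustness and
*reproducible failure* are designed in:

* **Deterministic multi-start.** Each fit runs from a fixed 27-point
  grid: `mu_max` starts at `max(mu) * {1, 2, 4}`, `Ks` at
  `{min(S)/10, median(S)/10, median(S)}`, `Ki` at
  `{max(S), 5*max(S), 25*max(S)}` (applied per substrate for double
  fits). No random numbers are involved: a table and options fully
  determine the result.
* **Start failure.** A start is discarded when the optimizer does not
  converge, the SSE is non-finite, a scale parameter diverges beyond
  `plausibility_factor` (default 1000) times the data range — the
  signature of a runaway fit — or an Edwards factor lands at
  `Ki <= Ks`. A *model* fails only when all 27 starts fail; it is then
  reported with `converged = FALSE` rather than dropped, so the
  15-row comparison layout is always complete. Which combinations fail
  is solver-relative, not a property of the data.
* **Tie-breaking.** Among converged starts the lowest SSE wins; ties
  (within 1e-12 relative) go to the smaller parameter-vector norm, so
  degenerate plateaus resolve deterministically.
* **Collinear designs.** The standard experimental design couples the
  carbon source to nitrate at a fixed C/N mass ratio (S2 = 5·S1). The
  two factors of a double-substrate model then see perfectly
  proportional inputs, the (S1, S2) design matrix has rank 1, and
  individual `Ks`/`Ki` values can trade off between factors without
  changing the likelihood. `fit_double()` detects this by a rank check
  and attaches a warning; `mu_max` (and the fitted curve) remain well
  identified, and recovery of all five constants is only claimed on
  crossed concentration grids.

Model comparison uses `R^2 = 1 - SS_res/SS_tot` with `SS_tot` about the
observed mean — the conventional regression coefficient — across the
fixed 15-fit layout (`fit_all()`): numbers 1–3 are Aiba/Edwards/Andrews
against nitrate, 4–6 against carbon, 7–15 the nine double combinations
with the nitrate-side law cycling fastest. No information criteria are
computed: the candidate models have equal parameter counts within each
block, so `R^2` ordering is the field's standard practice here.

The Arrhenius fit is ordinary linear regression of `ln(mu_max)` on
`1/T` (slope `-E/R`, intercept `ln A`). Two points give the exact
interpolating line with `R^2 = 1`; a negative fitted `E` (rates falling
with temperature) is an error, not a silent sign flip.

## Batch performance metrics

From a batch time series with baselines `C20` (nitrate) and `C10`
(nitrite) at the first point:

* nitrite accumulation efficiency
  `a = (C1i - C10)/(C20 - C2i) * 100` (%),
* nitrate removal efficiency `b = (C20 - C2i)/C20 * 100` (%),
* specific nitrate degradation rate `c = (C20 - C2i)/(dt * CC0)`,
* specific total oxidized-N reduction rate
  `d = (C20 - C2i + C10 - C1i)/(dt * CC0)`.

The fourth metric is deliberately named *total-N* rate: its formula
subtracts the nitrite that piled up, so it measures nitrogen reduced
past nitrite, and the three quantities obey `d = c * (1 - a/100)`
exactly — a useful internal consistency check that the test suite
asserts on random states. `CC0` is the cell concentration at
inoculation (not at the interval start), and the rates are reported in
the formula's own units, h^-1 times mg substrate per mg cells; no
attempt is made to re-express them per gram DCW, the caller controls
units. Efficiencies default to the series' first point as baseline,
with an explicit `baseline` index for truncated series.

`a` may exceed 100% when nitrite rises by more than the nitrate fell
(analytically possible with measurement noise); this is reported with a
warning, while a zero denominator (no nitrate consumed) is an error
rather than a silent `NaN`.

The log-phase growth rate is the maximum sliding-window slope of
`ln(biomass)` versus time. The default window of 3 consecutive points
is the shortest giving a non-trivial regression slope; wider windows
smooth more but blur the lag/log boundary. On noiseless exponential
data any window returns the generating `mu` to machine precision.

## Relative gene expression

`fold_table()` implements the 2^-ddCt method with an amplification
efficiency fixed at 2. The reference gene is an explicit argument (the
16S rRNA gene is the conventional choice for this organism) rather than
hard-coded. Replicates are aggregated by averaging delta-Ct *before*
exponentiation — equivalent to a geometric mean of per-replicate folds,
the standard practice because Ct noise is approximately additive in
cycles. Exact structural properties follow: control-condition folds are
1 by construction, a global Ct shift changes nothing, and swapping
sample and control inverts every fold.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the study designs so every analysis stage can
be validated by recovery:

* `gen_growth_table()` — the twelve-level nitrate gradient 50–2000
  mg l^-1 with carbon coupled at C/N = 5 (250–10000 mg l^-1), additive
  Gaussian noise on `mu` truncated at zero (rates cannot be negative;
  clipping is warned about).
* `gen_arrhenius_series()` — the five culturing temperatures 20–40 °C
  in 5 °C steps, multiplicative (log-scale) noise so rates stay
  positive.
* `gen_batch_series()` — a lag phase, exponential nitrate decay,
  nitrite tracking a constant accumulation efficiency, and exponential
  log-phase biomass. Defaults portray a favourable C/N = 5 batch:
  100 mg l^-1 initial nitrate-N, 94.2% accumulation efficiency, 6 h
  lag, ~2 h removal timescale, `mu` = 0.25 h^-1, hourly sampling over
  24 h. The series is *constructed from its target metrics*, not
  ODE-integrated: the point is that the noiseless output returns the
  generating truth exactly, giving sharp oracle tests. Real batch data
  have interacting substrate/biomass dynamics, non-constant
  accumulation efficiency and autocorrelated noise; passing recovery
  tests therefore validates the *estimators*, not any mechanistic
  growth model.
* `gen_ct_table()` — replicated Ct tables in which the reference gene
  sits at a fixed baseline and each target's Ct is offset by
  `-log2(fold)`, with Gaussian cycle noise applied to **every well**,
  reference and control included, as technical qPCR noise is. One
  statistical consequence is worth stating plainly: with per-well noise
  of 0.2 cycles and triplicates, the ddCt estimate carries an error of
  `sd = sqrt(4 * 0.2^2 / 3) = 0.23` cycles, so the probability that a
  recovered fold lands within 20% of truth is only about 79% — not a
  defect of the estimator but the noise floor of the design.
  Detecting the ~1.1–1.4-fold changes typical of denitrification genes
  at high confidence needs either more replicates or tighter Ct
  precision.

All generators draw from R's Mersenne–Twister stream through a local
seeding wrapper that restores the caller's RNG state, so identical
seeds give byte-identical CSV output and generation never perturbs a
surrounding simulation.

## Problem sizes and numerical choices

The validation suite runs recovery at the designs above (12-point
single-substrate tables, a 6×6 crossed grid for full double-substrate
identification, 5 temperatures), brute-force SSE oracles on 13^3
log-spaced parameter grids for 20 random draws per model kind, 1000
random states for the metric identities, and 500 seeded replicates for
the stochastic ddCt study — a few minutes end to end on one core.
Levenberg–Marquardt tolerances are tightened to 1e-12 (cost and step)
so that noiseless recovery reaches the printed precision of the
constants being recovered; the plausibility cut-off of 1000× the data
range is deliberately generous, rejecting only fits that have left the
data's scale entirely.

## Limitations

* Non-interactive (minimum-law) multi-substrate forms, Monod-family
  laws without inhibition, and pH-dependent rate models are out of
  scope.
* Confidence intervals on kinetic constants are not computed; the
  comparison is point estimates plus `R^2`, and on collinear designs
  only `mu_max` should be interpreted at all.
* The ddCt module assumes perfect doubling per cycle;
  efficiency-corrected variants are not implemented.
* TOC consumption is carried through the I/O schema but no TOC-removal
  kinetics are fitted.
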