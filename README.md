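# denitkin

Growth-kinetics and performance analysis for partial-denitrifying
bacteria.

Partial denitrification reduces nitrate (NO3⁻-N) only as far as nitrite
(NO2⁻-N), accumulating nitrite as a substrate for ANAMMOX instead of
completing reduction to N₂. Characterising a partial-denitrifying strain
means answering three quantitative questions, and `denitkin` implements
the standard toolkit for each:

1. **How does growth depend on substrate concentration?** Both nitrate
   and the carbon source stimulate growth at low concentration and
   inhibit it at high concentration. The package evaluates and fits the
   three classical substrate-inhibition laws

   - Andrews (Haldane): `μ = μmax / (1 + Ks/S + S/Ki)`
   - Aiba: `μ = μmax · S · exp(−S/Ki) / (Ks + S)`
   - Edwards: `μ = μmax · [exp(−S/Ki) − exp(−S/Ks)]`

   and their interactive double-substrate extension
   `μ = μmax · f₁(S₁) · f₂(S₂)`, where `f_k` is the normalized
   (μmax = 1) factor of substrate k. Fitting is bounded multi-start
   Levenberg–Marquardt least squares (positivity enforced by a
   log-parameter transform, 27 deterministic starts per model); models
   are compared by `R² = 1 − SS_res/SS_tot` across the standard
   15-combination layout (3 laws × 2 single substrates + 9 double
   combinations), with non-converging combinations flagged rather than
   dropped.

2. **How does temperature shift μmax?** Via the modified Arrhenius law
   `μmax = A · e^(−E/RT)` (R = 8.314 J mol⁻¹ K⁻¹): `ln μmax` is
   regressed on `1/T`, giving the pre-exponential factor `A` and the
   activation energy `E`.

3. **How well does the culture accumulate nitrite, and what do the
   denitrification genes do?** Batch time series yield the nitrite
   accumulation efficiency `a = (C1i − C10)/(C20 − C2i) × 100`, the
   nitrate removal efficiency, specific degradation rates, and the
   log-phase specific growth rate `μ = Δln(biomass)/Δt`; qPCR Ct tables
   yield relative expression of the denitrification genes (*napA*,
   *nirB*, *nirD*) by the 2^−ΔΔCt method with replicate ΔCt averaging.

A seeded synthetic-data module (`gen_growth_table()`,
`gen_batch_series()`, `gen_arrhenius_series()`, `gen_ct_table()`)
generates every input with known ground truth, so all estimators are
validated by recovery experiments.

## Worked example

Generate a noisy growth-rate table on the experimental design (twelve
nitrate levels 50–2000 mg l⁻¹, carbon coupled at C/N = 5) from a known
Andrews–Andrews truth, then fit all 15 candidate models:

```r
library(denitkin)

truth <- double_params(0.5523, "andrews", 4.34, 8970.72,
                       "andrews", 48.25, 14194.83)
tab  <- gen_growth_table(truth, mu_sd = 0.01, seed = 42)
fits <- fit_all(tab)
rank_fits(fits)[1:5, c("fitting_number", "model_no3", "model_toc",
                       "mu_max", "r_squared")]
#>   fitting_number model_no3 model_toc mu_max r_squared
#> 1             15 andrews   andrews    0.549     0.987
#> 2              9 andrews   aiba       0.553     0.987
#> 3             12 andrews   edwards    0.550     0.987
#> 4             14 edwards   andrews    0.550     0.987
#> 5             13 aiba      andrews    0.553     0.987
```

The generating combination (no. 15, Andrews–Andrews) tops the ranking,
and the recovered μmax (0.549 h⁻¹) sits within 1% of the generating
0.5523 h⁻¹ despite the noise; because the design couples S₂ = 5·S₁ the
fit carries a collinearity warning — individual Ks/Ki values are only
identifiable on a crossed concentration grid.

Temperature dependence and batch performance:

```r
ser <- gen_arrhenius_series(arrhenius_params(A = 77.48, E = 13.80),
                            log_sd = 0.02, seed = 42)
fit_arrhenius(ser$temperature_K, ser$mu_max)
#> <arrhenius_fit> A = 71.1, E = 13.56 kJ/mol, R^2 = 0.9907

ts <- gen_batch_series(c20 = 100, a = 94.2, lag_h = 6, mu = 0.25)
nitrite_accumulation_efficiency(ts, nrow(ts))  # 94.2 (%)
log_phase_mu(ts)$mu                            # 0.25 (h^-1)
```

With 2% multiplicative noise on five temperatures the Arrhenius
regression recovers E within ~2% (13.56 vs 13.80 kJ mol⁻¹); A, being
the extrapolated intercept at 1/T = 0, is the noise-sensitive quantity
(71.1 vs 77.48 d⁻¹). The noiseless batch series returns its generating
efficiency and growth rate exactly, by construction.

Relative gene expression from a triplicate Ct table (reference gene
16S, control condition C/N = 5):

```r
ct <- gen_ct_table(data.frame(condition = "C/N=7",
                              gene = c("napA", "nirB", "nirD"),
                              fold = c(1.12, 1.33, 1.41)),
                   control = "C/N=5", ct_sd = 0.2, seed = 42)
fold_table(ct, "C/N=5")
#>   condition gene     fold   fold_sd n_replicates
#> 1     C/N=5 napA 1.000000 0.2402419            3
#> 2     C/N=7 napA 1.216602 0.1418070            3
#> ...
```

Control-condition folds are 1 by construction; treatment folds scatter
around their generating values with ~0.2-cycle technical noise.

A command-line wrapper (`inst/scripts/denitkin.R`) exposes the same
pipeline as subcommands (`fit-all`, `arrhenius`, `metrics`, `ddct`,
`simulate`); see `?run_cli`.

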