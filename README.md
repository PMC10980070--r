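# nitroregime

Functional regimes of soil nitrate reduction under pH perturbation.

## What this package is for

Soil microbiomes reduce nitrate anaerobically, and their metabolic response
to a sudden pH change is surprisingly structured. `nitroregime` implements
the quantitative pipeline for microcosm experiments that probe this
structure: slurries from soils of different native pH are perturbed to a
grid of pH levels, incubated with 2 mM nitrate with and without
chloramphenicol (CHL+, which blocks growth), and sampled for nitrate over
four days alongside endpoint 16S amplicon sequencing with genomic spike-in
standards.

The core is a two-resource consumer-resource model. With functional biomass
x̃ (mM/day), nitrate A (mM) and a rescaled limiting nutrient C̃ (mM):

    dA/dt  = − x̃ · A/(A + K_A)
    dC̃/dt = − x̃ · C̃/(C̃ + K̃_C)
    dx̃/dt =  γ · x̃ · [A/(A + K_A)] · [C̃/(C̃ + K̃_C)]

With small affinities, growth is exponential until the scarcer resource is
exhausted at t\* = log(min(A₀, C̃₀)·γ/x̃₀ + 1)/γ, after which nitrate falls
linearly at rate γC̃₀ + x̃₀. Fitting the paired CHL∓ nitrate series (with
γ = 4.8/day and K_A = K̃_C = 0.01 mM fixed) yields two summary parameters —
initial functional biomass x̃₀ and available growth nutrient γC̃₀ — that
classify each condition into three regimes: **I** acidic death (both
small), **II** nutrient-limiting (x̃₀ ≥ 0.05), **III** resurgent growth
(x̃₀ < 0.05, γC̃₀ ≥ 1.5).

Around the model the package provides: a sensitivity analysis justifying
the fixed parameters; titration-curve interpolation and inversion
(dose ↔ pH); per-soil regime-boundary location and weighted trends against
native pH; the rate-fold collapse against NaOH dose; spike-in absolute
abundance with an empirically calibrated replicate noise model
σ(n) = √((c_frac·n)² + c₀²); Bonferroni-thresholded enrichment z-scores;
phylum growth/survival folds with rank-2 NMF; LASSO prediction of a soil's
native pH from its resurgent-growth taxa with leave-one-soil-out
validation and a permutation null; and a fully deterministic synthetic
panel generator that reproduces the entire study design with known ground
truth, so every stage is testable end to end.

## A worked example

```r
library(nitroregime)

truth  <- make_soil_panel(soil_panel_spec())   # 20 soils x 13 pH levels
series <- simulate_experiment(truth, seed = 1) # CHL-/CHL+ triplicate panel
fit    <- crm_fit(pair_timeseries(series)[[238]])  # soil 1 at its native pH
fit
#> Consumer-resource model fit
#>   x0_tilde = 0.3234 mM/day   C0_tilde = 0.03175 mM   gamma*C0_tilde = 0.1524 mM/day
#>   A0 = 2.001 mM   A0c = 1.999 mM (fixed: gamma = 4.8, KA = 0.01, KC_tilde = 0.01)
#>   RMSE = 0.0444 mM (2.22% of the 2 mM input), converged: TRUE
```

This condition was generated with x̃₀ = 0.324 mM/day and γC̃₀ = 0.144
mM/day: the fit recovers the biomass to 0.2% and the nutrient term to
about 6% from data with 0.05 mM measurement noise, and its summary
classifies the condition as Regime II (nutrient-limiting), matching the
planted truth. Fitting the whole panel and classifying the median fits
per condition:

```r
fits <- fit_panel(series)
cond <- aggregate_fits(fits)
cond$regime <- classify_regime(cond$x0_tilde, cond$gammaC0_tilde)
table(cond$regime)
#>   I  II III
#>  83 144  33
```

Acid-perturbed conditions fall into Regime I, conditions near each soil's
native pH into Regime II, and strong basic perturbations of the more
acidic soils into Regime III (natively basic soils reach pH 9 before the
nutrient-release threshold and stay nutrient-limited).

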