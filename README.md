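# bwspawn

Modelling the spawning distribution and phenology of blue whiting
(*Micromesistius poutassou*) from Continuous Plankton Recorder (CPR)
presence/absence records.

CPR silk squares (~10 nautical miles of tow each) record blue whiting
larvae as abundance categories; beyond 3 larvae only ranges are kept, so
the data are reduced to presence/absence and modelled as a Bernoulli GAM
on the logit scale:

    logit p = β0 + β_DN·DN + f(east, north, doy) [+ s(year)]

with UTM zone-28 coordinates, a cyclic day-of-year smooth, a solar-derived
day/night factor DN (night: sun ≥ 6° below the horizon), and ten candidate
structures for `f`/year — from fully additive to a 3-D tensor interaction,
with seasonal and/or year terms optionally conditioned on the spawning
component (split at 53°N) — ranked by conditional AIC (effective degrees
of freedom, overfit multiplier γ = 1.4 in the UBRE-type smoothness
criterion). Fitted models are turned into normalised spatial spawning
densities, peak-timing maps masked to the 75% highest-density core,
zonally integrated latitude×day-of-year distributions, and annual
abundance indices with posterior 67% intervals.

The real observations are available only on request from the curating
foundation, so the package ships a synthetic CPR-like survey generator
with a known two-component truth; every stage is validated by parameter
recovery against it. See the methods vignette
(`vignettes/spawning-distribution.Rmd`) for the model, the numerical
choices and the stated synthetic world.

## Worked example

Simulate a reduced survey (1958–1977) from the default truth, fit the
Model-6-style structure (`east*north*doy + syear`), and derive products:

```r
library(bwspawn)

truth <- default_truth(1958:1977)
smp   <- generate_samples(default_design(), 1958:1977, seed = 21)
obs   <- simulate_observations(truth, smp, seed = 22)
mean(obs$presence)                      # 0.0238 — rare presences, as real

m <- bw_gam(obs, model_spec("te3", "common"),
            fit_settings(k = list(k3 = c(5, 5, 6), kyear = 6),
                         optim_maxit = 60, multistart = FALSE))
print(m)
#> Bernoulli spatiotemporal GAM
#>   structure : east*north*doy + syear
#>   n = 27768, edf = 43.82, deviance = 3604.29 (null 6240.19)
#>   AIC = 3691.92, deviance explained = 0.422
#>   DN (day) coefficient = 0.167 [-0.028, 0.362]

grid <- evaluate_grid(m, default_grid_axes(m, ne = 40, nn = 60, doy_step = 5),
                      years = seq(1958, 1977, by = 3))
component_modes(spatial_pdf(grid))[, c("comp", "lon", "lat")]
#>    comp       lon      lat
#>   north -9.235924 56.67129      (truth centre:  -9.5, 56.5)
#>   south -12.40798 49.89100      (truth centre: -12.5, 50.0)
zonal_peak_days(zonal_marginal(grid))
#> north south
#> 117.5  77.5                     (truth: 120 / 80 — a 40-day southern lead)
```

The fitted day/night coefficient's interval covers the simulated +0.17
logit catchability offset, the spawning centres land within a few tens of
km of the truth, and the southern component leads the north by ~40 days.
`compare_ensemble(obs, build_ensemble(), ...)` reproduces the ten-model
comparison table (AIC, ΔAIC, AUC, deviance explained, DN coefficient).

## Pipeline / CLI

```sh
Rscript inst/cli/bwspawn.R run --config config.json --outdir out
```

Verbs: `simulate`, `fit` (alias `compare`), `products`, `run`. The JSON
config keys are documented in `?pipeline_config`; outputs are CSVs
(ensemble table, product grids, annual index), a JSON model archive, and
a run log. Reruns with the same config and seed are byte-identical on
product files.

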