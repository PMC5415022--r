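# porpoisepam

Year-round analysis of harbour porpoise (*Phocoena phocoena*) occurrence
from passive acoustic monitoring with C-POD-style echolocation click
detectors.

Bottom-moored click loggers record, per detected click train, a start
time, the inter-click intervals (ICIs, microseconds) and a classifier
quality class (`Hi`/`Med`/`Low`). From such logs plus recording-effort
intervals, daily environmental series and an external habitat-based
density product, the package reproduces a complete occurrence analysis:

1. **Detection processing** — keep only high/medium-quality trains, bin
   them into the number of detection-positive minutes per complete
   recorded hour (the response `Y_t ∈ 0..60`), and derive
   porpoise-positive hours (PPH), monthly detection metrics and ISO-8601
   weekly occurrence proportions.
2. **Temporal occurrence** — generalized autoregressive moving average
   (GARMA) models of the hourly series with log link,

   `g(μ_t) = X_t'β + Σ_{j=1..p} φ_j {g(y*_{t-j}) − X_{t-j}'β} + Σ_{j=1..q} θ_j {g(y*_{t-j}) − g(μ_{t-j})}`,

   where `X_t` holds sinusoidal pairs `sin(2πt/d)`, `cos(2πt/d)` for the
   diel (`d = 24` h) and seasonal (`d` = days in the year) cycles and
   `y* = max(y, c)` keeps the link finite at zero. Conditional
   distributions: Poisson, Poisson inverse-Gaussian (PIG; variance
   `μ(1+σμ)`, pmf via its Bessel-function closed form) and zero-inflated
   Poisson (ZIP), selected by AIC; diagnostics via randomized quantile
   residual ACF/PACF.
3. **Foraging behaviour** — hours whose pooled ICIs contain any interval
   ≤ 10 ms (a buzz) are foraging-positive; foraging presence/absence is
   modelled with a from-scratch penalized **cyclic cubic regression
   spline** binomial GAM on hour of day (period 24) and Julian day
   (period 366), with confusion matrices and rank-based ROC AUC.
4. **Environmental association** — ISO-week medians of SST, ln
   chlorophyll *a* and nightly moon-illuminated fraction, related to
   weekly occurrence with a Gaussian GAM; AIC over covariate subsets;
   centered response curves with ±2 SE bands.
5. **Density validation** — Spearman rank correlations (midranks; exact
   permutation p-values for n ≤ 8) between the four monthly acoustic
   metrics and monthly habitat-based density predictions.

Because raw C-POD click logs of this kind are rarely public, the package
ships a **synthetic data generator** (`sim_config()`,
`simulate_occupancy()`, `simulate_click_trains()`,
`simulate_environment()`, `simulate_density_predictions()`) that draws
from the same model family the fitters estimate and retains the full
ground truth, so every stage — and the whole pipeline — is testable
end to end.

## Worked example

```r
library(porpoisepam)
res <- run_pipeline(demo_config(seed = 1), out_dir = "demo_run")
```

The demo simulates four sites recorded November 2014 – May 2016 with a
winter–spring occupancy peak, an evening–morning diel cycle,
instrument-loss gaps at two sites, and over-dispersed zero-heavy hourly
counts, then runs the full analysis. Selected output:

```
print(res$garma$site3$fit)
#> GARMA(1,0) fit, pig distribution, n = 13488
#> Coefficients:
#> (Intercept)    sin_hour    cos_hour    sin_jday    cos_jday
#>     -2.1586     -0.2443      0.4596      1.3601      1.2596
#> phi:   0.2605
#> sigma: 0.5124
#> logLik = -7814.76, AIC = 15643.53, converged = TRUE
```

AIC selected the Poisson inverse-Gaussian distribution; the generating
values were `φ = 0.25` and `σ = 0.5`, and the seasonal harmonic pair
(amplitude 1.8 peaking at Julian day 46) is recovered within a few
percent.

```
print(res$env$gams$site2)
#> Penalized spline GAM (gaussian), n = 69
#> Smooth/linear terms (EDF):
#>   sst          EDF = 2.56  lambda = 1e+03
#>   lnchla       EDF = 1.00  lambda = 1e+06
#> Deviance explained = 92.15%, adj. R^2 = 0.92, AIC = -275.62
```

AIC retained SST (and chlorophyll) and dropped the null moon covariate;
`response_curve(res$env$gams$site2, "sst")` peaks at 5.0 °C, the
temperature at which the generator places maximum occupancy. The site-2
foraging GAM keeps the hour smooth (AUC 0.72; 82 % of foraging-positive
hours correctly predicted), with its diel minimum near 11:00. The
validation table correlates each site's monthly metrics with the density
product, e.g. for site 1:

```
#>    site          metric       rho      p_value n_months degenerate
#> 1 site1      median_pph 0.9805807 2.105294e-08       12      FALSE
#> 2 site1       total_pph 1.0000000 2.460937e-61       12      FALSE
#> 3 site1         max_pph 0.9663177 3.226433e-07       12      FALSE
#> 4 site1 proportion_days 0.9877423 2.135004e-09       12      FALSE
```

(The demo uses a noise-free monotone density link, so correlations sit
near 1; `sim_config(density_noise_sd = ...)` degrades them to realistic
levels.) A thin command-line front end is provided at
`inst/scripts/porpoise-pam.R` (`run-all` and `simulate` subcommands).

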