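---
title: "Models and methods behind porpoisepam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind porpoisepam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`porpoisepam` implements a year-round harbour porpoise occurrence
analysis from C-POD-style click-train logs. This vignette documents the
statistical models, the synthetic data generator that stands in for
undeposited field recordings, the numerical choices, and the package's
known limitations.

## Detection processing

The unit of analysis is the *complete recorded hour*: an hour fully
contained in a recording-effort interval. Within an hour, a minute is
detection-positive if at least one quality-filtered click train (classes
`Hi` or `Med`; `Low` trains are conservatively discarded) overlaps any
part of it. A train's temporal span is its start time plus the sum of
its inter-click intervals — the only duration derivable from the stored
fields. All intervals are half-open (`[h:00, h+1:00)`), so a train
ending exactly on a boundary does not occupy the next unit, and
overlapping trains within a minute count once.

Derived summaries follow the standard passive-acoustic definitions: a
porpoise-positive hour (PPH) has at least one train
(`minutes_detected >= 1`); monthly metrics per site are the median,
total and maximum PPH per day plus the proportion of recording days
with a PPH (a *recording day* needs at least one complete hour — the
field convention is not universal, so this is configurable in spirit but
fixed here and documented); weekly occurrence is the proportion of
complete hours that are PPH on the ISO-8601 week grid. All timestamps
are fixed-offset EST (UTC−5) so no daylight-saving corner cases exist.

## GARMA models of temporal occurrence

Hourly minutes detected are over-dispersed, zero-heavy, autocorrelated
counts. The conditional mean follows the link-scale recursion

$$g(\mu_t) = X_t'\beta + \sum_{j=1}^{p}\varphi_j\{g(y^*_{t-j}) -
X_{t-j}'\beta\} + \sum_{j=1}^{q}\theta_j\{g(y^*_{t-j}) -
g(\mu_{t-j})\}$$

with natural-log link and $y^* = \max(y, c)$, default $c = 0.1$
(configurable), because the log of a zero count is otherwise undefined.
The recursion restarts after every recording gap: lagged terms that
would reach across a gap contribute zero. Covariates are an intercept
plus sinusoidal pairs for the diel (period 24 h) and seasonal cycles;
the seasonal period is each year's true calendar length (365/366).

Three conditional distributions are implemented and compared by AIC
($2k - 2\ell$ with $k$ counting every free parameter including the
dispersion or zero mass):

* **Poisson**;
* **Poisson inverse-Gaussian (PIG)** — a Poisson mixed over an
  inverse-Gaussian latent rate with mean 1 and shape $1/\sigma$, giving
  mean $\mu$ and variance $\mu(1 + \sigma\mu)$. The pmf is evaluated
  through its modified-Bessel closed form; the half-integer-order
  Bessel factor $K_{y-1/2}(\omega)$ is computed by the upward three-term
  recurrence on the log scale, which is exact for half-integer orders
  and stays finite at counts and dispersions where the raw function
  overflows;
* **zero-inflated Poisson (ZIP)** with
  $P(0) = \pi + (1-\pi)e^{-\mu}$.

Estimation is conditional maximum likelihood: BFGS over
$(\beta, \varphi, \theta, \log\sigma \text{ or } \mathrm{logit}\,\pi)$
from a moment-based start plus jittered restarts (five starts by
default; the recovery harnesses use two, which suffices at their sample
sizes). The recursion and the PIG likelihood are in C++ because they
sit inside the optimizer's objective. Convergence is reported from the
optimizer status plus a finite-difference gradient norm below
$10^{-3}(1 + |\ell|)$ — an absolute gradient tolerance is not meaningful
at likelihood magnitudes of $10^4$ with numerical differentiation.
Standard errors come from the numerical Hessian. Residuals are
randomized quantile residuals (uniform draw between $F(y-1)$ and
$F(y)$, normal-quantile transformed), the standard choice for discrete
responses; their ACF/PACF with the $\pm 1.96/\sqrt{n}$ band diagnose
remaining serial dependence.

The AR/MA orders of the field analysis are not published; the package
defaults to comparing distributions at $(p,q) = (1,0)$ in the pipeline
and exposes the orders everywhere, making order selection explicit
rather than asserted.

## Penalized cyclic-spline GAMs

The GAM engine is written from scratch on cubic regression splines
parameterized by their knot values, with the classic banded relation
$B m = D\gamma$ between knot values $\gamma$ and knot second
derivatives $m$; the curvature penalty is
$\int f''^2 = \gamma'D'B^{-1}D\gamma$. Two bases:

* **cyclic** (`s_cyclic`): $k$ evenly spaced knots over $[0, P]$ with
  the endpoints identified ($k-1$ coefficients); value and first two
  derivatives match at $0$ and $P$. Hour of day uses $P = 24$; Julian
  day uses $P = 366$ so leap days are valid and day 366 wraps onto day
  1. Default $k = 10$; evenly spaced knots make the periodicity exact.
* **natural** (`s_spline`): $k$ evenly spaced knots over the data
  range, natural boundary conditions; out-of-range predictions are
  clamped to the boundary.

Each smooth carries a sum-to-zero constraint absorbed by a QR
reparameterization; penalties are Frobenius-normalized so one λ grid
serves all terms. Fitting is penalized IRLS (binomial-logit or
Gaussian-identity) with step halving, which makes the *penalized*
deviance monotonically non-increasing — a contract the tests assert.
Smoothing parameters minimize GCV,
$n D / (n - \gamma\,\mathrm{EDF})^2$, over a 41-point log-spaced grid
($10^{-4}$–$10^{6}$), coordinate-wise with two sweeps. The EDF
inflation factor $\gamma = 1.4$ counteracts the well-documented
tendency of plain GCV to undersmooth at moderate sample sizes.

For model selection, AIC counts the effective degrees of freedom
**plus one parameter per estimated smoothing parameter** (plus the
Gaussian scale). Smoothing parameters are fitted quantities, analogous
to variance components; ignoring them makes AIC retain null smooths at
high rates, while this convention rejects a pure-noise covariate most
of the time yet keeps genuinely informative smooths — the operating
characteristics the selection harnesses verify.

Goodness of fit is reported as deviance explained
($1 - D/D_0$), adjusted $R^2$, confusion matrices at a configurable
threshold (default 0.5; the threshold used in the original analyses is
unpublished) and rank-based ROC AUC with midranks for ties, which is
invariant under strictly increasing score transforms.

## Foraging classification

Porpoise foraging buzzes have much shorter inter-click intervals than
travelling click trains. Hours during which porpoises were detected are
classified foraging-positive when the minimum over all pooled ICIs of
the hour's trains is at most 10 ms — the threshold is applied
inclusively. ICIs are pooled across trains within the hour (the
per-train vs pooled granularity of the original export is unspecified;
pooling is the weaker assumption). The count of ICIs at or below
threshold is kept so that classification robustness (hours supported by
≥ 5 buzz ICIs) can be reported. Foraging presence/absence is modelled
with the binomial cyclic GAM on hour of day and Julian day; candidate
models (intercept, hour, jday, hour + jday) are compared by AIC. The
irregular spacing of porpoise-positive hours means residual
autocorrelation cannot be assessed by standard methods; foraging
occurrence per hour is treated as independent — a documented limitation
of this analysis design, not of the implementation. Sites with fewer
than 24 porpoise-positive hours are refused (configurable), mirroring
the exclusion of sparsely detected sites.

## Environmental association

Daily SST, chlorophyll *a* and nightly moon-illuminated fraction are
collapsed to ISO-week medians; chlorophyll is log-transformed *before*
the median by default (a `log_first = FALSE` switch takes the median
first — the two differ only under within-week skew). The weekly
proportion of porpoise-positive hours is modelled with a Gaussian GAM
on natural-spline smooths of the covariates; the Gaussian family on a
proportion response is deliberate fidelity to the analysis this package
reproduces, though a binomial would be more orthodox. AIC over all
covariate subsets performs the selection. Centered response curves with
±2 SE bands from the Bayesian coefficient covariance are the reporting
device; curves are centered over the evaluation grid, so they sum to
zero there.

## The synthetic generator

The generator emulates the study conditions end to end: four sites
recorded November 2014 – May 2016; a winter–spring seasonal peak
(log-scale amplitude 1.8 peaking at Julian day 46) and an
evening–morning diel cycle (amplitude 0.5 peaking at 22:00 EST) on a
log-link harmonic mean with AR(1) feedback ($\varphi = 0.25$); PIG
counts with $\sigma = 0.5$; per-site baselines (0.06, 0.08, 0.12,
0.015 expected minutes/hour) giving sparse, zero-heavy series;
instrument-loss gaps at two sites (including a site whose deployment
starts late and ends early); foraging probability per detection hour
following an evening–morning curve (logit amplitude 1.1 peaking at
23:00); travelling ICIs uniform on 30–120 ms and buzz runs of six ICIs
on 1.5–8 ms; quality classes Hi/Med/Low at (0.5, 0.3, 0.2); SST an
annual sinusoid (15 ± 10 °C peaking in August, so minimum ≈ 5 °C in
winter when occupancy peaks); chlorophyll a raised-cosine
winter–spring bloom (baseline 0.8, peak 6 mg m⁻³, days 10–110); moon
fraction a rectified cosine with the 29.53-day synodic period. Counts
are generated *un-truncated* in a regime where exceeding 60
minutes/hour is vanishingly rare (configurations whose expected mean
exceeds 60 are rejected outright), so the fitters need no truncation
correction; realized counts are still capped at 60. Each
detection-positive minute receives one Hi/Med train placed entirely
within its minute (so minute binning round-trips exactly), plus
Poisson-distributed Low-quality extras at rate $p_L/(1-p_L)$ so the
marginal class frequencies match the configured simplex.

Monthly density predictions emulate an external habitat-model product:
a monotone transform of true monthly mean occupancy (pooled calendar
months) with log-normal noise. The default noise (SD 0.6) was
calibrated once by Monte-Carlo so the expected rank correlation with
the acoustic metrics is ≈ 0.8, the level typical of such validations;
`noise_sd = 0` gives a noise-free monotone link. Note that even a
noise-free link to *true* occupancy cannot produce rank correlation
exactly 1 against *measured* metrics — they are different functionals
of the same realization — so the exact-correlation contract is stated,
and tested, for densities that are strictly increasing transforms of a
metric (ties map to ties, and midranks coincide).

What the generator does **not** emulate: acoustic propagation and
detection-range variation, false-positive trains from non-target
sources, classifier confusion structure, spatial correlation between
sites, environmental interannual anomalies, and tidal forcing. Tests
passing on synthetic data therefore demonstrate the correctness of the
statistical machinery under the stated model family, not robustness to
every field artefact.

Determinism: every generator stage seeds its own stream from
`config$seed` plus a fixed stage offset, so identical seeds give
byte-identical tables and any stage can be rerun in isolation.

## Numerical choices and degenerate inputs

* PIG pmf switches analytically to the Poisson limit below
  $\sigma = 10^{-8}$.
* GARMA likelihood evaluations reject link-scale means beyond
  $|\eta| > 30$ with a large penalty, keeping the optimizer in a sane
  region; all-zero (constant) response series are refused as
  unidentifiable rather than fitted.
* Spearman correlation uses midranks; p-values are exact by full
  enumeration for $n \le 8$ and use the t-approximation otherwise;
  constant margins are reported as degenerate (`NA`) rather than a
  number.
* AIC ties (GARMA and GAM selection alike) break toward fewer
  parameters.
* GAM separation (binomial fitted values reproducing the data exactly)
  is flagged, and singular designs raise an error.
* Sites × months pooling for validation pools all years into calendar
  months by default — consistent with climatological monthly density
  products — with per-year aggregation available
  (`monthly_metrics(pool_years = FALSE)`).

## Problem sizes in the test and acceptance harnesses

Chosen as the smallest sizes at which the estimators' asymptotics are
visibly in force: GARMA coefficient-coverage harness, 5,000 hourly
observations × 100 replicates (±3 SE per parameter); distribution
selection, 10,000 observations × 100 replicates (20 for the
Poisson-data control); diel smoother recovery, 600 binary observations
× 50 replicates; environmental recovery, ~80 weekly records × 50
replicates; the acceptance script runs the same harnesses at 30
replicates each and reports every sample size alongside its value.

## Known limitations

* The GARMA likelihood is conditional (recursion-based), not an exact
  marginal likelihood; dispersion is a constant, not a covariate
  function as in the full gamlss framework.
* GCV smoothing selection is reproducible but less refined than REML;
  EDF attribution per term uses the trace of the influence matrix.
* The Gaussian-on-proportions environmental model can in principle
  predict outside [0, 1].
* Confusion-matrix thresholds, AR/MA orders and the recording-day
  convention are all explicit parameters precisely because the original
  analysis choices are unpublished.
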