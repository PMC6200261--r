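---
title: "Statistical methods behind codcast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind codcast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codcast)
```

## The prediction problem

Ocean temperature and salinity anomalies formed in the subpolar North
Atlantic are carried by the mean circulation through the Faroe–Shetland
Channel and across the Barents Sea Opening, arriving years after they were
first observed upstream. Because the Barents Sea cod stock co-varies with
the hydrography of the Atlantic inflow, an upstream anomaly observed today
carries information about the stock several years ahead: a regression of
stock biomass on hydrography observed $l$ years earlier is a genuine
$l$-year forecast, with no knowledge of the future required at forecast
time.

codcast implements that chain of reasoning as a tested pipeline: screen
candidate predictors by lagged correlation, fit lag-$l$ regression models,
score them honestly against null and persistence benchmarks, and ask where
the remaining error comes from.

## The regression model

For predictand $y_i$ (e.g. total stock biomass in year $i$) and predictors
$x_{i-l,n}$ (hydrographic series, all leading by the same $l$ years):

$$y_i = \alpha_0 + \alpha_1 x_{i-l,1} + \dots + \alpha_n x_{i-l,n} + \epsilon_i.$$

Coefficients are ordinary least squares; the residual standard deviation
uses the $n - p - 1$ denominator. A shared lead is the default because it
is what makes the forecast $l$ years ahead: `align()` supports
per-predictor leads, but mixing leads shortens the effective horizon to
the smallest one, so the pipeline treats that as a diagnostic device, not
a forecasting configuration.

Collinear predictors (hydrographic sections along one pathway are strongly
correlated) are handled by `orthogonalize_predictors()`: successive
residualization in the listed order. This changes coefficients but not the
column span, so fitted values and residuals are identical — which is
exactly the point: it shows that multicollinearity does not influence the
predictions, while making individual coefficients interpretable order by
order.

Residual validity is checked by `diagnose()`: Durbin–Watson
($\mathrm{DW} \approx 2(1-\rho_1)$) plus a significance test of the lag-1
residual autocorrelation, Shapiro–Wilk normality, and a homoscedasticity
check correlating $|\epsilon_i|$ with fitted values. Failed flags warn
rather than abort: annual environmental records are short and serially
correlated, and the cross-validation protocol below — whose random subsets
break up serial correlation — is the structural defence, with the
every-second-year refit (tested in the suite) confirming that coefficients
are not artifacts of lag-1 autocorrelation.

## Skill scoring

Two complementary metrics. The anomaly correlation $r$ measures phase
agreement; the variance-ratio Brier score

$$\beta = 1 - \sigma^2_e / \sigma^2_o$$

(error variance over predictand variance, both with $n-1$ denominators)
measures amplitude: $\beta = 1$ is perfect, $\beta = 0$ is no better than
the climatological mean, and $\beta < 0$ is worse than it. For a
well-specified Gaussian linear model $\beta \approx r^2$, a redundancy the
test suite exploits as a consistency check. This $\beta$ is deterministic;
it is not the probabilistic Brier score that shares its name.

`cross_validate()` repeats, 1000 times by default: draw a uniform random
80% of the design rows (without replacement, non-contiguous), fit, and
score both the fitting subset and the held-out 20%. Medians and
inter-quartile ranges over iterations are the reported skill; the
per-iteration model ensemble provides a per-year min–max prediction
envelope. Iterations whose held-out subset has fewer than 3 rows, zero
variance, or a rank-deficient fit are redrawn, with a hard stop at
$10\times$ the iteration count. Similar fitting- and prediction-period
medians indicate the skill is real rather than overfitted.

Two benchmarks calibrate expectations. The lag-$l$ persistence forecast
predicts year $i$ with the observation of year $i-l$; its skill equals
the predictand's lag-$l$ autocorrelation, the bar any dynamical claim must
clear. The random-chance model refits after independently permuting each
predictor column (predictand untouched) inside the same cross-validation
protocol; its prediction-period skill distribution should be centred on
zero, and is — the suite checks median and IQR. Externally produced
short-term forecasts are scored on the same footing by
`subsample_skill()` (1000 random 80% subsamples of the paired years).

## Significance with memory: the random phase test

Serially correlated series produce spuriously large sample correlations,
so screening significance uses phase-randomization surrogates: Fourier
transform the predictor, randomize the free phases uniformly (keeping
conjugate symmetry, the mean, and for even lengths the Nyquist
coefficient), and invert. Surrogates preserve the periodogram — hence the
full autocovariance — while destroying any phase-locked relation to the
predictand. The two-sided p-value uses the $+1$ continuity correction
$p = (1 + \#\{|r_s| \ge |r_{obs}|\})/(N+1)$. Surrogates are built on the
predictor only (the cited method's standard usage); the test stays close
to its nominal level even when both series are strongly red, which an
ordinary correlation t-test does not (the suite measures both).

Defaults the method's sources do not pin down, chosen here once: 1000
surrogates, two-sided $\alpha = 0.05$, and per-segment linear detrending
before screening correlations (matching the convention for lagged peak
correlation tables); detrending is configurable off, and prediction
models operate on anomalies *without* detrending, since the low-frequency
variations are part of what is being predicted. Anomalies subtract the
mean over a fixed baseline window (1950–2012 in the motivating
application; the full series span by default for synthetic data).

## Prediction intervals

The paper-style "95% prediction interval" is not formally defined in the
sources, so codcast states its choice: the standard OLS predictive
variance $\sigma^2 (1 + x_0'(X'X)^{-1}x_0)$ — residual variance plus
parameter uncertainty — with a two-sided t quantile. A
parameter-uncertainty-only interval is available via
`interval = "parameter"`. The full interval is validated in the suite
against a parametric-bootstrap oracle (10,000 draws, agreement within
10%). The headline forecast comes from the model fit on all available
data; the cross-validation ensemble supplies only the spread shading,
which maximizes training data where it matters.

## Error attribution and frequency decomposition

The prediction models deliberately exclude fishing pressure: their purpose
is to isolate the hydrographic signal. `error_attribution()` therefore
correlates the retrospective error (observed minus predicted) with
harvest-rate anomalies (catch divided by biomass, `harvest_rate()`) at
leads 0–5. A negative correlation with harvest leading means lenient
fishing was followed by under-predicted stock — the fingerprint of the
omitted covariate. Attribution correlations are computed without
detrending by default (the error and harvest anomalies are compared
as-is), with the same surrogate significance machinery.

`run_highpass_skill()` decomposes skill by time scale: predictions and
observations are high-pass filtered by subtracting a centered 5-year
running mean and re-correlated. The running mean was chosen over a sharper
(e.g. Butterworth) filter for transparency and exact complementarity
(high-pass plus low-pass reconstructs the series bit-for-bit; edges use
the available window, even widths take half-weighted endpoints). The cost
of that transparency is a soft cutoff: at a 2-year period the 5-point
boxcar still has gain $1/5$, so the high-pass retains $(1-1/5)^2 = 64\%$
of a Nyquist oscillation's variance, not all of it. If filtered skill is
much lower than unfiltered skill, the predictability resides in the
multi-year, low-frequency band.

## What the synthetic generator emulates

There is no public generative model for this system, so `make_scenario()`
adopts the minimal structure the regression framework assumes — exactly
the assumptions the analysis exploits, which is what makes it the right
test bed:

* an upstream index as a stationary AR(1) (red noise, 100-step burn-in),
* downstream sections as lag–gain–noise links
  ($T_t = g\,S_{t-\Delta} + \eta_t$), with the first $\Delta$ years
  explicitly missing (no wrap-around; calendar labels never move),
* a stock responding linearly to lagged hydrography plus a lagged
  harvest-rate effect and white noise,
* recruitment as the stock's driver signal led by 2 years with a lower
  signal fraction.

Because every simulated series is an exact linear combination of
independent AR(1) and white-noise sources, all population covariances are
available in closed form. The generator returns them as ground truth:
per-link peak lags and correlations, and the multiple correlation of any
predictor set at any leads (`theoretical_design_r()`), so recovery tests
compare estimates against algebra, not against other simulations.

Default parameters (fixed once, from that algebra, to sit in the
0.5–0.8 band typical of observed lagged peak correlations along this
pathway): 60 years; upstream AR(1) $a = 0.6$, SD 1; AMO→FSC lag 3, gain
0.8, noise 0.6 (link correlation 0.80); FSC→BSO lag 1, gain 0.85, noise
0.53 (upstream→BSO correlation 0.68 at lag 4); stock
$= 0.6\,\mathrm{FSC}_{t-4} + 0.5\,\mathrm{BSO}_{t-3} - 0.3\,H_{t-2} +
\epsilon(0.55)$, giving an upstream→stock correlation of 0.67 at lag 7
and a drivers-only multiple correlation of 0.86; harvest rate an
independent AR(1) ($a = 0.5$); recruitment lead 2, gain 0.4, noise 0.8
(hydrography→recruitment correlation ≈ 0.46, deliberately weaker than the
stock's). One structural consequence of compressing the real pathway into
a consistent chain: with FSC driving the stock at lag 4, the synthetic
hydrography→recruitment lead is $4 - 2 = 2$ years, whereas on real data —
where inflow sections lead the stock by ~7 years — the same construction
yields the familiar 5-year recruitment lead. Pipeline configuration keeps
both possible.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: no seasonal cycle or gridded structure, no
nonlinear stock dynamics or density dependence, no observation error in
the assessed biomass (real stock series are themselves model output,
revised retroactively), no regime shifts or non-stationarity in the
advective lags, and recruitment is not mechanistically coupled to
spawning biomass. Green tests certify that the statistical machinery does
what it claims under the model's own assumptions; they cannot certify
that the ocean obeys those assumptions.

## Numerical and design choices

* **Missing data**: listwise deletion at alignment; gaps are explicit
  `NA`s on a dense consecutive-year grid, never dropped year labels, so
  lead bookkeeping can never silently relabel a year.
* **Peak ties**: `peak_lag()` breaks exact `|r|` ties toward the smallest
  lag (the most parsimonious lead).
* **Lag search**: 0–10 years by default, comfortably covering the 1–7
  year lags of interest.
* **Seeds**: every stochastic function takes an explicit seed and
  restores the caller's RNG state; one root seed drives a pipeline run
  through documented stream splitting, making full runs byte-identical —
  the suite diffs the report files of two runs.
* **Insufficient overlap** at a lag marks that lag unavailable (`NA` with
  its pair count) rather than silently shrinking the profile; fewer than
  100 surrogates warns about p-value resolution instead of failing.
* **Rank deficiency** is an error pointing at orthogonalization, except
  inside cross-validation, where the iteration is redrawn and counted.
* **Durbin–Watson with year gaps** differences only within consecutive
  runs and says so in the report.

Problem sizes used by the test suite and acceptance script — 60-year
scenarios, 200 realizations for recovery statistics, 100 for rate
estimates, 300–1000 cross-validation iterations, 300–500 surrogates,
5000-year series for closed-form checks — were chosen so that Monte-Carlo
error is small against the tested tolerances while a full run stays in
the minutes range on a single core.

## Known limitations

Skill estimates inherit every caveat of short annual records: ~50
effective data points, serial correlation that cross-validation mitigates
but cannot erase, and the assumption that the advective pathway and its
lags are stationary. The Brier score is unbounded below and noisy on
11-point held-out subsets, which is why medians over many resamples are
reported. The random phase test requires gap-free, evenly spaced
segments; callers with gappy series must restrict or interpolate first,
and the package deliberately refuses to do that silently.

## A worked synthetic run

```{r example, eval = FALSE}
library(codcast)
report <- run_all(default_run_config(seed = 1), out_dir = "codcast_out")
print(report)
```

The written `codcast_out/` directory contains the screening table, skill
and persistence tables, retrospective and future forecasts with intervals
and ensemble spread, the harvest attribution profile, and a plain-text
summary whose every number is recomputable from the config and seed.
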