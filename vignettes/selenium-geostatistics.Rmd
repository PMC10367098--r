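---
title: "Geostatistical mapping of plasma selenium: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistical mapping of plasma selenium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sekrige)
```

## The problem and the model

District-scale biomarker surveys measure plasma selenium (Se) in
cluster-sampled participants — children 6–59 months and women of
reproductive age — at GPS-located households. The quantity of public-health
interest is not only the prevalence of deficiency but its spatial
structure: whether an unsampled individual at a given location is likely
to fall below the plasma Se concentration needed for optimal selenoprotein
activity.

`sekrige` treats plasma Se within one district × group stratum as a
stationary Gaussian random field

$$Z(x) = \mu + \eta(x) + \varepsilon,$$

with a constant mean $\mu$ (the only fixed effect), a spatially correlated
component $\eta$ with variance $c_1$ (partial sill) and correlation
$\rho(h; a)$, and uncorrelated nugget variation $\varepsilon$ with variance
$c_0$ — measurement error plus person-to-person variation at scales below
the sampling resolution. Two correlation families are offered, exponential
($\rho = e^{-h/a}$, effective range $\approx 3a$) and spherical (exact
range $a$), plus the pure-nugget degenerate case. The assumptions that
matter are stationarity of the mean (checked by the octile-skewness gate
and classified post plots, below) and Gaussian marginals (plasma Se in
these populations is close to symmetric; strata that are not are flagged
for transformation rather than processed).

## Exploratory stage

* **Summaries and quantiles.** All quantiles, including the octiles in the
  skewness statistic, use linear interpolation of order statistics
  (`stats::quantile` type 7) — one convention package-wide. At stratum
  sizes of 200–260 the choice among common definitions moves medians and
  quartiles by far less than the survey's measurement error.
* **Octile skewness gate.** $\mathrm{skew} = ((O_7-O_4)-(O_4-O_1))/(O_7-O_1)$
  with $O_1, O_4, O_7$ the 12.5/50/87.5% quantiles. Strata pass when
  $|\mathrm{skew}| < 0.2$. The absolute value is used: negative skewness of
  the same magnitude is no more compatible with the Gaussian assumption
  than positive.
* **GPS exclusions.** Records with missing/non-finite coordinates or more
  than a configurable buffer (default 1 km) outside the district polygon
  are removed before variogram estimation; values are never modified.
  Fewer than 100 retained points triggers a warning, reflecting the
  conventional minimum of 100–150 points for variogram estimation.
* **Outliers** in the upper tail are retained; robustness is delegated to
  the Cressie–Hawkins estimator rather than to data exclusion.
* **Inflammation screen.** Spearman correlations of Se with CRP and AGP
  with two-sided p-values; the decision is `flag_for_adjustment` only for
  a significant *negative* correlation (inflammation suppressing measured
  Se). Rank correlation is used because CRP/AGP are strongly right-skewed.
  The pipeline itself never adjusts concentrations.

## Variogram estimation

The empirical semivariogram is diagnostic only. Both the Matheron moment
estimator and the Cressie–Hawkins robust estimator
$\hat\gamma(h) = \tfrac12\,[\overline{|z_i-z_j|^{1/2}}]^4 /
(0.457 + 0.494/N(h))$ are computed (default bins of 1 km to half the
maximum inter-point distance). Parameters are estimated from the
likelihood, not by curve-fitting to bins: REML under the constant-mean
linear mixed model, the standard error-contrast formulation

$$\ell_R = -\tfrac12\left[(n-1)\log 2\pi + \log|V| +
  \log(\mathbf 1^\top V^{-1}\mathbf 1) + r^\top V^{-1} r\right],
  \qquad V = c_1 R(a) + c_0 I .$$

Numerically, the fit is profiled: for a fixed range $a$ the correlation
matrix $R(a)$ is eigendecomposed once, after which the spatial share
$\rho = c_1/(c_0+c_1)$ is a cheap one-dimensional maximisation and the
total variance and mean have closed forms. The outer search over $a$ uses
five log-spaced multi-starts spanning 1–20 km followed by golden-section
refinement. This agrees with `nlme::gls(corExp, nugget)` to
$10^{-6}$ in parameters and log-likelihood on interior optima (asserted in
the test suite), at a fraction of the cost for repeated fits.

**Range search bounds.** By default the range is searched within the
multi-start span (1–20 km). This is deliberate: on cluster-sampled data a
range below the within-cluster point spacing is not identifiable — a
sub-resolution "spatial" component is indistinguishable from nugget noise,
and an unbounded likelihood search will happily park arbitrary variance
splits there (an unconstrained `gls` fit on unstructured data can push the
spatial share toward 1 at ranges of tens of metres with a marginally
higher likelihood). Confining the search to scales the design can resolve
avoids these boundary estimates; `a_bounds` widens it when the sampling
supports more.

**Coincident locations** are kept, never jittered. Between distinct
records the nugget applies at any separation including zero (covariance
$c_1\rho(h)$ off-diagonal, $c_0+c_1$ on the diagonal), so duplicate
coordinates contribute pure-nugget contrasts.

## Kriging, cross-validation and model selection

Ordinary kriging is solved in semivariance form with a Lagrange
multiplier; all data in the stratum are used at every target (strata have
at most ~260 records, so a global neighbourhood is exact and cheap).
Weights sum to one by construction; predictions reproduce data exactly at
zero nugget.

Leave-one-out cross-validation holds the fitted parameters fixed (no
per-fold re-estimation) and computes the standardized squared prediction
error $\theta_i = (z_i - \hat z_{-i})^2/\sigma^2_{K,-i}$. Under a valid
model $\theta$ is approximately $\chi^2_1$, whose median
`qchisq(0.5, 1) = 0.455` is the calibration constant; the distribution-free
95% interval for the median uses binomial order statistics. Model
selection minimises $|\mathrm{median}(\theta) - 0.455|$ over candidates,
reporting alongside whether 0.455 lies in each candidate's interval; exact
ties resolve toward fewer parameters, then exponential before spherical.
Degenerate folds (duplicate locations under zero nugget make either the
fold system singular or its variance zero) are excluded and counted, never
silently dropped.

## Mapping

Prediction and variance surfaces are computed at nodes of a square grid
(spacing given in metres, default 250 m) anchored at the polygon
bounding-box lower-left corner — anchoring at a data-dependent point would
make outputs change with the data — and clipped by an even-odd
point-in-polygon rule with boundary nodes included. The probability of
deficiency below threshold $T$ is the Gaussian plug-in
$\Phi((T-\hat z)/\sigma_K)$; a zero-variance node degenerates to the
indicator, with ties at $T$ mapped to 0.5. Variogram-parameter uncertainty
is not propagated (plug-in kriging variance only).

Thresholds default to 70 µg/L (conventional deficiency) and the optimal
selenoprotein-activity cut-offs 100 (SELENOP), 84.9 (GPX3) and 64.8 (IDI)
µg/L, with strict inequality: a value exactly at a threshold is not
deficient. Children are mapped against IDI (growth and thyroid function),
women of reproductive age against GPX3 (antioxidant protection), both
configurable. Probabilities are labelled with the IPCC calibrated
likelihood scale — *virtually certain* (> 0.99), *very likely* (> 0.90),
*likely* (> 0.66), *about as likely as not* (0.33–0.66), *unlikely*,
*very unlikely*, *exceptionally unlikely* — with configurable boundaries;
the bands partition $[0,1]$.

District-average probabilities are unweighted means over grid nodes (an
equal-area lattice makes this the area average). Averaging over household
locations instead is exposed via `average_surface(surface, at = ...)`;
which population a survey's "average probability" refers to is a reporting
choice, and the node average is the default because it describes the
district area rather than the realised sample.

## The synthetic survey generator

`simulate_survey()` emulates a three-district pilot (Murewa, Shamva,
Mutasa; ~50 × 50 km each; 30 enumeration areas per district, households
Gaussian-scattered around cluster centres). Stratum means, total variances
and sample sizes follow the exploratory summaries of such a survey
(children: means 37–48.5 µg/L, variances 129–342, n = 201–223; women:
means 53.9–74.7, variances 279–470, n = 239–260). The split of variance
into nugget and spatial components and the ranges follow the survey
variogram narrative — strongest spatial structure in Murewa (share 0.6,
~6 km effective range), weakest in Shamva (share 0.35; short range for
women, ~12 km effective for children), Mutasa intermediate — with an
exponential family throughout and $a$ = effective range / 3. Within-cluster
spread defaults to 0.5 km, a modelling choice consistent with an
enumeration area of ~120 households; surveys do not usually report it.

The generator draws exact Gaussian fields by dense Cholesky factorisation
(rank-deficient covariances fall back to an eigendecomposition with
clamped eigenvalues, so zero-nugget duplicates are exactly continuous).
Negative simulated concentrations are possible under Gaussian marginals
with these means and are *retained* by default: truncation would bias the
parameter-recovery and calibration tests. A `truncate_at` option exists
for realism demonstrations. Reproducibility is by a counter-based child
seed scheme (`child_seed`), so each stage draws from its own stream.

What the generator does **not** emulate: non-Gaussian marginals (real CRP
is far more skewed than plasma Se), sampling weights and PPS inclusion
probabilities, GPS error, inter-district covariance, or covariate-driven
trends. Passing tests therefore demonstrate that the estimation machinery
is correct and calibrated under its own assumptions — not that those
assumptions hold in any particular field dataset.

## Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere; quartile post-plot classes send boundary
  ties to the lower bin; a constant stratum collapses to bin 1 with a
  warning.
* Octile skewness is undefined (NA, gate "indeterminate") for n < 8 or a
  zero inter-octile range.
* REML: eigenvalues of $R(a)$ clamped at zero; the spatial share is
  searched in $[0, 1-10^{-8}]$ with explicit endpoint comparison; the
  refinement never returns less than the best multi-start.
* Kriging variances are clipped at zero (they can be $-10^{-14}$ at data
  nodes); singular systems (duplicates with zero nugget) are errors at
  prediction time and flagged exclusions in cross-validation.
* Grids with no strictly interior node (spacing exceeding the polygon) are
  errors rather than a single boundary-corner "grid".

## Problem sizes

The test-suite and acceptance-script simulations use the reference
conditions: an exponential field with $c_0 = 40$, $c_1 = 120$, $a = 5$ km
sampled at 250 clustered points in a 50 km square; 100 replicates for
cross-validation calibration and parameter recovery, 50 for the
nugget-only and robustness studies; pipeline demonstrations use a 1 km
grid. These sizes give Monte-Carlo error comfortably below the assertion
tolerances while keeping a full run in minutes on one core.

## Known limitations

* Isotropic variograms only; no Matérn family; no trend beyond the
  constant mean (no universal kriging).
* One stratum at a time: districts are never pooled, matching the
  analysis unit of district-scale surveys, so nothing is learned across
  district boundaries.
* The probability maps inherit the plug-in assumption: kriging variance
  understates uncertainty because variogram-parameter error is ignored.
* On unstructured data the REML spatial share has a non-negligible null
  distribution at n ≈ 250 (spurious shares of 5–15% in a minority of
  replicates, with likelihood gains under 2 units); comparing candidate
  models by cross-validation, as the pipeline does, is the intended guard
  rather than trusting a single fitted share.
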