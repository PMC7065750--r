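---
title: "Methods: satellite kelp canopy series and community statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite kelp canopy series and community statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpcanopy)
```

This vignette is the package's account of its models, numerical
conventions, and the design decisions taken where the methodology left
genuine choices open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. Spectral mixture analysis

Emergent kelp canopy is bright in the near infrared while seawater is dark
everywhere, so a pixel that partially contains canopy is well described by
a sum-to-one linear mixture of two endmembers,

$$ r = f\,k + (1 - f)\,w + \varepsilon, \qquad f \in [0, 1], $$

with $r$ the observed reflectance spectrum, $k$ a single static kelp
endmember and $w$ one of $K$ seawater endmembers (default $K = 30$). The
seawater library is refreshed per image because water-leaving radiance
changes between dates (phytoplankton blooms, suspended sediment, sunglint);
trying every seawater candidate and keeping the lowest-RMSE model lets the
water background float while the kelp signature stays fixed.

`unmix_pixel()` solves the one-parameter least-squares problem in closed
form, $f = \langle r - w,\, k - w\rangle / \lVert k - w\rVert^2$, then
clips to $[0, 1]$ — fractions are physical proportions, and the RMSE is
evaluated at the clipped value so a wildly extrapolated fit cannot win the
model competition. RMSE is computed over all bands, unweighted. Ties in
minimal RMSE are broken by the lowest endmember index, making
`unmix_scene()` fully deterministic. The model uses exactly one kelp plus
one water spectrum per candidate: no shade endmember and no multi-endmember
combinations, which is the appropriate complexity for open-water kelp
canopy.

For real imagery the package does not prescribe how per-image seawater
spectra are obtained (typical practice samples offshore kelp-free pixels);
the synthetic generator sidesteps the question by perturbing a base
seawater library per date (`water_variability`, reflectance units).

## 2. From fraction maps to canopy series

**Site extraction.** A site series sums the canopy fraction of all pixels
whose *centres* fall within `radius_m` (default 100 m) of the site
coordinate, on a north-up grid with pixel-centre geometry — the convention
is fixed so extraction is testable to the pixel. Wider radii (400 m,
1000 m) are supported per site for locations with few kelp pixels nearby,
and a site with no pixel in range raises an explicit empty-site error
rather than returning a silent zero. The summed fraction ("canopy
density", in fraction·pixel units) is used as the canopy abundance proxy
throughout; every downstream statistic is either scale-invariant or
relative, so an unknown linear fraction-to-biomass coefficient would cancel
anyway.

**Cloud rule.** A date is removed when *strictly more* than 25 % of the
site's pixels are cloud-obscured; a date at exactly 25 % is retained
(`site_cloud_filter()`, threshold configurable).

**Trimesters.** Observations are averaged within calendar trimesters fixed
at Jan–Apr / May–Aug / Sep–Dec. Three 4-month bins per year is what
"trimester" implies; calendar alignment is the only choice that needs no
further convention. Interior empty trimesters are filled by linear
interpolation between the neighbouring observed trimesters and flagged
with `n_obs = 0`; leading and trailing gaps are left missing — the package
interpolates but never extrapolates.

**Proportional standardization.** Each series is divided by its maximum
over the full record, mapping it onto $[0, 1]$ and removing differences in
available kelp habitat between sites. An all-zero series is returned
unchanged (documented convention; no 0/0 NaN propagation).

**Regional series.** Image-level regional sums are averaged within each
trimester (absorbing tide- and current-driven variation between same-season
acquisitions) and then standardized the same way.

**Running mean.** The 2-year smoother is a centered 6-trimester moving
average with windows shrinking symmetrically at the edges (offsets
$-\lfloor (w-1)/2\rfloor \dots +\lceil (w-1)/2\rceil$); missing steps are
excluded from each window mean. It is applied identically to canopy,
SST-like and ENSO-like series before interannual comparison.

## 3. Climate coupling and trend

`lagged_pearson(x, y, lag)` correlates $y(t)$ with $x(t - \mathrm{lag})$:
the climate driver is passed as `x` and *leads* the canopy response, and a
one-year lag is exactly 3 trimesters. The two-sided p-value uses the t
distribution on the overlapping length. When the inputs are running means
this p-value is reported but *descriptive only* — smoothing inflates
autocorrelation and the nominal degrees of freedom overstate the evidence —
so the package computes it without endorsing it as inference; the
calibrated inferential tool for long-run behaviour is the trend test.

`gls_ar1_trend()` fits $y = a + b\,t$ by generalized least squares with an
AR1 error correlation $\mathrm{cor}(e_i, e_j) = \rho^{|t_i - t_j|}$ (gaps
enter through the exponent). $\rho$ is estimated by profiling over the grid
$-0.95, -0.94, \dots, 0.95$; the profile objective is the *restricted*
(REML) likelihood rather than the full likelihood, because maximum
likelihood biases $\rho$ low at the series lengths typical here (tens of
trimesters), which deflates the slope's standard error and inflates type-I
error; REML profiling is the standard remedy and is what dedicated
mixed-model software defaults to. The slope's standard error comes from
$(X' V^{-1} X)^{-1}\hat\sigma^2$ at the selected $\rho$, with a two-sided
t test on $n - 2$ degrees of freedom. The test suite verifies calibration
on trendless $\rho = 0.6$ series (and that ordinary regression is *not*
calibrated there), and agreement of slope, $\rho$ and standard error with
an independent mixed-model implementation.

**Validation regression.** Satellite fractions are validated against diver
densities with reduced major axis regression
(`slope = sign(r)\,sd(y)/sd(x)`), the symmetric fit appropriate when both
variables carry error. Per site the mean fraction of the four pixels
surrounding the survey coordinate is used; sites may be excluded a priori
(low geographic precision) and sites with no kelp signal within 500 m are
dropped automatically, since shadowed south-facing shores defeat satellite
retrieval at high southern latitudes.

**Temperature–nitrate.** `smooth_fit()` is a univariate penalized
cubic-spline smoother with fixed effective degrees of freedom (default 4 —
enough for one saturating bend without chasing noise; configurable).
Requesting `df` within 1 of the number of unique predictor values switches
to a numerically unpenalized spline, giving the interpolation limit.
`depletion_threshold()` evaluates whether fitted nitrate falls below a
fraction (default 10 %) of its fitted maximum above a given temperature.

## 4. Community statistics

Abundance tables are tibbles of densities (individuals·m⁻²; counts divided
by the 50 m² transect area). Bray–Curtis dissimilarities and the
ordination/PERMANOVA stack operate on ln(x+1)-transformed densities;
diversity metrics and the dominance table use raw values, whose percentage
shares are what a dominance index is defined on.

* **Diversity** (`diversity_metrics()`): $S$ = taxa with non-zero counts,
  $N$ = total individuals, Margalef $d = (S-1)/\ln N$, Shannon
  $H = -\sum p_i \ln p_i$ (natural logs throughout, for consistency with
  $H$), Pielou $J = H / \ln S$, reported missing for monocultures where
  $\ln S = 0$.
* **Dominance** (`ird_table()`): per taxon, percent numerical abundance
  (share of total density × 100) and percent frequency of occurrence
  (share of samples containing the taxon × 100);
  $\mathrm{IRD} = \%\mathrm{num} \times \%\mathrm{freq}$, reported rounded
  to the nearest integer (the convention of published dominance tables)
  alongside the unrounded value, ranked descending.
* **Bray–Curtis** (`bray_curtis()`): the dissimilarity form
  $d_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk}) \in [0,1]$.
  Two all-zero samples get distance 0 with a warning.
* **PERMANOVA** (`permanova_2way()`): the distance matrix is partitioned
  through its Gower-centered inner-product form; sums of squares are
  Type III (partial), defined by sum-to-zero contrasts, so each term —
  including main effects in unbalanced designs — is adjusted for all
  others. Inestimable terms (empty cells) raise a design error instead of
  being silently dropped. Each term's null distribution permutes
  reduced-model residuals (Freedman–Lane): with $H_r$ the reduced-model
  hat matrix and $G$ the centered matrix, permuted datasets are
  $G^* = H_r G H_r + P\,(I - H_r)G(I - H_r)\,P'$, and
  $p = (b + 1)/(m + 1)$ counts permuted pseudo-F values at or above the
  observed one — the +1 includes the observed statistic, so $p$ can never
  be 0. The permutation seed is a mandatory argument. Pairwise comparisons
  (`pairwise_permanova()`) run the one-way two-group test within each
  stratum and report $t = \sqrt{F}$; Monte-Carlo permutations (with seed)
  are used rather than exhaustive enumeration.
* **PCO** (`pco()`): eigen-decomposition of the Gower-centered matrix;
  coordinates are eigenvectors scaled by the square root of positive
  eigenvalues. Negative eigenvalues — expected for Bray–Curtis, which is
  non-Euclidean — are retained and reported, never silently dropped, and
  percent variation is computed on positive eigenvalues only, with no
  correction by default (a Lingoes correction is available by flag).
  Species vectors (`vector_overlay()`) are Pearson correlations of each
  taxon with the first two axes, retained when the stronger correlation
  reaches 0.5; zero-variance taxa are excluded with a warning.
* **MANOVA** (`pillai_manova()`): Pillai's trace
  $V = \sum_i \lambda_i/(1+\lambda_i)$ over the eigenvalues of $E^{-1}H$,
  chosen for robustness to variance heterogeneity, with the standard F
  approximation. A singular error matrix raises an error suggesting
  variable reduction.
* **t and chi-square**: paired t on site-matched differences, pooled-
  variance two-sample t (zero pooled variance with equal means yields
  $t = 0$ by convention; with unequal means it is an error), and a Pearson
  chi-square of compositional homogeneity without continuity correction.

## 5. The synthetic-data layer

The generators are first-class, tested code; their defaults are the study
conditions the rest of the package is verified under.

* **Endmember library** (`sim_endmember_library()`): the kelp spectrum is a
  fixed vegetation-like shape (dark visible, NIR plateau) and seawater
  spectra are dark with randomized visible-band variation; only this
  contrast, not radiative-transfer realism, matters to the algorithm. A
  spectral-angle separation floor (0.15 rad) between kelp and every
  seawater spectrum is enforced at generation.
* **Scenes** (`sim_scene_series()`): a Gaussian kelp patch whose per-date
  amplitude sets the true fraction field (any truth array can be supplied
  instead); each unmasked pixel mixes the truth with a randomly drawn,
  date-perturbed seawater spectrum plus Gaussian sensor noise (default
  0.002 reflectance, roughly the post-atmospheric-correction noise floor
  of 30 m-class sensors; a tenth of the faintest kelp signal of interest);
  clouds are independent per-pixel Bernoulli occlusions (default 5 %).
  Acquisition dates are drawn from August–April only, because usable
  high-latitude optical imagery does not exist in austral winter.
* **Climate coupling** (`sim_climate_canopy()`): the climate index is a
  standardized AR1 process with persistence 0.8 (ENSO-like interannual
  memory on trimester steps); canopy is a seasonal cycle minus
  `coupling_beta` times the lagged index plus noise, min-max rescaled to
  $[0, 1]$. Because the index carries no seasonal component, the lagged
  cross-correlation peaks at the planted lag, which is what the recovery
  tests exploit.
* **Surveys** (`sim_survey_tables()`): negative binomial counts (default
  dispersion size 1.5 — strongly overdispersed, matching transect tables
  whose standard deviations rival their means) with log-scale
  multiplicative factor effects on selected taxa, over a 2×2
  location × exposure design with 5/5/4/4 samples per cell (18 samples,
  the classic station count for this design). All-ones effect sizes give
  an exchangeable null used for type-I calibration.

What the generators deliberately do *not* emulate: sensor-specific band
responses and cross-calibration, atmospheric effects, tides and currents,
geolocation error, spatial autocorrelation of communities among transects,
and taxon–taxon correlation beyond what shared factors induce. Passing
tests therefore demonstrate algorithmic correctness and statistical
calibration under the stated generative conditions, not robustness to
every artefact of real imagery or field data.

## 6. Numerical conventions and problem sizes

* All randomness flows through explicit integer seeds in specs and function
  arguments; generators are pure functions of (spec, seed); the pipeline
  runner records every stage's seed in its run report.
* Raster I/O is a plain-text long-format CSV plus a YAML grid header, with
  `NA` in every band as the nodata/cloud convention; double columns are
  printed with 17 significant digits so round-trips are bit-exact.
* Permutation p-values are $(b+1)/(m+1)$; their attainable minimum is
  $1/(m+1)$.
* The rho grid (step 0.01) bounds the AR1 estimate away from ±1; profile
  ties resolve to the first maximum.
* The calibration studies in the test suite use 200 null communities
  (199 permutations each) for PERMANOVA and 500 trendless AR1 series
  (n = 80) for the trend test; brute-force equivalence of the unmixer is
  checked on 16×16 scenes against the full 30-endmember library; the
  end-to-end lag recovery runs a 27-year, 12×12-pixel world with one
  acquisition per trimester. These sizes were chosen to estimate the
  relevant rates to within about one percentage point while keeping the
  whole suite fast enough to run routinely.

## 7. Known limitations

* The canopy abundance proxy is the fraction sum; absolute biomass requires
  an external fraction-to-biomass coefficient that is region- and
  sensor-specific and is deliberately out of scope.
* The AR1 trend model assumes a single stationary autocorrelation
  parameter; regime shifts or seasonally varying persistence are not
  modelled (the trimester averaging and running means absorb much of the
  seasonal structure).
* Correlations between heavily smoothed series are reported with
  descriptive p-values only, as discussed above.
* `pairwise_permanova()` inherits the low permutation resolution of small
  strata; with very few samples per group the attainable minimum p may
  exceed 0.05, and such comparisons should be read as effect sizes
  ($t = \sqrt{F}$) rather than tests.
* PCO percent-variation values depend on the stated convention (positive
  eigenvalues, no correction); comparisons with software using Lingoes or
  Cailliez corrections should switch on the corresponding flag.
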