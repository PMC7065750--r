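# kelpcanopy

Giant kelp (*Macrocystis pyrifera*) forms floating canopies that are visible
to multispectral satellites, which makes 30 m-class imagery the only
practical way to monitor kelp dynamics over decades in remote regions such
as the kelp forests at the southern tip of South America. `kelpcanopy` is an
R package for marine ecologists working with such data. It implements, as
tested and reusable functions, the two halves of a kelp-forest monitoring
analysis:

1. **Remote sensing.** Per-pixel two-endmember spectral mixture analysis
   with per-image dynamic seawater endmembers; site and regional canopy
   time series on 4-month trimesters with cloud filtering, proportional
   standardization and 2-year running means; lagged Pearson correlations
   against climate indices (ENSO, SST); AR1-generalized-least-squares trend
   tests; reduced major axis validation against diver surveys; and a
   temperature–nitrate spline smoother.
2. **Community ecology.** Diversity indices (Margalef, Shannon, Pielou),
   the Index of Relative Dominance, Bray–Curtis dissimilarity, two-way
   PERMANOVA with permutation of residuals under a reduced model (Type III
   sums of squares), pairwise permutation comparisons, principal
   coordinates ordination with species vector overlays, Pillai's-trace
   MANOVA, t-tests, and chi-square composition tests.

A synthetic-data layer (`sim_*` functions) generates multiband scenes with
known canopy-fraction truth, lag-coupled climate/canopy series, and
factorial community tables, so every stage of the pipeline can be verified
by parameter recovery without any satellite download.

## The core model

Each unmasked pixel reflectance spectrum *r* is modelled as a sum-to-one
linear mixture of one static kelp endmember *k* and one of *K* seawater
endmembers *w* (default *K* = 30, refreshed per image to absorb changing
water conditions):

    r = f k + (1 - f) w + e,   f in [0, 1]

The least-squares fraction has the closed form
`f = <r - w, k - w> / <k - w, k - w>` (clipped to [0, 1]); the pixel keeps
the (f, RMSE) pair from the seawater endmember with the lowest RMSE. Site
series sum `f` over all pixels within a radius (default 100 m) of the site
coordinates, dropping dates with more than 25 % of site pixels obscured by
cloud. Trends are tested with `value = a + b t` under AR1 errors
(`cor(e_i, e_j) = rho^|i-j|`), with `rho` profiled on a grid; climate
coupling is measured as `cor(canopy(t), climate(t - lag))` with a one-year
(3-trimester) lag.

On the community side, dominance is summarized by
`IRD = %num x %freq` (percent numerical abundance times percent frequency
of occurrence), and assemblage structure is tested on Bray–Curtis
dissimilarities of ln(x+1)-transformed densities with a two-way
location x exposure PERMANOVA whose p-values come from permuting
reduced-model residuals (Freedman–Lane), `p = (b + 1) / (n_perm + 1)`.

## Worked example

Simulate a 20-year scene series whose canopy is depressed by a persistent
climate index one year earlier, unmix it, and recover the planted lag:

```r
library(kelpcanopy)

lib <- sim_endmember_library(n_water = 30, n_bands = 6, seed = 1)
cc  <- sim_climate_canopy(climate_spec(n_years = 20, coupling_beta = 1,
                                       lag_trimesters = 3, seed = 1))
sp  <- scene_spec(n_rows = 16, n_cols = 16, dates = cc$canopy$date + 45,
                  amplitude = cc$canopy$value, noise_sd = 0.005,
                  cloud_prob = 0.05, seed = 1)
maps <- unmix_stack(sim_scene_series(sp, lib), lib)

site <- extract_site_series(maps, site_coord = c(240, 240), radius_m = 100)
tri  <- proportional_standardize(to_trimesters(site))
lag_scan(running_mean(cc$climate$value, 6),
         running_mean(tri$value, 6), lags = 0:6)
#>     lag      r  p_value     n
#> 1     0 -0.585 9.11e- 7    60
#> 2     1 -0.792 7.79e-14    59
#> 3     2 -0.937 3.03e-27    58
#> 4     3 -0.998 2.09e-66    57   <- planted one-year lag, maximal |r|
#> 5     4 -0.943 1.81e-27    56
#> 6     5 -0.795 4.39e-13    55
#> 7     6 -0.571 6.38e- 6    54

gls_ar1_trend(tri)
#> AR1-GLS trend: slope = 0.0006452 (se 0.003992), rho = 0.66, t = 0.162,
#> p = 0.8722 (n = 60)
```

The correlation is strongest, and strongly negative, exactly at the planted
3-trimester lag (warm climate anomalies depress canopy a year later), and
the trend test correctly finds no long-term trend in a trendless
simulation. The p-values of smoothed series are descriptive: a 2-year
running mean inflates autocorrelation.

Community statistics run from tibbles of densities and factors:

```r
tabs <- sim_survey_tables(survey_spec(seed = 1))     # 18 samples, 2x2 design
d <- bray_curtis(ln1p_transform(tabs$abundance))
permanova_2way(d, tabs$factors, n_perm = 999, seed = 1)
#>               term df      SS      MS pseudo_F p_perm
#>           location  1 0.06146 0.06146   1.1763  0.319
#>           exposure  1 0.04441 0.04441   0.8501  0.515
#>  location:exposure  1 0.04014 0.04014   0.7682  0.574
#>           Residual 14 0.73146 0.05225       NA     NA
#>              Total 17 0.88160      NA     NA     NA

head(ird_table(tabs$abundance), 3)
#>   taxon          mean_density sd_density pct_num pct_freq   ird
#> 1 barnacle_dom           5.27       3.62    37.2      100  3719
#> 2 bivalve_frond          2.45       1.31    17.3      100  1730
#> 3 urchin_chilean         1.47       1.07    10.4      100  1038
```

This null simulation shows the expected non-significant factor effects with
the (1, 1, 1, 14, 17) degrees-of-freedom partition of an 18-sample
two-factor design.

A five-stage command-line pipeline (`simulate`, `unmix`, `series`, `stats`,
`report`) is exposed through `run_cli()`; see `?run_cli`. The methods and
all numerical conventions are documented in
`vignettes/kelp-canopy-methods.Rmd`.

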