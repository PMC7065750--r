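# Full synthetic chain: climate/canopy truth -> scenes -> unmixing -> site
# series -> trimesters -> standardization -> 2-year running means -> lag scan.
run_synthetic_chain <- function(seed, n_years = 27, n_rows = 12, n_cols = 12,
                                n_water = 12, noise_sd = 0.005,
                                cloud_prob = 0.05, coupling_beta = 1,
                                lag_trimesters = 3) {
  cc <- sim_climate_canopy(climate_spec(
    n_years = n_years, coupling_beta = coupling_beta,
    lag_trimesters = lag_trimesters, noise_sd = 0.05, seed = seed
  ))
  dates <- cc$canopy$date + 45                 # mid-trimester acquisitions
  lib <- sim_endmember_library(n_water, 6, seed = seed + 1)
  sp <- scene_spec(n_rows = n_rows, n_cols = n_cols, dates = dates,
                   amplitude = cc$canopy$value, noise_sd = noise_sd,
                   cloud_prob = cloud_prob, water_variability = 0.002,
                   seed = seed + 2)
  st <- sim_scene_series(sp, lib)
  maps <- unmix_stack(st, lib)
  site <- extract_site_series(maps, c(n_cols * 30 / 2, n_rows * 30 / 2),
                              radius_m = 100)
  tri <- proportional_standardize(to_trimesters(site))
  off <- which(cc$climate$date == tri$date[1]) - 1L
  clim <- cc$climate$value[seq_len(nrow(tri)) + off]
  smooth_canopy <- running_mean(tri$value, 6)
  smooth_climate <- running_mean(clim, 6)
  list(scan = lag_scan(smooth_climate, smooth_canopy, lags = 0:8),
       site_trimesters = tri, climate = cc$climate, maps = maps)
}
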