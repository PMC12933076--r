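# Shared simulation configurations and cached small datasets.

# fully null generator: no temperature effect, no FE variance, no selection
null_cfg <- function(seed, p0 = 0.5, n_regions = 4, psus_per_region = 4,
                     births_per_psu = 100, year_range = c(2009, 2012), ...) {
  sim_config(seed = seed, n_regions = n_regions,
             psus_per_region = psus_per_region,
             births_per_psu = births_per_psu, year_range = year_range,
             grid = list(n_lat = 2, n_lon = 2 * n_regions),
             p0 = p0,
             fe_true = list(sd_region_month = 0, sd_region_year = 0), ...)
}

# one small simulated world, built once per test run and reused
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- null_cfg(seed = 42, births_per_psu = 150)
      climate <- simulate_climate(cfg)
      psus <- simulate_psus(cfg)
      births <- simulate_births(cfg, climate, psus)
      kept <- suppressMessages(filter_sample(births))
      cache <<- list(cfg = cfg, climate = climate, psus = psus,
                     births = births, kept = kept)
    }
    cache
  }
})

# constant-temperature climate helper (no seasonality, noise or trend)
constant_climate_cfg <- function(seed, temp, ...) {
  null_cfg(seed,
           climatology = list(regional_mean_tmax = temp,
                              seasonal_amplitude = 0, daily_noise_sd = 0,
                              daily_ar1 = 0, warming_trend = 0), ...)
}
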