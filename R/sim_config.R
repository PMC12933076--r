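#' Simulation configuration for DHS-like birth records and gridded climate
#'
#' Builds and validates the configuration that drives the synthetic-data
#' generator. The generator emulates the statistical structure of
#' georeferenced survey birth records (one row per live birth with sex,
#' timing, location and maternal covariates) linked to gridded daily maximum
#' temperature on a regular 0.5 x 0.5 degree grid, with a known ground-truth
#' temperature-to-sex response injected through two channels: a per-day
#' linear effect on the probability of a male birth (`beta_true`, the
#' prenatal-mortality channel) and a sex-selective-abortion channel whose
#' probability falls with hot days in the second trimester
#' (`abortion_model`).
#'
#' @param seed integer; master seed for all generator randomness.
#' @param mode `"ssa"` or `"india"`; sets the baseline proportion male
#'   (`p0` = 0.5087 or 0.5237) and the default share of "northern"
#'   (son-preference) regions (0 or 0.5). Any field can still be overridden.
#' @param n_regions number of subnational regions.
#' @param psus_per_region number of primary sampling units (survey clusters)
#'   per region.
#' @param births_per_psu live births generated per PSU.
#' @param year_range integer vector `c(first, last)` of birth calendar years;
#'   must span at least 3 years so region-by-year effects are identified.
#'   Climate is generated with 12 lead-in months before `first`.
#' @param grid list: `lat0`, `lon0` (south-west corner), `n_lat`, `n_lon`,
#'   `cell_size_deg` (default 0.5). `n_lon` must be a multiple of
#'   `n_regions`: regions tile the grid in contiguous longitude blocks.
#' @param climatology list: `regional_mean_tmax` (deg C, scalar or one per
#'   region), `seasonal_amplitude` (deg C), `daily_noise_sd` (deg C,
#'   marginal SD of the daily noise), `daily_ar1` in `[0, 1)`,
#'   `warming_trend` (deg C per year), `hemisphere_south` (logical, one per
#'   region or scalar; flips the seasonal phase by half a year).
#' @param rainfall list: `monthly_mean` (mm), `seasonal_amplitude` (mm),
#'   `noise_sd` (mm). Monthly totals are truncated at zero.
#' @param p0 baseline proportion male in `(0, 1)`.
#' @param beta_true 3 x 5 matrix of per-day effects on the proportion male;
#'   rows `T1`, `T2`, `T3`, columns `lt15`, `b15_20`, `b20_25`, `b25_30`,
#'   `gt30`. The reference column `b15_20` must be zero.
#' @param fe_true list: `sd_region_month`, `sd_region_year` - SDs of the
#'   Gaussian region-by-calendar-month and region-by-year effects added to
#'   the linear predictor.
#' @param composition list: `urban_prob`, `secondary_plus_prob`,
#'   `parity_probs` (distribution of completed sibship size 1..6),
#'   `age_first_mean`, `age_first_sd` (maternal age at first birth),
#'   `month_weights` (12 birth-seasonality weights),
#'   `migration_prob` (probability a mother moved in the year before birth).
#' @param abortion_model list: `enabled`, `q0` (baseline probability that an
#'   eligible female pregnancy is aborted), `gamma` (per-hot-day reduction
#'   of that probability; a hot day is a day with maximum temperature above
#'   20 deg C in the second trimester). Eligibility: live parity >= 4,
#'   no previous son, northern region.
#' @param beta_modifier optional list `list(column =, value =)`; when set,
#'   `beta_true` applies only to births whose covariate `column` equals
#'   `value` (used to inject stratum-specific biological effects).
#' @param gestation_jitter_months 0 (default) or 1; when 1 the exposure
#'   window used to generate the true response is shifted by -1/0/+1 months
#'   uniformly at random per birth, emulating gestational-length
#'   misclassification. The recorded birth month is not changed.
#'
#' @return a validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_regions = 2, psus_per_region = 5,
#'                   births_per_psu = 50, year_range = c(2008, 2011))
sim_config <- function(seed = 1L,
                       mode = c("ssa", "india"),
                       n_regions = 10L,
                       psus_per_region = 20L,
                       births_per_psu = 100L,
                       year_range = c(2005L, 2014L),
                       grid = list(),
                       climatology = list(),
                       rainfall = list(),
                       p0 = NULL,
                       beta_true = NULL,
                       fe_true = list(),
                       composition = list(),
                       abortion_model = list(),
                       beta_modifier = NULL,
                       gestation_jitter_months = 0L) {
  mode <- match.arg(mode)

  grid_def <- list(lat0 = -10, lon0 = 10, n_lat = 2L,
                   n_lon = 2L * n_regions, cell_size_deg = 0.5)
  grid <- utils::modifyList(grid_def, grid)

  clim_def <- list(regional_mean_tmax = 28, seasonal_amplitude = 5,
                   daily_noise_sd = 3, daily_ar1 = 0.5,
                   warming_trend = 0.02, hemisphere_south = FALSE)
  climatology <- utils::modifyList(clim_def, climatology)

  rain_def <- list(monthly_mean = 80, seasonal_amplitude = 50, noise_sd = 30)
  rainfall <- utils::modifyList(rain_def, rainfall)

  if (is.null(p0)) p0 <- if (mode == "ssa") 0.5087 else 0.5237

  if (is.null(beta_true)) beta_true <- matrix(0, 3, 5)
  beta_true <- as.matrix(beta_true)
  dimnames(beta_true) <- list(c("T1", "T2", "T3"),
                              c("lt15", "b15_20", "b20_25", "b25_30", "gt30"))

  fe_def <- list(sd_region_month = 0.005, sd_region_year = 0.005)
  fe_true <- utils::modifyList(fe_def, fe_true)

  comp_def <- list(urban_prob = 0.26,
                   secondary_plus_prob = 0.16,
                   parity_probs = c(0.15, 0.15, 0.20, 0.20, 0.15, 0.15),
                   age_first_mean = 19, age_first_sd = 3,
                   month_weights = 1 + 0.1 * cos(2 * pi * (1:12) / 12),
                   migration_prob = 0.05,
                   north_fraction = if (mode == "india") 0.5 else 0)
  composition <- utils::modifyList(comp_def, composition)

  ab_def <- list(enabled = FALSE, q0 = 0.3, gamma = 0.015)
  abortion_model <- utils::modifyList(ab_def, abortion_model)

  cfg <- structure(list(
    seed = as.integer(seed), mode = mode,
    n_regions = as.integer(n_regions),
    psus_per_region = as.integer(psus_per_region),
    births_per_psu = as.integer(births_per_psu),
    year_range = as.integer(year_range),
    grid = grid, climatology = climatology, rainfall = rainfall,
    p0 = p0, beta_true = beta_true, fe_true = fe_true,
    composition = composition, abortion_model = abortion_model,
    beta_modifier = beta_modifier,
    gestation_jitter_months = as.integer(gestation_jitter_months)
  ), class = "sim_config")

  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail_if(length(cfg$year_range) != 2 ||
            diff(cfg$year_range) < 2,
          "year_range must span at least 3 calendar years (got %s)",
          paste(cfg$year_range, collapse = "-"))
  g <- cfg$grid
  fail_if(g$cell_size_deg <= 0, "grid cell_size_deg must be > 0")
  fail_if(g$n_lat < 1 || g$n_lon < 1, "grid must have at least one cell")
  fail_if(g$n_lon %% cfg$n_regions != 0,
          "grid n_lon (%d) must be a multiple of n_regions (%d)",
          g$n_lon, cfg$n_regions)
  fail_if(any(abs(cfg$beta_true[, "b15_20"]) > 0),
          "beta_true for the 15-20 C reference bin must be zero")
  fail_if(cfg$p0 <= 0 || cfg$p0 >= 1, "p0 must be in (0,1)")
  ar1 <- cfg$climatology$daily_ar1
  fail_if(ar1 < 0 || ar1 >= 1, "daily_ar1 must be in [0, 1)")
  ab <- cfg$abortion_model
  fail_if(ab$q0 < 0 || ab$q0 > 1, "abortion_model q0 must be in [0, 1]")
  fail_if(ab$gamma < 0, "abortion_model gamma must be >= 0")
  pp <- cfg$composition$parity_probs
  fail_if(any(pp < 0) || abs(sum(pp) - 1) > 1e-8,
          "composition parity_probs must be a probability vector")

  # Worst-case linear predictor: largest per-window |beta| times the maximum
  # number of days the window can contain, plus a 4-sigma allowance for the
  # Gaussian fixed effects. Rejects configurations that could push the
  # Bernoulli probability outside [0, 1].
  max_days <- c(T1 = 93, T2 = 93, T3 = 124)
  worst <- sum(apply(abs(cfg$beta_true), 1, max) * max_days) +
    4 * (cfg$fe_true$sd_region_month + cfg$fe_true$sd_region_year)
  fail_if(cfg$p0 + worst > 1 || cfg$p0 - worst < 0,
          paste0("configuration can push birth probability outside [0,1]: ",
                 "p0 = %.4f, worst-case |linear predictor| = %.4f"),
          cfg$p0, worst)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> mode=%s seed=%d | %d regions x %d PSUs x %d births, years %d-%d\n",
              x$mode, x$seed, x$n_regions, x$psus_per_region, x$births_per_psu,
              x$year_range[1], x$year_range[2]))
  cat(sprintf("  grid %dx%d @ %.2f deg | p0=%.4f | abortion channel %s\n",
              x$grid$n_lat, x$grid$n_lon, x$grid$cell_size_deg, x$p0,
              if (isTRUE(x$abortion_model$enabled)) "on" else "off"))
  if (any(x$beta_true != 0)) {
    cat("  nonzero beta_true (prob/day):\n")
    print(x$beta_true[, colSums(abs(x$beta_true)) > 0, drop = FALSE])
  }
  invisible(x)
}
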