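#' Simulate gridded daily maximum temperature and monthly rainfall
#'
#' Generates a `climate_fields` object covering the configured year range
#' plus 12 lead-in months (so every birth in the range has 11 lag months of
#' climate). Daily maximum temperature in each grid cell is
#' `regional mean + seasonal sinusoid + warming trend + AR(1) noise`; the
#' seasonal phase flips by half a year for regions flagged southern
#' hemisphere. The AR(1) innovations are scaled so the marginal SD of the
#' noise equals `daily_noise_sd` regardless of `daily_ar1`. Monthly rainfall
#' is an analogous sinusoid plus white noise, truncated at zero.
#'
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a `climate_fields` list: `tmax` array `[day, lat, lon]` (deg C)
#'   with a `dates` axis, `rain` array `[month, lat, lon]` (mm) with a
#'   `months` axis (integer year*12 + month - 1), and `grid` metadata
#'   including the region of every longitude column.
#' @export
simulate_climate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- cfg$grid
  cl <- cfg$climatology
  first <- cfg$year_range[1] - 1L       # 12 lead-in months
  last <- cfg$year_range[2]
  dates <- seq(as.Date(sprintf("%d-01-01", first)),
               as.Date(sprintf("%d-12-31", last)), by = "day")
  n_days <- length(dates)
  n_cells <- g$n_lat * g$n_lon

  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  year <- lt$year + 1900L
  day_ym <- ym_index(year, lt$mon + 1L)

  # region of each longitude column (contiguous blocks)
  cols_per_region <- g$n_lon %/% cfg$n_regions
  region_of_col <- rep(seq_len(cfg$n_regions), each = cols_per_region)
  region_of_cell <- rep(region_of_col, each = g$n_lat)  # cell = i + (j-1)*n_lat

  rmean <- rep_len(cl$regional_mean_tmax, cfg$n_regions)
  south <- rep_len(cl$hemisphere_south, cfg$n_regions)

  # deterministic components, per cell
  phase <- ifelse(south, pi, 0)                       # per region
  seasonal <- outer(doy, phase[region_of_cell],
                    function(d, ph) cos(2 * pi * (d - 196) / 365.2425 + ph)) *
    cl$seasonal_amplitude
  base <- matrix(rmean[region_of_cell], n_days, n_cells, byrow = TRUE)
  trend <- cl$warming_trend * (year - cfg$year_range[1])

  noise <- with_local_seed(derive_seed(cfg$seed, 1L), {
    innov_sd <- cl$daily_noise_sd * sqrt(1 - cl$daily_ar1^2)
    e <- matrix(stats::rnorm(n_days * n_cells, sd = innov_sd), n_days, n_cells)
    if (cl$daily_ar1 > 0) {
      e <- stats::filter(e, cl$daily_ar1, method = "recursive")
      e <- matrix(as.numeric(e), n_days, n_cells)
    }
    e
  })

  tmax <- base + seasonal + trend + noise
  dim(tmax) <- c(n_days, g$n_lat, g$n_lon)

  # monthly rainfall over the same span
  months <- seq.int(ym_index(first, 1L), ym_index(last, 12L))
  n_months <- length(months)
  mon <- ym_month(months)
  rain_season <- outer(mon, phase[region_of_cell],
                       function(m, ph) cos(2 * pi * (m - 7) / 12 + ph)) *
    cfg$rainfall$seasonal_amplitude
  rain_noise <- with_local_seed(derive_seed(cfg$seed, 2L), {
    matrix(stats::rnorm(n_months * n_cells, sd = cfg$rainfall$noise_sd),
           n_months, n_cells)
  })
  rain <- pmax(0, cfg$rainfall$monthly_mean + rain_season + rain_noise)
  dim(rain) <- c(n_months, g$n_lat, g$n_lon)

  structure(list(
    grid = c(g, list(region_of_col = region_of_col)),
    dates = dates, day_ym = day_ym,
    tmax = tmax,
    months = months, rain = rain
  ), class = "climate_fields")
}

#' @export
print.climate_fields <- function(x, ...) {
  cat(sprintf("<climate_fields> %d days (%s to %s), grid %dx%d @ %.2f deg, %d months of rainfall\n",
              length(x$dates), min(x$dates), max(x$dates),
              x$grid$n_lat, x$grid$n_lon, x$grid$cell_size_deg,
              length(x$months)))
  invisible(x)
}

#' Extract the daily series of one grid cell
#'
#' @param climate a `climate_fields` object.
#' @param i,j latitude / longitude cell indices.
#' @return data.frame with columns `date`, `tmax`.
#' @export
cell_series <- function(climate, i, j) {
  data.frame(date = climate$dates, tmax = climate$tmax[, i, j])
}
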