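# Orchestration and plain-text artifact I/O. Tabular artifacts are CSV
# (UTF-8, documented headers); gridded climate is stored as plain CSV
# matrices plus a JSON metadata file; results are JSON.

#' Write / read a climate object as plain arrays + JSON metadata
#'
#' `tmax.csv` holds one row per day (first column `date`), one column per
#' grid cell in column-major `[lat, lon]` order; `rain.csv` the analogous
#' monthly matrix; `grid.json` the grid metadata.
#'
#' @param climate a `climate_fields` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly (`write_climate`); a `climate_fields` object
#'   (`read_climate`).
#' @export
write_climate <- function(climate, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- climate$grid
  n_cells <- g$n_lat * g$n_lon
  tm <- climate$tmax; dim(tm) <- c(length(climate$dates), n_cells)
  rn <- climate$rain; dim(rn) <- c(length(climate$months), n_cells)
  cell_names <- paste0("c", rep(seq_len(g$n_lat), g$n_lon), "_",
                       rep(seq_len(g$n_lon), each = g$n_lat))
  utils::write.csv(data.frame(date = format(climate$dates),
                              round(tm, 4), check.names = FALSE) |>
                     stats::setNames(c("date", cell_names)),
                   file.path(dir, "tmax.csv"), row.names = FALSE)
  utils::write.csv(data.frame(ym = climate$months, round(rn, 3)) |>
                     stats::setNames(c("ym", cell_names)),
                   file.path(dir, "rain.csv"), row.names = FALSE)
  jsonlite::write_json(g, file.path(dir, "grid.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_climate
#' @export
read_climate <- function(dir) {
  g <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  tm <- utils::read.csv(file.path(dir, "tmax.csv"), check.names = FALSE)
  rn <- utils::read.csv(file.path(dir, "rain.csv"), check.names = FALSE)
  dates <- as.Date(tm$date)
  tmax <- as.matrix(tm[, -1]); dim(tmax) <- c(length(dates), g$n_lat, g$n_lon)
  months <- rn$ym
  rain <- as.matrix(rn[, -1]); dim(rain) <- c(length(months), g$n_lat, g$n_lon)
  lt <- as.POSIXlt(dates)
  structure(list(grid = g, dates = dates,
                 day_ym = ym_index(lt$year + 1900L, lt$mon + 1L),
                 tmax = tmax, months = months, rain = rain),
            class = "climate_fields")
}

#' A small end-to-end configuration
#'
#' Two regions, five PSUs each, three years, ~2,000 births: completes the
#' whole pipeline in seconds and is used by the packaged smoke test.
#'
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
smoke_config <- function(seed = 1L) {
  sim_config(seed = seed, n_regions = 2, psus_per_region = 5,
             births_per_psu = 200, year_range = c(2010, 2012),
             grid = list(n_lat = 2, n_lon = 4))
}

#' Run the whole chain: simulate, link, fit, subgroups, report, project
#'
#' Executes every stage in order, writing plain-text artifacts plus a
#' manifest with content hashes to `out_dir`. With `resume = TRUE` a stage
#' whose artifact already exists is loaded from disk instead of recomputed,
#' so deleting one artifact re-runs only that stage and the ones after it.
#'
#' @param cfg a [sim_config()].
#' @param out_dir run directory.
#' @param subgroup_dims character vector of dimensions for
#'   [run_subgroups()] (default none).
#' @param scenario optional uniform temperature shift (deg C) for
#'   [project_scenario()].
#' @param resume reuse existing artifacts.
#' @return list with the in-memory results of every stage plus the manifest.
#' @export
run_pipeline <- function(cfg, out_dir, subgroup_dims = character(0),
                         scenario = NULL, resume = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  stage <- function(file, compute, write, read) {
    if (resume && all(file.exists(pth(file)))) return(read())
    val <- compute()
    write(val)
    val
  }

  climate <- stage("climate/grid.json",
                   function() simulate_climate(cfg),
                   function(v) write_climate(v, pth("climate")),
                   function() read_climate(pth("climate")))
  psus <- stage("psus.csv",
                function() simulate_psus(cfg),
                function(v) utils::write.csv(v, pth("psus.csv"), row.names = FALSE),
                function() utils::read.csv(pth("psus.csv")))
  births <- stage("births.csv",
                  function() {
                    b <- simulate_births(cfg, climate, psus)
                    if (isTRUE(cfg$abortion_model$enabled)) {
                      b <- apply_son_preference(b, climate, cfg, psus)
                    }
                    b
                  },
                  function(v) utils::write.csv(v, pth("births.csv"),
                                               row.names = FALSE),
                  function() utils::read.csv(pth("births.csv")))
  kept <- filter_sample(births)
  exposure <- stage("exposure.csv",
                    function() build_exposure(kept, climate, psus),
                    function(v) utils::write.csv(v, pth("exposure.csv"),
                                                 row.names = FALSE),
                    function() {
                      x <- utils::read.csv(pth("exposure.csv"))
                      nm <- names(x)
                      attr(x, "treatment_cols") <-
                        grep("^t[123]_bin", nm, value = TRUE)
                      attr(x, "control_cols") <-
                        grep("^lag1[01]_bin", nm, value = TRUE)
                      attr(x, "rain_cols") <- grep("^rain_lag", nm, value = TRUE)
                      x
                    })
  fit <- stage("fit.json",
               function() srb_fit(exposure),
               function(v) {
                 est <- stats::coef(v)
                 jsonlite::write_json(list(
                   coefficients = as.list(est[!is.na(est)]),
                   se = as.list(v$se), p = as.list(v$pval),
                   n_obs = v$nobs, n_clusters = v$n_clusters,
                   n_dropped_singletons = v$n_dropped_singletons,
                   dropped_collinear = v$dropped_collinear,
                   absorption_iterations = v$iterations,
                   final_delta = v$final_delta
                 ), pth("fit.json"), auto_unbox = TRUE, digits = NA)
               },
               function() srb_fit(exposure))   # refit: model objects are cheap

  effects <- effect_table(fit, exposure)
  utils::write.csv(effects, pth("effects.csv"), row.names = FALSE)

  subgroups <- NULL
  if (length(subgroup_dims)) {
    subgroups <- lapply(subgroup_dims, function(d) {
      run_subgroups(kept, climate, psus, d)$table
    })
    names(subgroups) <- subgroup_dims
    utils::write.csv(do.call(rbind, lapply(subgroup_dims, function(d)
      cbind(dimension = d, subgroups[[d]]))),
      pth("subgroups.csv"), row.names = FALSE)
  }

  projection <- NULL
  if (!is.null(scenario)) {
    projection <- project_scenario(fit, climate, psus, kept, scenario)
    jsonlite::write_json(projection[c("delta_p", "baseline_srb",
                                      "new_srb", "delta_srb")],
                         pth("projection.json"), auto_unbox = TRUE, digits = NA)
  }

  arts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  arts <- arts[basename(arts) != "manifest.json"]
  manifest <- list(
    config = unclass(cfg)[c("seed", "mode", "n_regions", "psus_per_region",
                            "births_per_psu", "year_range", "p0")],
    hashes = as.list(tools::md5sum(arts) |>
                       stats::setNames(sub(paste0(out_dir, "/?"), "",
                                           arts, fixed = FALSE)))
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  list(climate = climate, psus = psus, births = births, exposure = exposure,
       fit = fit, effects = effects, subgroups = subgroups,
       projection = projection, manifest = manifest)
}

#' Write the small hand-enumerable fixtures used by the unit tests
#'
#' Three plain-text fixtures: a 12-month single-cell daily temperature
#' series with known per-month bin counts, a 12-row / 3-cluster toy
#' regression for the sandwich-variance check, and a 20-row birth table for
#' the son-preference classification check. Byte-stable given the seed.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return named character vector of the files written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(daily = file.path(dir, "daily_series_10mo.csv"),
             vcov = file.path(dir, "cluster_toy_12row.csv"),
             sonpref = file.path(dir, "son_preference_20row.csv"))

  with_local_seed(seed, {
    dates <- seq(as.Date("2011-01-01"), as.Date("2011-12-31"), by = "day")
    tmax <- round(22 + 10 * sin(seq_along(dates) / 20) +
                    stats::rnorm(length(dates)), 2)
    utils::write.csv(data.frame(date = format(dates), tmax = tmax),
                     files["daily"], row.names = FALSE)

    toy <- data.frame(y = round(stats::rnorm(12), 4),
                      x1 = round(stats::rnorm(12), 4),
                      x2 = round(stats::rnorm(12), 4),
                      cluster = rep(1:3, each = 4))
    utils::write.csv(toy, files["vcov"], row.names = FALSE)

    sp <- data.frame(
      birth_id = 1:20,
      mother_id = rep(1:4, each = 5),
      parity = rep(1:5, 4),
      male = c(0,0,0,0,1, 1,0,0,0,0, 0,0,0,1,0, 0,1,1,0,0),
      north = rep(c(1,1,0,0), each = 5))
    sp$sonless_before <- as.integer(stats::ave(sp$male, sp$mother_id,
                                               FUN = function(m) cumsum(m) - m) == 0)
    utils::write.csv(sp, files["sonpref"], row.names = FALSE)
  })
  files
}
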