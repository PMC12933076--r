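#' Gestational window specification
#'
#' The gestational period is approximated by the birth month and the nine
#' months before it. In `"trimester"` mode the third trimester is the birth
#' month plus lags 1-3, the second trimester lags 4-6, and the first
#' trimester lags 7-9; lags 10-11 enter as autocorrelation controls. In
#' `"monthly"` mode lags 0-9 each form their own window, with the same
#' controls.
#'
#' @param mode `"trimester"` or `"monthly"`.
#' @return list with `mode`, `windows` (named list of lag vectors) and
#'   `control_lags`.
#' @export
gest_window_spec <- function(mode = c("trimester", "monthly")) {
  mode <- match.arg(mode)
  windows <- if (mode == "trimester") {
    list(T3 = 0:3, T2 = 4:6, T1 = 7:9)
  } else {
    stats::setNames(lapply(0:9, identity), paste0("m", 0:9))
  }
  lags <- sort(unlist(windows, use.names = FALSE))
  stopifnot(identical(lags, 0:9))          # disjoint, union = 0..9
  structure(list(mode = mode, windows = windows, control_lags = 10:11),
            class = "gest_window_spec")
}

#' Temperature bin specification
#'
#' Absolute bins are the 5 deg C intervals
#' `(-Inf,15), [15,20), [20,25), [25,30), [30,Inf)` with `[15,20)` as the
#' reference; bin edges are half-open on the right, so 15.0 falls in
#' `[15,20)` and 30.0 in `[30,Inf)`. Relative bins are per-PSU deciles of a
#' long-term reference temperature distribution (see [longterm_deciles()]);
#' the reference decile is configurable.
#'
#' @param kind `"absolute"` or `"relative"`.
#' @param edges numeric cut points for absolute bins.
#' @param cutpoints for relative bins: a matrix with 9 columns of decile
#'   cutpoints, one row per PSU, rownames = `psu_id`.
#' @param reference index of the reference bin (absolute default: 2, the
#'   15-20 deg C bin; relative default: 1, the lowest decile).
#' @return a `bin_spec` list with `labels` and `reference` resolved.
#' @export
bin_spec <- function(kind = c("absolute", "relative"),
                     edges = c(15, 20, 25, 30),
                     cutpoints = NULL,
                     reference = NULL) {
  kind <- match.arg(kind)
  if (kind == "absolute") {
    fail_if(is.unsorted(edges, strictly = TRUE), "bin edges must be increasing")
    labels <- c("lt15", "b15_20", "b20_25", "b25_30", "gt30")
    if (length(edges) != 4) {
      labels <- c(paste0("lt", edges[1]),
                  paste0("b", utils::head(edges, -1), "_", edges[-1]),
                  paste0("gt", edges[length(edges)]))
    }
    if (is.null(reference)) reference <- 2L
  } else {
    fail_if(is.null(cutpoints), "relative bins need per-PSU decile cutpoints")
    cutpoints <- as.matrix(cutpoints)
    fail_if(ncol(cutpoints) != 9, "relative cutpoints must have 9 columns")
    bad <- apply(cutpoints, 1, is.unsorted)   # non-decreasing allowed
    fail_if(any(bad), "relative cutpoints must be non-decreasing per PSU")
    labels <- paste0("d", 1:10)
    if (is.null(reference)) reference <- 1L
  }
  fail_if(reference < 1 || reference > length(labels),
          "reference bin index out of range")
  structure(list(kind = kind, edges = edges, cutpoints = cutpoints,
                 labels = labels, reference = as.integer(reference)),
            class = "bin_spec")
}

#' Locate the grid cell containing a point
#'
#' Cells are half-open `[edge, edge + cell_size)` in both coordinates, so a
#' point on a shared edge belongs to the cell whose lower/left edge it lies
#' on. Points outside the grid raise an error; there is no silent
#' nearest-cell fallback.
#'
#' @param lat,lon point coordinates (vectorized).
#' @param grid grid metadata (`lat0`, `lon0`, `n_lat`, `n_lon`,
#'   `cell_size_deg`), e.g. `climate$grid`.
#' @return data.frame with columns `i` (lat index), `j` (lon index) and
#'   `cell` (flat index `i + (j-1)*n_lat`).
#' @export
locate_cell <- function(lat, lon, grid) {
  cs <- grid$cell_size_deg
  i <- floor((lat - grid$lat0) / cs) + 1
  j <- floor((lon - grid$lon0) / cs) + 1
  bad <- i < 1 | i > grid$n_lat | j < 1 | j > grid$n_lon
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("point (%.4f, %.4f) is outside the grid [%g, %g) x [%g, %g)",
                 lat[k], lon[k],
                 grid$lat0, grid$lat0 + grid$n_lat * cs,
                 grid$lon0, grid$lon0 + grid$n_lon * cs), call. = FALSE)
  }
  data.frame(i = as.integer(i), j = as.integer(j),
             cell = as.integer(i + (j - 1) * grid$n_lat))
}

# bin index of temperature values under a bin_spec (absolute edges or one
# PSU's decile cutpoints)
bin_of <- function(x, edges) findInterval(x, edges) + 1L

#' Count days per temperature bin in one calendar month
#'
#' @param daily_series data.frame with columns `date` and `tmax` covering at
#'   least the full calendar month.
#' @param year,month the calendar month to count.
#' @param bins a [bin_spec()]; for relative bins the single PSU's cutpoints
#'   row must be supplied as `cutpoints`.
#' @param cutpoints optional numeric vector overriding the bin edges (used
#'   for per-PSU relative bins).
#' @return named integer vector of counts, one per bin; sums to the number
#'   of calendar days in the month (leap-aware).
#' @export
month_bin_counts <- function(daily_series, year, month, bins = bin_spec(),
                             cutpoints = NULL) {
  d0 <- as.Date(sprintf("%d-%02d-01", year, month))
  need <- seq(d0, by = "day", length.out = days_in_month(year, month))
  idx <- match(need, daily_series$date)
  if (anyNA(idx)) {
    stop(sprintf("daily series is missing dates: %s",
                 paste(format(need[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  edges <- if (!is.null(cutpoints)) cutpoints
           else if (bins$kind == "absolute") bins$edges
           else stop("relative bins need per-PSU cutpoints", call. = FALSE)
  b <- bin_of(daily_series$tmax[idx], edges)
  stats::setNames(tabulate(b, nbins = length(bins$labels)), bins$labels)
}

#' Decile cutpoints of a long-term daily temperature distribution
#'
#' Empirical quantiles at probabilities 0.1..0.9 using the linear
#' interpolation definition (R quantile type 7). Each of the ten relative
#' bins then captures ~10% of reference days.
#'
#' @param daily_series data.frame with `date` and `tmax`, or a bare numeric
#'   vector.
#' @param reference_years optional integer vector of calendar years to
#'   restrict the reference period to (the choice of reference period is
#'   left to the caller).
#' @return numeric vector of 9 non-decreasing cutpoints.
#' @export
longterm_deciles <- function(daily_series, reference_years = NULL) {
  x <- if (is.data.frame(daily_series)) {
    if (!is.null(reference_years)) {
      yr <- as.POSIXlt(daily_series$date)$year + 1900L
      daily_series$tmax[yr %in% reference_years]
    } else daily_series$tmax
  } else as.numeric(daily_series)
  fail_if(length(x) == 0, "empty reference series")
  q <- unname(stats::quantile(x, probs = seq(0.1, 0.9, by = 0.1), type = 7))
  if (anyDuplicated(q)) {
    warning("degenerate relative bins: some decile cutpoints coincide")
  }
  q
}

#' Apply the analysis sample restrictions
#'
#' Keeps births by mothers aged 15 to 45 at childbirth who did not migrate
#' in the year before the birth; both restrictions address exposure
#' misclassification. Counts removed per criterion are reported via
#' `message()`.
#'
#' @param births a birth-record table.
#' @return the filtered table.
#' @export
filter_sample <- function(births) {
  age_ok <- births$maternal_age_at_birth >= 15 &
    births$maternal_age_at_birth <= 45
  mig_ok <- births$migrant_last_year == 0
  message(sprintf("filter_sample: removed %d by age, %d migrants (kept %d of %d)",
                  sum(!age_ok), sum(age_ok & !mig_ok),
                  sum(age_ok & mig_ok), nrow(births)))
  out <- births[age_ok & mig_ok, , drop = FALSE]
  if (nrow(out) == 0) warning("filter_sample: no births left after restrictions")
  rownames(out) <- NULL
  out
}

#' Per-month bin-day counts for every grid cell (or PSU)
#'
#' Precomputes, for each calendar month covered by the climate object, the
#' number of days in each temperature bin. For absolute bins counts are per
#' grid cell; for relative bins per PSU (each PSU has its own decile
#' cutpoints but reads its containing cell's series).
#'
#' @param climate a `climate_fields` object.
#' @param bins a [bin_spec()].
#' @param psus required for relative bins: PSU table with coordinates whose
#'   `psu_id`s match the cutpoint rownames.
#' @return list: `months` (integer year*12+month-1), `counts` array
#'   `[month, unit, bin]`, `by` (`"cell"` or `"psu"`), `unit_ids`.
#' @export
climate_month_bins <- function(climate, bins = bin_spec(), psus = NULL) {
  g <- climate$grid
  n_cells <- g$n_lat * g$n_lon
  n_days <- length(climate$dates)
  tm <- climate$tmax
  dim(tm) <- c(n_days, n_cells)
  months <- sort(unique(climate$day_ym))
  mpos <- match(climate$day_ym, months)
  n_m <- length(months)
  nb <- length(bins$labels)

  if (bins$kind == "absolute") {
    b <- matrix(bin_of(tm, bins$edges), n_days, n_cells)
    idx <- mpos + (rep(seq_len(n_cells), each = n_days) - 1L) * n_m +
      (b - 1L) * (n_m * n_cells)
    counts <- array(tabulate(idx, nbins = n_m * n_cells * nb),
                    dim = c(n_m, n_cells, nb),
                    dimnames = list(NULL, NULL, bins$labels))
    list(months = months, counts = counts, by = "cell",
         unit_ids = seq_len(n_cells))
  } else {
    fail_if(is.null(psus), "relative bins need the PSU table")
    ids <- rownames(bins$cutpoints)
    fail_if(is.null(ids) || !all(as.character(psus$psu_id) %in% ids),
            "cutpoint rownames must cover every psu_id")
    cell <- locate_cell(psus$lat, psus$lon, g)$cell
    n_p <- nrow(psus)
    counts <- array(0L, dim = c(n_m, n_p, nb),
                    dimnames = list(NULL, NULL, bins$labels))
    for (p in seq_len(n_p)) {
      cp <- bins$cutpoints[as.character(psus$psu_id[p]), ]
      b <- bin_of(tm[, cell[p]], cp)
      counts[, p, ] <- t(vapply(split(b, mpos),
                                tabulate, integer(nb), nbins = nb))
    }
    list(months = months, counts = counts, by = "psu",
         unit_ids = psus$psu_id)
  }
}

# Sum bin-day counts over lag windows for a vector of births.
# ym: birth-month index per birth; unit: column index into bt$counts;
# windows: named list of lag vectors. Returns n x (windows*bins) matrix with
# names like "T1_gt30".
window_bin_counts <- function(ym, unit, bt, windows) {
  n <- length(ym)
  nb <- dim(bt$counts)[3]
  labs <- dimnames(bt$counts)[[3]]
  n_m <- length(bt$months)
  n_u <- dim(bt$counts)[2]
  out <- matrix(0L, n, length(windows) * nb)
  colnames(out) <- as.vector(t(outer(names(windows), labs, paste, sep = "_")))
  col <- 0L
  cnt <- bt$counts
  dim(cnt) <- c(n_m * n_u, nb)
  for (w in seq_along(windows)) {
    acc <- matrix(0L, n, nb)
    for (lag in windows[[w]]) {
      mp <- match(ym - lag, bt$months)
      if (anyNA(mp)) {
        stop(sprintf("climate does not cover lag %d for %d births",
                     lag, sum(is.na(mp))), call. = FALSE)
      }
      acc <- acc + cnt[mp + (unit - 1L) * n_m, , drop = FALSE]
    }
    out[, col + seq_len(nb)] <- acc
    col <- col + nb
  }
  out
}

#' Build the regression design from births and gridded climate
#'
#' Links every birth to its grid cell, counts days per temperature bin in
#' each gestational window, adds the lag-10/11 autocorrelation controls
#' (same non-reference bin counts, one set per lag month) and ten monthly
#' rainfall totals (birth month and nine preceding months). The reference
#' bin's counts are computed internally (the per-month counts always sum to
#' the calendar days) but excluded from the emitted design unless
#' `keep_reference = TRUE`.
#'
#' @param births (filtered) birth-record table.
#' @param climate a `climate_fields` object covering lag 11 for every birth.
#' @param psus PSU table with coordinates.
#' @param window a [gest_window_spec()].
#' @param bins a [bin_spec()].
#' @param keep_reference include the reference-bin columns in the output.
#' @return data.frame (class `exposure_matrix`) with the birth columns
#'   carried through plus treatment / control / rainfall columns; attributes
#'   `treatment_cols`, `control_cols`, `rain_cols`, `reference_cols`.
#' @export
build_exposure <- function(births, climate, psus,
                           window = gest_window_spec(),
                           bins = bin_spec(),
                           keep_reference = FALSE) {
  pi_psu <- match(births$psu_id, psus$psu_id)
  fail_if(anyNA(pi_psu), "unknown psu_id in births: %s",
          paste(utils::head(setdiff(births$psu_id, psus$psu_id)), collapse = ","))
  bt <- climate_month_bins(climate, bins,
                           psus = if (bins$kind == "relative") psus else NULL)
  unit <- if (bt$by == "cell") {
    locate_cell(psus$lat[pi_psu], psus$lon[pi_psu], climate$grid)$cell
  } else pi_psu

  ymb <- ym_index(births$birth_year, births$birth_month)
  all_windows <- c(window$windows,
                   stats::setNames(as.list(window$control_lags),
                                   paste0("lag", window$control_lags)))
  counts <- window_bin_counts(ymb, unit, bt, all_windows)

  # column naming: T1 -> t1_bin20_25, lag10 -> lag10_bin_gt30, etc.
  pretty <- function(wn, lab) {
    w <- ifelse(grepl("^T", wn), tolower(wn), wn)
    suf <- c(lt15 = "_bin_lt15", b15_20 = "_bin15_20", b20_25 = "_bin20_25",
             b25_30 = "_bin25_30", gt30 = "_bin_gt30")[lab]
    suf[is.na(suf)] <- paste0("_bin_", lab[is.na(suf)])
    paste0(w, suf)
  }
  wn <- sub("_.*$", "", colnames(counts))
  lab <- sub("^[^_]+_", "", colnames(counts))
  colnames(counts) <- pretty(wn, lab)

  ref_lab <- bins$labels[bins$reference]
  is_ref <- lab == ref_lab
  is_ctrl <- grepl("^lag", wn)
  treatment_cols <- colnames(counts)[!is_ref & !is_ctrl]
  control_cols <- colnames(counts)[!is_ref & is_ctrl]
  reference_cols <- colnames(counts)[is_ref]

  # rainfall: monthly totals for birth month and 9 preceding months
  g <- climate$grid
  cell <- locate_cell(psus$lat[pi_psu], psus$lon[pi_psu], climate$grid)$cell
  rain <- climate$rain
  dim(rain) <- c(length(climate$months), g$n_lat * g$n_lon)
  rain_cols <- paste0("rain_lag", 0:9)
  rmat <- matrix(NA_real_, nrow(births), 10, dimnames = list(NULL, rain_cols))
  for (lag in 0:9) {
    mp <- match(ymb - lag, climate$months)
    fail_if(anyNA(mp), "rainfall does not cover lag %d for some births", lag)
    rmat[, lag + 1] <- rain[mp + (cell - 1L) * length(climate$months)]
  }

  keep <- c(treatment_cols, control_cols, if (keep_reference) reference_cols)
  out <- cbind(births, as.data.frame(counts[, keep, drop = FALSE]),
               as.data.frame(rmat))
  rownames(out) <- NULL
  structure(out,
            treatment_cols = treatment_cols,
            control_cols = control_cols,
            rain_cols = rain_cols,
            reference_cols = if (keep_reference) reference_cols else character(0),
            window_mode = window$mode, bin_kind = bins$kind,
            class = c("exposure_matrix", "data.frame"))
}
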