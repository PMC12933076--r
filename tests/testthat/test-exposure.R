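grid0 <- list(lat0 = 0, lon0 = 10, n_lat = 4, n_lon = 6, cell_size_deg = 0.5)

test_that("locate_cell honours half-open cell edges", {
  # cell centre
  expect_equal(locate_cell(0.25, 10.25, grid0)$cell, 1L)
  # point on a shared edge belongs to the upper cell (lower edge inclusive)
  hit <- locate_cell(0.5, 10.0, grid0)
  expect_equal(c(hit$i, hit$j), c(2L, 1L))
  # outside: explicit error, no nearest-cell fallback
  expect_error(locate_cell(2.0, 10.2, grid0), "outside the grid")
  expect_error(locate_cell(-0.01, 10.2, grid0), "outside the grid")
})

test_that("locate_cell agrees with a brute-force scan over all cells", {
  set.seed(1)
  lat <- runif(100, 0, 2 - 1e-9); lon <- runif(100, 10, 13 - 1e-9)
  got <- locate_cell(lat, lon, grid0)
  for (k in seq_len(100)) {
    found <- NULL
    for (i in seq_len(grid0$n_lat)) for (j in seq_len(grid0$n_lon)) {
      la <- grid0$lat0 + (i - 1) * 0.5; lo <- grid0$lon0 + (j - 1) * 0.5
      if (lat[k] >= la && lat[k] < la + 0.5 && lon[k] >= lo && lon[k] < lo + 0.5)
        found <- c(i, j)
    }
    expect_equal(c(got$i[k], got$j[k]), found)
  }
})

test_that("month_bin_counts enumerates days correctly, leap-aware", {
  june <- data.frame(date = seq(as.Date("2015-06-01"), by = "day", length.out = 30),
                     tmax = 22)
  expect_equal(month_bin_counts(june, 2015, 6, bin_spec()),
               c(lt15 = 0, b15_20 = 0, b20_25 = 30, b25_30 = 0, gt30 = 0))

  # alternating 14.9 / 30.0 over a 31-day month, day 1 = 14.9; 30.0 must land
  # in the top bin (edge convention)
  jul <- data.frame(date = seq(as.Date("2015-07-01"), by = "day", length.out = 31),
                    tmax = rep_len(c(14.9, 30.0), 31))
  cnt <- month_bin_counts(jul, 2015, 7, bin_spec())
  expect_equal(unname(cnt[c("lt15", "gt30")]), c(16, 15))

  feb <- data.frame(date = seq(as.Date("2020-02-01"), by = "day", length.out = 29),
                    tmax = rnorm(29, 20, 8))
  expect_equal(sum(month_bin_counts(feb, 2020, 2, bin_spec())), 29)

  expect_error(month_bin_counts(june[-3, ], 2015, 6, bin_spec()),
               "missing dates: 2015-06-03")
})

test_that("bin edges are half-open: 15.0 and 30.0 land per the convention", {
  s <- data.frame(date = seq(as.Date("2015-06-01"), by = "day", length.out = 30),
                  tmax = c(15.0, 30.0, rep(17, 28)))
  cnt <- month_bin_counts(s, 2015, 6, bin_spec())
  expect_equal(unname(cnt), c(0, 29, 0, 0, 1))
})

test_that("longterm_deciles uses linear-interpolation quantiles", {
  got <- longterm_deciles(1:100)
  expect_equal(got, seq(10.9, 90.1, by = 9.9), tolerance = 1e-12)
  expect_warning(cp <- longterm_deciles(rep(20, 400)), "degenerate")
  expect_true(all(cp == 20))
  # non-decreasing for arbitrary input
  set.seed(2)
  for (r in 1:20) expect_false(is.unsorted(longterm_deciles(rnorm(200, 20, 6))))
  expect_error(longterm_deciles(numeric(0)), "empty")
  # reference-year restriction actually subsets
  df <- data.frame(date = seq(as.Date("2000-01-01"), as.Date("2003-12-31"), "day"))
  df$tmax <- ifelse(format(df$date, "%Y") %in% c("2000", "2001"), 10, 30)
  expect_true(all(suppressWarnings(longterm_deciles(df, 2000:2001)) == 10))
})

test_that("filter_sample applies age and migration restrictions inclusively", {
  b <- data.frame(maternal_age_at_birth = c(14, 15, 45, 46),
                  migrant_last_year = 0)
  expect_message(kept <- filter_sample(b), "removed 2 by age")
  expect_equal(kept$maternal_age_at_birth, c(15, 45))

  allmig <- data.frame(maternal_age_at_birth = rep(30, 4), migrant_last_year = 1)
  suppressMessages(expect_warning(filter_sample(allmig), "no births left"))

  toy <- data.frame(maternal_age_at_birth = c(14, rep(30, 9)),
                    migrant_last_year = c(0, 1, 1, 1, rep(0, 6)))
  suppressMessages(expect_equal(nrow(filter_sample(toy)), 6))
})

test_that("build_exposure matches hand enumeration on a one-birth fixture", {
  cfg <- sim_config(seed = 8, n_regions = 1, psus_per_region = 1,
                    births_per_psu = 5, year_range = c(2010, 2012),
                    grid = list(n_lat = 1, n_lon = 1))
  cl <- simulate_climate(cfg)
  ps <- data.frame(psu_id = 1, region_id = 1,
                   lat = cfg$grid$lat0 + 0.1, lon = cfg$grid$lon0 + 0.1,
                   urban = 0, north = 0)
  b <- data.frame(birth_id = 1, mother_id = 1, psu_id = 1, region_id = 1,
                  male = 1, birth_month = 3, birth_year = 2011,
                  maternal_age_at_birth = 25, education = "none_or_primary",
                  parity = 1, urban = 0, sonless_before = 1, north = 0,
                  migrant_last_year = 0)
  x <- build_exposure(b, cl, ps, keep_reference = TRUE)

  # independent plain loop over the daily series
  s <- cell_series(cl, 1, 1)
  count_window <- function(lags) {
    tot <- c(0, 0, 0, 0, 0)
    for (l in lags) {
      ym <- 2011 * 12 + 3 - 1 - l
      y <- ym %/% 12; m <- ym %% 12 + 1
      days <- s$tmax[format(s$date, "%Y-%m") == sprintf("%d-%02d", y, m)]
      for (v in days) {
        k <- if (v < 15) 1 else if (v < 20) 2 else if (v < 25) 3
             else if (v < 30) 4 else 5
        tot[k] <- tot[k] + 1
      }
    }
    tot
  }
  for (spec in list(list("t3", 0:3), list("t2", 4:6), list("t1", 7:9),
                    list("lag10", 10), list("lag11", 11))) {
    hand <- count_window(spec[[2]])
    cols <- paste0(spec[[1]], c("_bin_lt15", "_bin15_20", "_bin20_25",
                                "_bin25_30", "_bin_gt30"))
    expect_equal(unname(unlist(x[1, cols])), hand,
                 info = spec[[1]])
    # day-count conservation for the window
    n_days <- sum(vapply(spec[[2]], function(l) {
      ym <- 2011 * 12 + 2 - l
      heatsrb:::days_in_month(ym %/% 12, ym %% 12 + 1)
    }, numeric(1)))
    expect_equal(sum(hand), n_days)
  }
  # rainfall columns come from the right months
  rain <- cl$rain[, 1, 1]
  m0 <- match(2011 * 12 + 3 - 1, cl$months)
  expect_equal(x$rain_lag0, rain[m0])
  expect_equal(x$rain_lag9, rain[m0 - 9])
})

test_that("constant 22 C climate loads only the 20-25 bin with window totals", {
  cfg <- constant_climate_cfg(seed = 12, temp = 22, births_per_psu = 20)
  cl <- simulate_climate(cfg); ps <- simulate_psus(cfg)
  b <- simulate_births(cfg, cl, ps)
  x <- build_exposure(b, cl, ps)
  tcols <- attr(x, "treatment_cols")
  zero_cols <- setdiff(tcols, c("t1_bin20_25", "t2_bin20_25", "t3_bin20_25"))
  expect_true(all(as.matrix(x[, zero_cols]) == 0))
  # t2 window = lags 4-6: the 20-25 count equals those months' calendar days
  ym <- b$birth_year * 12 + b$birth_month - 1
  t2_days <- rowSums(vapply(4:6, function(l) {
    m <- ym - l
    heatsrb:::days_in_month(m %/% 12, m %% 12 + 1)
  }, numeric(nrow(b))))
  expect_equal(x$t2_bin20_25, t2_days)
})

test_that("trimester counts equal the sum of their constituent months", {
  w <- small_world()
  x <- build_exposure(w$kept, w$climate, w$psus,
                      window = gest_window_spec("monthly"),
                      keep_reference = TRUE)
  xt <- build_exposure(w$kept, w$climate, w$psus, keep_reference = TRUE)
  for (lab in c("_bin_lt15", "_bin15_20", "_bin20_25", "_bin25_30", "_bin_gt30")) {
    expect_equal(xt[[paste0("t3", lab)]],
                 rowSums(sapply(0:3, function(l) x[[paste0("m", l, lab)]])))
    expect_equal(xt[[paste0("t1", lab)]],
                 rowSums(sapply(7:9, function(l) x[[paste0("m", l, lab)]])))
  }
  # monthly mode emits 40 treatment columns
  expect_length(attr(x, "treatment_cols"), 40)
  expect_length(attr(xt, "treatment_cols"), 12)
  expect_length(attr(xt, "control_cols"), 8)
})

test_that("build_exposure is row-order invariant and idempotent", {
  w <- small_world()
  b <- w$kept[1:200, ]
  x1 <- build_exposure(b, w$climate, w$psus)
  x2 <- build_exposure(b[sample(nrow(b)), ], w$climate, w$psus)
  x2 <- x2[order(x2$birth_id), ]; rownames(x2) <- NULL
  expect_equal(as.data.frame(x1), as.data.frame(x2))
  x3 <- build_exposure(b, w$climate, w$psus)
  expect_equal(as.data.frame(x1), as.data.frame(x3))
})

test_that("relative bins reduce to absolute bins at matching cutpoints", {
  w <- small_world()
  b <- w$kept[1:150, ]
  cp <- matrix(rep(c(15, 15, 20, 20, 25, 25, 30, 30, 30), nrow(w$psus)),
               ncol = 9, byrow = TRUE,
               dimnames = list(w$psus$psu_id, NULL))
  xr <- build_exposure(b, w$climate, w$psus,
                       bins = bin_spec("relative", cutpoints = cp),
                       keep_reference = TRUE)
  xa <- build_exposure(b, w$climate, w$psus, keep_reference = TRUE)
  # with tied cutpoints at the absolute edges: d1=lt15, d3=15-20, d5=20-25,
  # d7=25-30, d10=gt30; the even deciles are empty
  expect_equal(xr$t1_bin_d1, xa$t1_bin_lt15)
  expect_equal(xr$t1_bin_d3, xa$t1_bin15_20)
  expect_equal(xr$t2_bin_d5, xa$t2_bin20_25)
  expect_equal(xr$t3_bin_d7, xa$t3_bin25_30)
  expect_equal(xr$t1_bin_d10, xa$t1_bin_gt30)
  expect_true(all(xr$t1_bin_d2 == 0) && all(xr$t1_bin_d4 == 0))
})

test_that("unknown PSUs and missing climate coverage raise errors", {
  w <- small_world()
  b <- w$kept[1:5, ]
  b$psu_id[1] <- 9999
  expect_error(build_exposure(b, w$climate, w$psus), "unknown psu_id")
  b2 <- w$kept[1:5, ]
  b2$birth_year <- 1990
  expect_error(build_exposure(b2, w$climate, w$psus), "does not cover")
})
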