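#' Simulate primary sampling units (survey clusters)
#'
#' PSUs are scattered uniformly within their region's block of grid cells;
#' the urban flag is Bernoulli with the configured probability.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `psu_id`, `region_id`, `lat`, `lon`,
#'   `urban`, `north`.
#' @export
simulate_psus <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fail_if(cfg$psus_per_region <= 0, "psus_per_region must be positive")
  g <- cfg$grid
  cols_per_region <- g$n_lon %/% cfg$n_regions
  n <- cfg$n_regions * cfg$psus_per_region
  region_id <- rep(seq_len(cfg$n_regions), each = cfg$psus_per_region)
  n_north <- floor(cfg$composition$north_fraction * cfg$n_regions)
  north_region <- seq_len(cfg$n_regions) <= n_north

  with_local_seed(derive_seed(cfg$seed, 3L), {
    lat <- g$lat0 + stats::runif(n) * g$n_lat * g$cell_size_deg
    lon0_r <- g$lon0 + (region_id - 1) * cols_per_region * g$cell_size_deg
    lon <- lon0_r + stats::runif(n) * cols_per_region * g$cell_size_deg
    urban <- stats::rbinom(n, 1, cfg$composition$urban_prob)
    data.frame(psu_id = seq_len(n), region_id = region_id,
               lat = lat, lon = lon, urban = urban,
               north = as.integer(north_region[region_id]))
  })
}

#' Simulate DHS-like birth records with a known temperature-sex response
#'
#' One row per live birth (before any sex-selective abortion; see
#' [apply_son_preference()]). Mothers get 1-6 births; birth months follow
#' the configured seasonality; the probability of a male birth is
#' `p0 + sum_kj beta_true[k, j] * count_kj + alpha_rm + delta_ry`, where the
#' bin-day counts over the approximate trimesters are computed with the same
#' counting engine used by [build_exposure()] (single source of truth) and
#' `alpha`, `delta` are Gaussian region-by-calendar-month and region-by-year
#' effects with the configured SDs. Raw maternal ages span 10-55 so the
#' 15-45 sample restriction of [filter_sample()] is testable.
#'
#' @param cfg a [sim_config()].
#' @param climate a [simulate_climate()] result.
#' @param psus a [simulate_psus()] result.
#' @return data.frame with columns `birth_id`, `mother_id`, `psu_id`,
#'   `region_id`, `male`, `birth_month`, `birth_year`,
#'   `maternal_age_at_birth`, `education`, `parity`, `urban`,
#'   `sonless_before`, `north`, `migrant_last_year`.
#' @export
simulate_births <- function(cfg, climate, psus) {
  stopifnot(inherits(cfg, "sim_config"), inherits(climate, "climate_fields"))
  comp <- cfg$composition
  years <- seq.int(cfg$year_range[1], cfg$year_range[2])

  with_local_seed(derive_seed(cfg$seed, 4L), {
    # --- mothers: sibship sizes per PSU until the per-PSU birth quota is met
    n_psu <- nrow(psus)
    target <- cfg$births_per_psu
    # expected mothers per PSU, with head-room; trim afterwards
    mean_k <- sum(seq_along(comp$parity_probs) * comp$parity_probs)
    per_psu <- ceiling(target / mean_k * 1.6) + 3L
    sizes <- sample(seq_along(comp$parity_probs), n_psu * per_psu,
                    replace = TRUE, prob = comp$parity_probs)
    m_psu <- rep(psus$psu_id, each = per_psu)
    # keep mothers until each PSU reaches its quota; truncate the last sibship
    cum <- stats::ave(sizes, m_psu, FUN = cumsum)
    keep <- cum - sizes < target
    sizes <- pmin(sizes[keep], target - (cum[keep] - sizes[keep]))
    m_psu <- m_psu[keep]
    n_mothers <- length(sizes)
    mother_id <- seq_len(n_mothers)

    edu <- stats::rbinom(n_mothers, 1, comp$secondary_plus_prob)
    age_first <- pmin(40, pmax(12, round(stats::rnorm(
      n_mothers, comp$age_first_mean, comp$age_first_sd))))

    # --- births
    n_b <- sum(sizes)
    b_mother <- rep(mother_id, sizes)
    b_psu <- rep(m_psu, sizes)
    pi_psu <- match(b_psu, psus$psu_id)
    b_region <- psus$region_id[pi_psu]
    b_year <- sample(years, n_b, replace = TRUE)
    b_month <- sample(1:12, n_b, replace = TRUE, prob = comp$month_weights)
    # order births within mother chronologically; parity = order
    ord <- order(b_mother, b_year * 12L + b_month, stats::runif(n_b))
    b_mother <- b_mother[ord]; b_psu <- b_psu[ord]; b_region <- b_region[ord]
    b_year <- b_year[ord]; b_month <- b_month[ord]; pi_psu <- pi_psu[ord]
    parity <- stats::ave(rep(1L, n_b), b_mother, FUN = seq_along)

    mi <- match(b_mother, mother_id)
    age <- pmin(55L, pmax(10L, age_first[mi] + (b_year - stats::ave(
      b_year, b_mother, FUN = min))))

    # --- true exposure counts via the exposure-module counting engine
    bt <- climate_month_bins(climate, bin_spec())
    cell <- locate_cell(psus$lat[pi_psu], psus$lon[pi_psu], climate$grid)
    ymb <- ym_index(b_year, b_month)
    if (cfg$gestation_jitter_months > 0) {
      ymb_exp <- ymb + sample(c(-1L, 0L, 1L), n_b, replace = TRUE)
    } else ymb_exp <- ymb
    win <- gest_window_spec("trimester")
    counts <- window_bin_counts(ymb_exp, cell$cell, bt,
                                win$windows[c("T1", "T2", "T3")])
    # counts: n_b x (3 windows x 5 bins), column order T1 bins, T2 bins, T3 bins
    beta_vec <- as.vector(t(cfg$beta_true))   # T1 bins..., T2 bins..., T3 bins...
    lin <- as.vector(counts %*% beta_vec)
    if (!is.null(cfg$beta_modifier)) {
      bm <- cfg$beta_modifier
      mod_val <- switch(bm$column,
                        urban = psus$urban[pi_psu],
                        north = psus$north[pi_psu],
                        stop("beta_modifier column must be 'urban' or 'north'"))
      lin <- lin * as.numeric(mod_val == bm$value)
    }

    alpha <- matrix(stats::rnorm(cfg$n_regions * 12,
                                 sd = cfg$fe_true$sd_region_month),
                    cfg$n_regions, 12)
    delta <- matrix(stats::rnorm(cfg$n_regions * length(years),
                                 sd = cfg$fe_true$sd_region_year),
                    cfg$n_regions, length(years))
    p <- cfg$p0 + lin + alpha[cbind(b_region, b_month)] +
      delta[cbind(b_region, match(b_year, years))]
    if (any(p < 0 | p > 1)) {
      bad <- which(p < 0 | p > 1)[1]
      stop(sprintf(paste0("simulate_births: birth probability %.4f outside [0,1] ",
                          "(p0 = %.4f, max |beta| = %g, fe sds = %g/%g)"),
                   p[bad], cfg$p0, max(abs(cfg$beta_true)),
                   cfg$fe_true$sd_region_month, cfg$fe_true$sd_region_year),
           call. = FALSE)
    }
    male <- stats::rbinom(n_b, 1, p)

    prior_sons <- stats::ave(male, b_mother, FUN = function(m) cumsum(m) - m)
    migrant <- stats::rbinom(n_b, 1, comp$migration_prob)

    data.frame(
      birth_id = seq_len(n_b),
      mother_id = b_mother, psu_id = b_psu, region_id = b_region,
      male = male, birth_month = b_month, birth_year = b_year,
      maternal_age_at_birth = age,
      education = ifelse(edu[mi] == 1, "secondary_plus", "none_or_primary"),
      parity = parity, urban = psus$urban[pi_psu],
      sonless_before = as.integer(prior_sons == 0),
      north = psus$north[pi_psu],
      migrant_last_year = migrant,
      stringsAsFactors = FALSE
    )
  })
}

#' Apply the sex-selective-abortion (son preference) channel
#'
#' For eligible pregnancies - live parity at least 4, no previous son, and a
#' northern region - that drew a female sex, the birth is removed with
#' probability `q = max(0, q0 - gamma * H)`, where `H` is the number of
#' second-trimester days (birth-month lags 4-6) with daily maximum
#' temperature above 20 deg C. Removal re-indexes subsequent parities for
#' that mother, so the returned table contains live births only, with
#' `parity` and `sonless_before` recomputed over the post-selection history.
#'
#' Selection operates on the female draw after sex assignment, matching the
#' demographic mechanism of sex-selective abortion; hotter second trimesters
#' make the abortion less likely, so heat raises the share of female live
#' births in the eligible stratum.
#'
#' @param births output of [simulate_births()].
#' @param climate the matching [simulate_climate()] result.
#' @param cfg the [sim_config()]; `cfg$abortion_model$enabled` must be TRUE.
#' @param psus the matching [simulate_psus()] table.
#' @return the post-selection birth table; attribute `"removed"` holds the
#'   `birth_id`s of aborted pregnancies.
#' @export
apply_son_preference <- function(births, climate, cfg, psus) {
  ab <- cfg$abortion_model
  fail_if(!isTRUE(ab$enabled), "abortion_model is not enabled in this config")
  fail_if(ab$q0 < 0 || ab$q0 > 1, "q0 must be in [0, 1]")
  fail_if(ab$gamma < 0, "gamma must be >= 0")
  if (ab$q0 == 0) {
    attr(births, "removed") <- integer(0)
    return(births)
  }

  # hot second-trimester days per birth (days > 20 C in lags 4-6)
  bt <- climate_month_bins(climate, bin_spec())
  pi_psu <- match(births$psu_id, psus$psu_id)
  cell <- locate_cell(psus$lat[pi_psu], psus$lon[pi_psu], climate$grid)
  cnt <- window_bin_counts(ym_index(births$birth_year, births$birth_month),
                           cell$cell, bt, list(T2 = 4:6))
  H <- rowSums(cnt[, c("T2_b20_25", "T2_b25_30", "T2_gt30"), drop = FALSE])

  # only mothers who could ever have an eligible birth need the sequential
  # pass: northern, sibship >= 4, and first three births all female
  # (births 1-3 are never removed, so an early son blocks eligibility).
  ord <- order(births$mother_id, births$parity)
  b <- births[ord, ]
  H <- H[ord]
  sib <- stats::ave(rep(1L, nrow(b)), b$mother_id, FUN = length)
  first3_male <- stats::ave(b$male * (b$parity <= 3), b$mother_id, FUN = max)
  candidate <- b$north == 1 & sib >= 4 & first3_male == 0

  removed <- logical(nrow(b))
  new_parity <- b$parity
  new_sonless <- b$sonless_before

  cand_rows <- which(candidate)
  if (length(cand_rows)) {
    with_local_seed(derive_seed(cfg$seed, 5L), {
      for (rows in split(cand_rows, b$mother_id[cand_rows])) {
        live <- 0L; has_son <- FALSE
        for (r in rows) {
          eligible <- (live + 1L >= 4L) && !has_son
          if (eligible && b$male[r] == 0L) {
            q <- max(0, ab$q0 - ab$gamma * H[r])
            if (stats::runif(1) < q) { removed[r] <- TRUE; next }
          }
          live <- live + 1L
          new_parity[r] <- live
          new_sonless[r] <- as.integer(!has_son)
          has_son <- has_son || b$male[r] == 1L
        }
      }
    })
  }

  out <- b[!removed, ]
  out$parity <- new_parity[!removed]
  out$sonless_before <- new_sonless[!removed]
  out <- out[order(out$birth_id), ]
  rownames(out) <- NULL
  attr(out, "removed") <- b$birth_id[removed]
  out
}
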