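#' Per-SD effect of an exposure variable
#'
#' Multiplies a coefficient in percentage points per day by the sample SD of
#' the exposure column (days), giving the effect of a 1-SD increase in the
#' predictor. For display, round with [round_half_away()] to 2 decimals;
#' the unrounded value is what this function returns.
#'
#' @param coef_pp coefficient, percentage points per additional day.
#' @param sd_days sample SD of the exposure count, days (>= 0).
#' @return percentage points per 1-SD change (unrounded).
#' @export
#' @examples
#' round_half_away(per_sd(0.022, 18.8), 2)  # 0.41
per_sd <- function(coef_pp, sd_days) {
  fail_if(any(sd_days < 0), "sd_days must be >= 0")
  coef_pp * sd_days
}

#' Sex ratio at birth from the proportion male
#'
#' @param p proportion of births that are male, in (0, 1).
#' @return males per 100 females, `100 * p / (1 - p)`.
#' @export
srb_from_prop <- function(p) {
  fail_if(any(p <= 0 | p >= 1), "proportion male must be in (0, 1)")
  100 * p / (1 - p)
}

#' Proportion male from the sex ratio at birth
#'
#' Inverse of [srb_from_prop()].
#' @param srb males per 100 females (> 0).
#' @return proportion male.
#' @export
prop_from_srb <- function(srb) {
  fail_if(any(srb <= 0), "SRB must be positive")
  srb / (100 + srb)
}

#' Shift a baseline SRB by a percentage-point change in proportion male
#'
#' Converts the baseline SRB to a proportion male, subtracts `delta_pp / 100`
#' (so a positive `delta_pp` is a reduction in male births), and converts
#' back. This is the translation used to express per-SD effects as changes
#' in male births per 100 female births.
#'
#' @param baseline_srb males per 100 females.
#' @param delta_pp reduction in the probability of a male birth, percentage
#'   points.
#' @return data.frame with `baseline_srb`, `new_srb`, `reduction`
#'   (`baseline - new`).
#' @export
#' @examples
#' srb_shift(109.95, 0.26)  # new_srb ~ 108.81
srb_shift <- function(baseline_srb, delta_pp) {
  fail_if(any(baseline_srb <= 0), "baseline SRB must be positive")
  p0 <- prop_from_srb(baseline_srb)
  p1 <- p0 - delta_pp / 100
  fail_if(any(p1 <= 0 | p1 >= 1),
          "shift pushes the proportion male outside (0, 1)")
  new_srb <- srb_from_prop(p1)
  data.frame(baseline_srb = baseline_srb, new_srb = new_srb,
             reduction = baseline_srb - new_srb)
}

#' Effect table: coefficients translated into per-SD and SRB units
#'
#' For every treatment column of a fitted model: the coefficient in
#' percentage points per day, the sample SD of the exposure (days), the
#' per-SD effect (pp), and the SRB after a 1-SD increase relative to the
#' baseline. Percentage-point scaling (x100) happens only here, at the
#' reporting layer; the fit itself is in probability units.
#'
#' @param fit a [felpm()] / [srb_fit()] object.
#' @param exposure the exposure matrix the model was fitted on.
#' @param baseline_srb baseline males per 100 females, or `"auto"` to derive
#'   it from the sample proportion male.
#' @return data.frame, one row per treatment column, with both unrounded and
#'   display-rounded (half away from zero, 2 dp) per-SD effects.
#' @export
effect_table <- function(fit, exposure, baseline_srb = "auto") {
  cols <- fit$treatment_cols
  if (is.null(cols)) cols <- names(stats::coef(fit))
  cols <- intersect(cols, names(stats::coef(fit))[!is.na(stats::coef(fit))])
  if (identical(baseline_srb, "auto")) {
    baseline_srb <- srb_from_prop(mean(exposure$male))
  }
  keep <- fit$keep
  est <- stats::coef(fit)[cols]
  coef_pp <- 100 * est
  sd_days <- vapply(cols, function(cn) stats::sd(exposure[[cn]][keep]),
                    numeric(1))
  eff <- per_sd(coef_pp, sd_days)
  # negative coefficient -> positive reduction; a per-SD effect too large for
  # the probability scale (possible for very noisy columns) reports NA
  p1 <- prop_from_srb(baseline_srb) + eff / 100
  ok <- p1 > 0 & p1 < 1
  sh <- data.frame(new_srb = ifelse(ok, 100 * p1 / (1 - p1), NA_real_))
  sh$reduction <- baseline_srb - sh$new_srb
  if (any(!ok)) {
    warning(sprintf("per-SD effect out of probability range for: %s",
                    paste(cols[!ok], collapse = ", ")))
  }
  data.frame(term = cols,
             coef_pp_per_day = coef_pp,
             se_pp = 100 * fit$se[cols],
             p_value = fit$pval[cols],
             sd_days = sd_days,
             per_sd_pp = eff,
             per_sd_pp_2dp = round_half_away(eff, 2),
             baseline_srb = baseline_srb,
             srb_after_1sd = sh$new_srb,
             srb_reduction = sh$reduction,
             row.names = NULL)
}

#' Back-of-the-envelope warming-scenario projection
#'
#' Applies a climate scenario - a uniform additive shift of every daily
#' maximum temperature, or explicit per-column day-count deltas - recounts
#' bin days with the exposure machinery, and translates the implied change
#' in bin-day counts through the fitted coefficients:
#' `delta_p = mean_i sum_c beta_c * delta_count_ic`. The result is reported
#' with a per-column decomposition so the saturation mechanism (days already
#' above the top bin cannot move between bins under warming) is inspectable.
#'
#' @param fit a fitted [srb_fit()] model.
#' @param climate,psus,births the inputs the exposure was built from
#'   (`births` already filtered).
#' @param shift either a single number (uniform deg C added to every daily
#'   maximum) or a named numeric vector of day-count deltas per design
#'   column.
#' @param window,bins the exposure specification used in the fit.
#' @param baseline_srb baseline males per 100 females or `"auto"`.
#' @return list: `delta_p` (change in proportion male), `baseline_srb`,
#'   `new_srb`, `delta_srb`, and `by_column` decomposition data.frame.
#' @export
project_scenario <- function(fit, climate, psus, births, shift,
                             window = gest_window_spec(), bins = bin_spec(),
                             baseline_srb = "auto") {
  est <- stats::coef(fit)
  est <- est[!is.na(est)]
  bin_cols <- grep("_bin", names(est), value = TRUE)

  x0 <- build_exposure(births, climate, psus, window, bins)
  if (is.numeric(shift) && is.null(names(shift)) && length(shift) == 1) {
    shifted <- climate
    shifted$tmax <- climate$tmax + shift
    x1 <- build_exposure(births, shifted, psus, window, bins)
    dmat <- as.matrix(x1[, bin_cols, drop = FALSE]) -
      as.matrix(x0[, bin_cols, drop = FALSE])
  } else {
    fail_if(is.null(names(shift)), "per-bin shifts must be a named vector")
    unknown <- setdiff(names(shift), bin_cols)
    fail_if(length(unknown) > 0, "unknown design columns in shift: %s",
            paste(unknown, collapse = ", "))
    dmat <- matrix(0, nrow(x0), length(bin_cols),
                   dimnames = list(NULL, bin_cols))
    dmat[, names(shift)] <- rep(shift, each = nrow(x0))
    newc <- as.matrix(x0[, names(shift), drop = FALSE]) + dmat[, names(shift)]
    fail_if(any(newc < 0), "scenario pushes a bin-day count negative")
  }

  dp_i <- as.vector(dmat %*% est[bin_cols])
  delta_p <- mean(dp_i)
  if (identical(baseline_srb, "auto")) {
    baseline_srb <- srb_from_prop(mean(births$male))
  }
  sh <- srb_shift(baseline_srb, -100 * delta_p)
  by_col <- data.frame(term = bin_cols,
                       mean_delta_days = colMeans(dmat),
                       coef = est[bin_cols],
                       contribution_p = colMeans(dmat) * est[bin_cols],
                       row.names = NULL)
  list(delta_p = delta_p, baseline_srb = baseline_srb,
       new_srb = sh$new_srb, delta_srb = sh$new_srb - baseline_srb,
       by_column = by_col)
}
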