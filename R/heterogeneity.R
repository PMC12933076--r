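#' Subgroup labels for the heterogeneity analyses
#'
#' Builds the partition used for subgroup-specific regressions:
#' urban/rural, maternal education (none or primary vs secondary plus),
#' maternal age at birth (15-24, 25-29, 30+), birth order (1, 2, 3, 4+),
#' the son-preference design (sonless vs has-son crossed with north/south,
#' restricted to parities 4 and higher), or any user-supplied categorical
#' column.
#'
#' @param births birth-record table (after [filter_sample()]).
#' @param dimension one of `"urban_rural"`, `"education"`, `"age"`,
#'   `"parity"`, `"son_preference"`, or the name of a column in `births`.
#' @return a factor with one label per birth; `NA` for births outside the
#'   dimension's domain (only the son-preference design excludes rows).
#' @export
subgroup_labels <- function(births, dimension) {
  switch(dimension,
    urban_rural = factor(ifelse(births$urban == 1, "urban", "rural"),
                         levels = c("urban", "rural")),
    education = factor(births$education,
                       levels = c("none_or_primary", "secondary_plus")),
    age = cut(births$maternal_age_at_birth, c(-Inf, 24.5, 29.5, Inf),
              labels = c("15-24", "25-29", "30+")),
    parity = factor(ifelse(births$parity >= 4, "4+", as.character(births$parity)),
                    levels = c("1", "2", "3", "4+")),
    son_preference = {
      lab <- rep(NA_character_, nrow(births))
      hi <- births$parity >= 4
      lab[hi] <- paste0(ifelse(births$sonless_before[hi] == 1,
                               "sonless", "has_son"),
                        "_", ifelse(births$north[hi] == 1, "north", "south"))
      factor(lab, levels = c("sonless_north", "sonless_south",
                             "has_son_north", "has_son_south"))
    },
    {
      fail_if(is.null(births[[dimension]]),
              "unknown subgroup dimension '%s'", dimension)
      factor(births[[dimension]])
    }
  )
}

#' Split births into labeled subgroup samples
#'
#' @inheritParams subgroup_labels
#' @return named list of birth tables, one per non-empty category; empty
#'   categories are skipped with a warning.
#' @export
split_births <- function(births, dimension) {
  lab <- subgroup_labels(births, dimension)
  out <- split(births[!is.na(lab), , drop = FALSE], lab[!is.na(lab)])
  empty <- names(out)[vapply(out, nrow, integer(1)) == 0]
  if (length(empty)) {
    warning(sprintf("empty subgroup(s) skipped: %s",
                    paste(empty, collapse = ", ")))
    out <- out[setdiff(names(out), empty)]
  }
  out
}

#' Run the full pipeline separately within each subgroup
#'
#' For each category of the dimension: rebuild the exposure matrix, rebuild
#' the fixed-effect groups within the subgroup (the only estimable choice),
#' fit the linear probability model, and translate effects. Subgroups
#' smaller than `min_n` are skipped with a message.
#'
#' @inheritParams subgroup_labels
#' @param climate,psus inputs for [build_exposure()].
#' @param window,bins exposure specification.
#' @param min_n minimum subgroup size for estimation.
#' @param ... passed to [srb_fit()].
#' @return list with elements `fits` (named list of `felpm` objects),
#'   `effects` (named list of [effect_table()]s), `table` (combined long
#'   coefficient table), `sizes`. Note: confidence-interval overlap between
#'   subgroups is not a formal test; no cross-subgroup statistic is
#'   computed.
#' @export
run_subgroups <- function(births, climate, psus, dimension,
                          window = gest_window_spec(), bins = bin_spec(),
                          min_n = 200, ...) {
  parts <- split_births(births, dimension)
  fits <- list(); effs <- list(); rows <- list()
  for (nm in names(parts)) {
    b <- parts[[nm]]
    if (nrow(b) < min_n) {
      message(sprintf("subgroup '%s' skipped (n = %d < %d)", nm, nrow(b), min_n))
      next
    }
    xp <- build_exposure(b, climate, psus, window, bins)
    fit <- srb_fit(xp, ...)
    fits[[nm]] <- fit
    effs[[nm]] <- effect_table(fit, xp)
    et <- effs[[nm]]
    rows[[nm]] <- cbind(subgroup = nm, n = nrow(b), et)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(fits = fits, effects = effs, table = tab,
       sizes = vapply(parts, nrow, integer(1)))
}

#' Side-by-side placebo contrast of two coefficient tables
#'
#' Aligns the effect tables of two samples (for example a son-preference
#' population versus a placebo population without the sex-selection
#' channel) term by term. Descriptive only: no pooled interaction test is
#' computed, and overlapping confidence intervals are not a formal test of
#' equality.
#'
#' @param results_a,results_b [effect_table()] outputs (or any data.frames
#'   with columns `term`, `coef_pp_per_day`, `se_pp`).
#' @param labels character(2) names for the two samples.
#' @return data.frame with one row per term: both estimates, SEs and the
#'   raw difference.
#' @export
placebo_contrast <- function(results_a, results_b,
                             labels = c("sample_a", "sample_b")) {
  fail_if(!setequal(results_a$term, results_b$term),
          "coefficient tables do not have matching terms")
  b <- results_b[match(results_a$term, results_b$term), ]
  out <- data.frame(term = results_a$term,
                    est_a = results_a$coef_pp_per_day, se_a = results_a$se_pp,
                    est_b = b$coef_pp_per_day, se_b = b$se_pp)
  out$difference <- out$est_a - out$est_b
  names(out)[2:5] <- c(paste0("est_", labels[1]), paste0("se_", labels[1]),
                       paste0("est_", labels[2]), paste0("se_", labels[2]))
  attr(out, "note") <- "descriptive contrast; CI overlap is not a test"
  out
}

#' Linear-combination test of a set of coefficients
#'
#' t statistic for `c'beta` under the cluster-robust variance, with the
#' fit's `G - 1` degrees of freedom. Used to summarize, e.g., the average
#' of the three above-20-C second-trimester bins in one number.
#'
#' @param fit a `felpm` object.
#' @param terms coefficient names; the combination averages them.
#' @param weights optional non-negative weights (normalized to sum to 1);
#'   e.g. each bin's share of hot days, giving the effect of one additional
#'   average hot day.
#' @return list: `estimate`, `se`, `t`, `p`, `df`.
#' @export
lincom <- function(fit, terms, weights = NULL) {
  est <- stats::coef(fit)
  fail_if(!all(terms %in% names(est)) || anyNA(est[terms]),
          "terms not all estimated: %s", paste(terms, collapse = ", "))
  v <- vcov(fit)
  w <- if (is.null(weights)) rep(1 / length(terms), length(terms))
       else weights / sum(weights)
  point <- sum(w * est[terms])
  se <- sqrt(drop(t(w) %*% v[terms, terms] %*% w))
  tt <- point / se
  list(estimate = point, se = se, t = tt,
       p = 2 * stats::pt(-abs(tt), df = fit$df), df = fit$df)
}
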