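#' Absorb high-dimensional fixed effects by alternating demeaning
#'
#' Iterated within-group mean subtraction, cycling over the fixed-effect
#' groups until the maximum absolute change of any cell (on columns
#' standardized to unit scale) falls below `tol`, or `max_iter` cycles.
#' With a single group one pass is exact; with nested groups convergence
#' takes at most two cycles. Observations that are singletons in any group
#' cell (after iteratively intersecting groups) are removed before
#' demeaning, since they would be fitted perfectly by their own fixed
#' effect.
#'
#' @param x numeric matrix (columns to demean).
#' @param groups list of factors (or vectors coercible to factors), one
#'   label per row of `x`.
#' @param tol convergence tolerance on standardized columns.
#' @param max_iter maximum number of cycles over all groups.
#' @return list: `x` (demeaned matrix, singleton rows removed), `keep`
#'   (logical row filter applied), `iterations`, `delta` (last max change),
#'   `n_singletons`, `levels` (per-group level counts after drops).
#' @export
absorb_fe <- function(x, groups, tol = 1e-10, max_iter = 10000L) {
  fail_if(length(groups) < 1, "at least one fixed-effect group is required")
  x <- as.matrix(x)
  n <- nrow(x)
  gs <- lapply(groups, function(g) as.integer(factor(g)))
  fail_if(!all(lengths(gs) == n), "each group must have one label per row")

  # iterative singleton removal: a row alone in any group cell is dropped,
  # which can create new singletons in other groups
  keep <- rep(TRUE, n)
  repeat {
    dropped <- FALSE
    for (g in gs) {
      # counts per cell among kept rows only (g * FALSE = 0 is ignored)
      cnt <- tabulate(g * keep)
      is_single <- keep & cnt[g] == 1L
      if (any(is_single)) { keep[is_single] <- FALSE; dropped <- TRUE }
    }
    if (!dropped) break
  }
  n_singletons <- sum(!keep)
  xk <- x[keep, , drop = FALSE]
  gk <- lapply(gs, function(g) as.integer(factor(g[keep])))
  counts <- lapply(gk, tabulate)

  # standardize columns for the convergence test; demeaning is linear so the
  # result rescales exactly
  scale_x <- apply(xk, 2, function(c) {
    s <- stats::sd(c); if (!is.finite(s) || s == 0) 1 else s
  })
  xs <- sweep(xk, 2, scale_x, "/")

  it <- 0L
  delta <- Inf
  while (it < max_iter) {
    it <- it + 1L
    prev <- xs
    for (k in seq_along(gk)) {
      gm <- rowsum(xs, gk[[k]], reorder = TRUE) / counts[[k]]
      xs <- xs - gm[gk[[k]], , drop = FALSE]
    }
    delta <- max(abs(xs - prev))
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop(sprintf("absorb_fe did not converge in %d cycles (last delta %.3e)",
                 max_iter, delta), call. = FALSE)
  }
  list(x = sweep(xs, 2, scale_x, "*"), keep = keep,
       iterations = it, delta = delta, n_singletons = n_singletons,
       levels = vapply(gk, max, integer(1)))
}

# Least squares on demeaned columns via rank-revealing (pivoted) QR.
# Returns coefficients for retained columns and names of dropped ones.
ols_solve <- function(x, y, tol = 1e-7) {
  fail_if(ncol(x) == 0, "no regressors to fit")
  qx <- qr(x, tol = tol)
  r <- qx$rank
  kept <- sort(qx$pivot[seq_len(r)])
  dropped <- colnames(x)[setdiff(seq_len(ncol(x)), kept)]
  if (r == 0) stop("all regressor columns are collinear with the fixed effects",
                   call. = FALSE)
  xk <- x[, kept, drop = FALSE]
  beta <- qr.coef(qr(xk), y)
  list(beta = beta, kept = colnames(x)[kept], dropped = dropped, x = xk)
}

#' One-way cluster-robust (CR1) sandwich variance
#'
#' Computes
#' \deqn{(X'X)^{-1} \Big(\sum_g X_g' e_g e_g' X_g\Big) (X'X)^{-1}}
#' scaled by the CR1 small-sample factor `G/(G-1) * (N-1)/(N-K)`, where `K`
#' counts the retained regressors plus the degrees of freedom absorbed by
#' the fixed effects.
#'
#' @param x demeaned regressor matrix (retained columns only).
#' @param residuals residual vector from the demeaned least squares fit.
#' @param clusters cluster label per observation; at least 2 clusters.
#' @param k_absorbed degrees of freedom absorbed by fixed effects (0 if the
#'   model had none).
#' @return the variance-covariance matrix, with attributes `G` (number of
#'   clusters) and `dof` (t-distribution degrees of freedom, `G - 1`).
#' @export
cluster_vcov <- function(x, residuals, clusters, k_absorbed = 0L) {
  cl <- as.integer(factor(clusters))
  G <- max(cl)
  fail_if(G < 2, "cluster-robust variance needs at least 2 clusters (got %d)", G)
  n <- nrow(x)
  K <- ncol(x) + k_absorbed
  xe <- x * residuals
  scores <- rowsum(xe, cl)                    # G x p matrix of cluster sums
  meat <- crossprod(scores)
  bread <- chol2inv(chol(crossprod(x)))
  adj <- G / (G - 1) * (n - 1) / (n - K)
  v <- adj * bread %*% meat %*% bread
  dimnames(v) <- list(colnames(x), colnames(x))
  structure((v + t(v)) / 2, G = G, dof = G - 1L)
}

#' Linear probability model with absorbed high-dimensional fixed effects
#'
#' Fits `y = X b + fixed effects + e` by alternating-projection demeaning
#' ([absorb_fe()]) followed by least squares on the demeaned columns, with
#' one-way cluster-robust (CR1) inference. For a binary outcome this is the
#' linear probability model: coefficients are changes in the probability of
#' the outcome per unit of the regressor (per additional day, for bin-count
#' exposures). p-values use a t distribution with `G - 1` degrees of
#' freedom, `G` the number of clusters.
#'
#' @param formula model formula, e.g. `male ~ t1_bin20_25 + ...`. No
#'   intercept is fitted (it is absorbed by the fixed effects).
#' @param data data.frame containing the outcome, regressors, fixed-effect
#'   and cluster columns.
#' @param fe character vector of column names in `data`, or a list of
#'   factors, defining the fixed-effect groups (e.g. region x calendar
#'   month and region x year; a mother id group is equally valid).
#' @param cluster column name or vector of cluster labels (e.g. region).
#' @param weights optional observation weights (experimental; defaults to
#'   1 and is not part of the canonical analysis).
#' @param tol,max_iter absorption controls, see [absorb_fe()].
#' @return an object of class `felpm` with methods `print`, `summary`,
#'   `coef`, `vcov`, `confint`, `residuals`, `fitted`, `nobs`.
#' @export
felpm <- function(formula, data, fe, cluster,
                  weights = NULL, tol = 1e-10, max_iter = 10000L) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(stats::update(formula, . ~ . - 1), mf)

  groups <- if (is.character(fe)) {
    stats::setNames(lapply(fe, function(nm) {
      fail_if(is.null(data[[nm]]), "fixed-effect column '%s' not in data", nm)
      data[[nm]]
    }), fe)
  } else fe
  cl_vec <- if (is.character(cluster) && length(cluster) == 1) {
    fail_if(is.null(data[[cluster]]), "cluster column '%s' not in data", cluster)
    data[[cluster]]
  } else cluster

  if (!is.null(weights)) {
    w <- sqrt(weights)
    x <- x * w; y <- y * w
    warning("weights are experimental; the canonical analysis is unweighted")
  }

  ab <- absorb_fe(cbind(y = y, x), groups, tol = tol, max_iter = max_iter)
  keep <- ab$keep
  yd <- ab$x[, 1]
  xd <- ab$x[, -1, drop = FALSE]
  cl_kept <- cl_vec[keep]

  sol <- ols_solve(xd, yd)
  e <- yd - sol$x %*% sol$beta
  k_absorbed <- sum(ab$levels) - (length(ab$levels) - 1L)
  v <- cluster_vcov(sol$x, as.vector(e), cl_kept, k_absorbed = k_absorbed)

  se <- sqrt(diag(v))
  tstat <- sol$beta / se
  dof <- attr(v, "dof")
  pval <- 2 * stats::pt(-abs(tstat), df = dof)

  coefs <- stats::setNames(rep(NA_real_, ncol(x)), colnames(x))
  coefs[sol$kept] <- sol$beta

  structure(list(
    coefficients = coefs,
    vcov = v, se = se, tstat = tstat, pval = pval,
    df = dof, n_clusters = attr(v, "G"),
    nobs = sum(keep), n_dropped_singletons = ab$n_singletons,
    dropped_collinear = sol$dropped,
    iterations = ab$iterations, final_delta = ab$delta,
    k_absorbed = k_absorbed, fe_levels = ab$levels,
    residuals = as.vector(e), keep = keep,
    fitted = y[keep] - as.vector(e),
    y_name = deparse(formula[[2]]),
    call = match.call()
  ), class = "felpm")
}

#' @export
coef.felpm <- function(object, ...) object$coefficients

#' @export
vcov.felpm <- function(object, ...) object$vcov

#' @export
nobs.felpm <- function(object, ...) object$nobs

#' @export
residuals.felpm <- function(object, ...) object$residuals

#' @export
fitted.felpm <- function(object, ...) object$fitted

#' @export
confint.felpm <- function(object, parm, level = 0.95, ...) {
  est <- object$coefficients[!is.na(object$coefficients)]
  if (missing(parm)) parm <- names(est)
  tc <- stats::qt(1 - (1 - level) / 2, df = object$df)
  ci <- cbind(est[parm] - tc * object$se[parm],
              est[parm] + tc * object$se[parm])
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  ci
}

#' @export
print.felpm <- function(x, ...) {
  cat(sprintf("<felpm> %s on %d obs (%d singleton%s dropped), %d clusters, t(%d) inference\n",
              x$y_name, x$nobs, x$n_dropped_singletons,
              if (x$n_dropped_singletons == 1) "" else "s",
              x$n_clusters, x$df))
  cat(sprintf("  FE levels: %s (K absorbed = %d); absorption: %d cycles, delta %.2e\n",
              paste(x$fe_levels, collapse = " x "), x$k_absorbed,
              x$iterations, x$final_delta))
  if (length(x$dropped_collinear)) {
    cat("  dropped collinear:", paste(x$dropped_collinear, collapse = ", "), "\n")
  }
  est <- x$coefficients[!is.na(x$coefficients)]
  print(round(est, 6))
  invisible(x)
}

#' @export
summary.felpm <- function(object, ...) {
  est <- object$coefficients[!is.na(object$coefficients)]
  tab <- cbind(Estimate = est, `Std. Error` = object$se,
               `t value` = object$tstat, `Pr(>|t|)` = object$pval)
  structure(list(coefficients = tab, df = object$df,
                 n_clusters = object$n_clusters, nobs = object$nobs,
                 n_dropped_singletons = object$n_dropped_singletons,
                 dropped_collinear = object$dropped_collinear,
                 call = object$call),
            class = "summary.felpm")
}

#' @export
print.summary.felpm <- function(x, ...) {
  cat("Linear probability model with absorbed fixed effects\n")
  cat(sprintf("n = %d, clusters = %d, t(%d) p-values (CR1)\n",
              x$nobs, x$n_clusters, x$df))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Fit the canonical SRB temperature regression on an exposure matrix
#'
#' Convenience wrapper around [felpm()]: regresses the male indicator on
#' every treatment, control-lag and rainfall column of an exposure matrix,
#' absorbing region-by-calendar-month and region-by-year fixed effects (an
#' optional mother fixed effect can be added), clustering at the region
#' level.
#'
#' @param exposure an [build_exposure()] result.
#' @param fe any of `"region_month"`, `"region_year"`, `"mother"`;
#'   the default is the canonical two-way structure.
#' @param cluster column used for clustering (default `"region_id"`).
#' @param region_trend replace the region-by-year fixed effect with a linear
#'   calendar-year trend interacted with region (added as regressors).
#' @param ... passed to [felpm()].
#' @return a `felpm` object.
#' @export
srb_fit <- function(exposure, fe = c("region_month", "region_year"),
                    cluster = "region_id", region_trend = FALSE, ...) {
  xcols <- c(attr(exposure, "treatment_cols"), attr(exposure, "control_cols"),
             attr(exposure, "rain_cols"))
  groups <- list()
  if ("region_month" %in% fe) {
    groups$region_month <- interaction(exposure$region_id, exposure$birth_month,
                                       drop = TRUE)
  }
  if ("region_year" %in% fe && !region_trend) {
    groups$region_year <- interaction(exposure$region_id, exposure$birth_year,
                                      drop = TRUE)
  }
  if ("mother" %in% fe) {
    groups$mother <- factor(exposure$mother_id)
  }
  df <- exposure[, c("male", xcols), drop = FALSE]
  if (region_trend) {
    tr <- stats::model.matrix(~ 0 + factor(region_id), exposure) *
      (exposure$birth_year - min(exposure$birth_year))
    colnames(tr) <- paste0("trend_r", sort(unique(exposure$region_id)))
    df <- cbind(df, as.data.frame(tr))
    xcols <- c(xcols, colnames(tr))
  }
  fml <- stats::reformulate(xcols, response = "male")
  fit <- felpm(fml, data = df, fe = groups,
               cluster = exposure[[cluster]], ...)
  fit$treatment_cols <- attr(exposure, "treatment_cols")
  fit
}
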