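make_crossed <- function(n, G1 = 10, G2 = 12, p = 3, seed = 1, cl_n = 10) {
  set.seed(seed)
  g1 <- factor(sample(G1, n, TRUE))
  g2 <- factor(sample(G2, n, TRUE))
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- seq_len(p) / 2
  y <- as.vector(x %*% beta) + rnorm(G1)[g1] + rnorm(G2)[g2] + rnorm(n)
  data.frame(y = y, x, g1 = g1, g2 = g2, cl = sample(cl_n, n, TRUE))
}

test_that("single-group absorption is exact one-pass demeaning", {
  set.seed(4)
  x <- matrix(rnorm(60), 30, 2)
  g <- rep(1:5, each = 6)
  ab <- absorb_fe(x, list(g))
  gm <- rowsum(ab$x, g) / 6
  expect_lt(max(abs(gm)), 1e-12)
  expect_lte(ab$iterations, 2)
})

test_that("nested groups converge in at most two cycles", {
  set.seed(5)
  g_outer <- rep(1:4, each = 25)
  g_inner <- rep(1:20, each = 5)      # nested within outer
  x <- matrix(rnorm(200), 100, 2)
  ab <- absorb_fe(x, list(g_outer, g_inner))
  expect_lte(ab$iterations, 2)
  expect_lt(max(abs(rowsum(ab$x, g_inner))), 1e-8)
})

test_that("crossed-group absorption matches dense dummy-variable residuals", {
  d <- make_crossed(200, seed = 6)
  ab <- absorb_fe(cbind(d$y, d$x1, d$x2, d$x3),
                  list(d$g1, d$g2))
  keep <- ab$keep
  for (k in 1:4) {
    v <- list(d$y, d$x1, d$x2, d$x3)[[k]][keep]
    oracle <- residuals(lm(v ~ g1 + g2, data = d[keep, ]))
    expect_lt(max(abs(ab$x[, k] - oracle)), 1e-8)
  }
})

test_that("absorption reports non-convergence instead of failing silently", {
  d <- make_crossed(200, seed = 7)
  expect_error(absorb_fe(cbind(d$y), list(d$g1, d$g2), tol = 1e-14,
                         max_iter = 1L),
               "did not converge")
})

test_that("felpm equals dense dummy OLS and obeys Frisch-Waugh-Lovell", {
  d <- make_crossed(400, seed = 8)
  f <- felpm(y ~ x1 + x2 + x3, d, fe = c("g1", "g2"), cluster = "cl")
  ol <- lm(y ~ x1 + x2 + x3 + g1 + g2, d)
  expect_lt(max(abs(coef(f)[1:3] - coef(ol)[c("x1", "x2", "x3")])), 1e-8)
})

test_that("orthonormal demeaned design gives beta = X'y", {
  set.seed(9)
  n <- 64
  q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  colnames(q) <- c("a", "b")
  y <- rnorm(n)
  sol <- heatsrb:::ols_solve(q, y)
  expect_equal(unname(sol$beta), as.vector(t(q) %*% y), tolerance = 1e-10)
})

test_that("duplicate columns are dropped by name, estimates unchanged", {
  d <- make_crossed(300, seed = 10)
  d$x1_dup <- d$x1
  f2 <- felpm(y ~ x1 + x1_dup + x2 + x3, d, fe = c("g1", "g2"), cluster = "cl")
  f1 <- felpm(y ~ x1 + x2 + x3, d, fe = c("g1", "g2"), cluster = "cl")
  expect_equal(f2$dropped_collinear, "x1_dup")
  expect_equal(coef(f2)[c("x1", "x2", "x3")], coef(f1)[c("x1", "x2", "x3")],
               tolerance = 1e-10)
})

test_that("cluster vcov with singleton clusters reduces to HC1 up to dof", {
  set.seed(11)
  n <- 40
  x <- cbind(a = rnorm(n), b = rnorm(n))
  e <- rnorm(n)
  v <- cluster_vcov(x, e, seq_len(n))
  xtxi <- solve(crossprod(x))
  hc0 <- xtxi %*% crossprod(x * e) %*% xtxi
  ratio <- n / (n - 1) * (n - 1) / (n - 2)      # CR1 factor at G = N, K = 2
  expect_equal(unname(v), unname(hc0 * ratio), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(cluster_vcov(x, e, rep(1, n)), "at least 2 clusters")
})

test_that("cluster vcov matches the sandwich package on a dummy-variable fit", {
  d <- make_crossed(600, G1 = 5, G2 = 4, seed = 12, cl_n = 12)
  f <- felpm(y ~ x1 + x2 + x3, d, fe = c("g1", "g2"), cluster = "cl")
  expect_equal(f$n_dropped_singletons, 0L)
  ol <- lm(y ~ x1 + x2 + x3 + g1 + g2, d)
  vo <- sandwich::vcovCL(ol, cluster = d$cl, type = "HC1", cadjust = TRUE)
  expect_equal(unname(vcov(f)[1:3, 1:3]),
               unname(vo[c("x1", "x2", "x3"), c("x1", "x2", "x3")]),
               tolerance = 1e-7)
})

test_that("cluster SEs stay near classical SEs under homoskedastic errors", {
  set.seed(13)
  ratios <- replicate(200, {
    n <- 250; G <- 50
    g <- rep(1:G, each = n / G)
    x <- rnorm(n)
    y <- 0.3 * x + rnorm(n)
    d <- data.frame(y, x, g, one = 1)
    f <- felpm(y ~ x, d, fe = list(rep(1, n)), cluster = d$g)
    ols <- lm(y ~ x)
    f$se["x"] / summary(ols)$coefficients["x", "Std. Error"]
  })
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("estimates are invariant to observation order", {
  d <- make_crossed(300, seed = 14)
  f1 <- felpm(y ~ x1 + x2 + x3, d, fe = c("g1", "g2"), cluster = "cl")
  ix <- sample(nrow(d))
  f2 <- felpm(y ~ x1 + x2 + x3, d[ix, ], fe = c("g1", "g2"), cluster = "cl")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(f1$se, f2$se, tolerance = 1e-9)
})

test_that("singleton observations are flagged and removed", {
  set.seed(15)
  g1 <- c(rep(1:3, each = 10), 4)       # one obs alone in its cell
  g2 <- sample(2, 31, TRUE)
  x <- rnorm(31); y <- rnorm(31)
  d <- data.frame(y, x, g1, g2, cl = sample(4, 31, TRUE))
  f <- felpm(y ~ x, d, fe = c("g1", "g2"), cluster = "cl")
  expect_gte(f$n_dropped_singletons, 1)
  expect_equal(f$nobs + f$n_dropped_singletons, 31)
})

test_that("changing the reference bin leaves coefficient contrasts stable", {
  # five bin-count columns summing to a fixed 90-day window: dropping any one
  # as the reference spans the same model space, so contrasts between two
  # retained bins must be identical
  set.seed(17)
  n <- 500
  counts <- t(rmultinom(n, 90, prob = c(.1, .2, .3, .25, .15)))
  colnames(counts) <- paste0("bin", 1:5)
  g1 <- factor(sample(10, n, TRUE)); g2 <- factor(sample(6, n, TRUE))
  y <- counts %*% c(0.002, 0, -0.001, -0.003, -0.004) +
    rnorm(10)[g1] * 0.05 + rnorm(n, sd = 0.2)
  d <- data.frame(y = as.vector(y), counts, g1 = g1, g2 = g2,
                  cl = sample(8, n, TRUE))
  f_ref2 <- felpm(y ~ bin1 + bin3 + bin4 + bin5, d, fe = c("g1", "g2"),
                  cluster = "cl")
  f_ref3 <- felpm(y ~ bin1 + bin2 + bin4 + bin5, d, fe = c("g1", "g2"),
                  cluster = "cl")
  c1 <- coef(f_ref2)["bin5"] - coef(f_ref2)["bin4"]
  c2 <- coef(f_ref3)["bin5"] - coef(f_ref3)["bin4"]
  expect_equal(unname(c1), unname(c2), tolerance = 1e-8)
  # and each coefficient shifts by the (new reference's) old coefficient
  expect_equal(unname(coef(f_ref3)["bin5"]),
               unname(coef(f_ref2)["bin5"] - coef(f_ref2)["bin3"]),
               tolerance = 1e-8)
})

test_that("confidence intervals attain nominal coverage with G = 50 clusters", {
  set.seed(16)
  reps <- 200
  cover <- logical(reps)
  for (r in seq_len(reps)) {
    n <- 1500; G <- 50
    g1 <- factor(sample(G, n, TRUE)); g2 <- factor(sample(12, n, TRUE))
    x <- rnorm(n) + 0.5 * rnorm(G)[g1]
    y <- 0.5 * x + rnorm(G)[g1] + rnorm(12)[g2] + rnorm(n)
    d <- data.frame(y, x, g1, g2)
    f <- felpm(y ~ x, d, fe = c("g1", "g2"), cluster = d$g1)
    ci <- confint(f)
    cover[r] <- ci[1, 1] <= 0.5 && 0.5 <= ci[1, 2]
  }
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("region trend option replaces the region-year group", {
  w <- small_world()
  x <- build_exposure(w$kept, w$climate, w$psus)
  f <- srb_fit(x, region_trend = TRUE)
  expect_true(any(grepl("^trend_r", names(coef(f)))))
  expect_equal(length(f$fe_levels), 1L)   # only region-month absorbed
})

test_that("mother fixed effects are accepted as an additional group", {
  w <- small_world()
  x <- build_exposure(w$kept, w$climate, w$psus)
  f <- srb_fit(x, fe = c("region_month", "region_year", "mother"))
  expect_equal(length(f$fe_levels), 3L)
  expect_gt(f$n_dropped_singletons, 0)    # one-birth mothers drop out
})
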