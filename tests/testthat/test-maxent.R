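make_env <- function(n, p = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * p), n, p)
  colnames(m) <- paste0("v", seq_len(p))
  m
}

test_that("feature expansion has the expected dictionary sizes", {
  bg <- make_env(50, 2)
  f <- maxent_features(bg, classes = c("linear", "quadratic", "product"))
  expect_equal(nrow(f$meta), 5L) # 2 linear + 2 quadratic + 1 product
  f2 <- maxent_features(bg[, 1, drop = FALSE], classes = "hinge",
                        n_hinge_knots = 50)
  expect_equal(nrow(f2$meta), 100L) # two directions per knot
  # constant background column is dropped with a warning
  bg3 <- cbind(bg, k = 1)
  expect_warning(f3 <- maxent_features(bg3, "l"), "constant")
  expect_equal(f3$vars, c("v1", "v2"))
  # single variable with product class yields no product features
  expect_warning(f4 <- maxent_features(bg[, 1, drop = FALSE], "lp"),
                 "product")
  expect_equal(unique(f4$meta$kind), "linear")
})

test_that("feature values respect scaling bounds and clamping", {
  bg <- make_env(100, 1)
  f <- maxent_features(bg, "l")
  d <- feature_design(f, bg)
  expect_equal(range(d), c(0, 1))
  beyond <- matrix(c(-5, 5), 2, 1, dimnames = list(NULL, "v1"))
  expect_equal(as.vector(feature_design(f, beyond)), c(0, 1))
})

test_that("total shrinkage and monotone separation behave as expected", {
  bg <- make_env(200, 2, seed = 2)
  pres <- make_env(30, 2, seed = 3)
  m <- maxent_sdm(pres, bg, classes = "l", beta = 1e6)
  expect_true(all(m$lambda == 0))
  q <- predict(m, bg, type = "raw")
  expect_equal(q, rep(1 / 200, 200), tolerance = 1e-12)
  # a binary feature present at every presence gets a positive weight
  bgb <- cbind(v1 = c(rep(0, 150), rep(1, 50)))
  presb <- cbind(v1 = rep(1, 20))
  mb <- maxent_sdm(presb, bgb, classes = "l", beta = 0.5)
  expect_gt(mb$lambda[["l_v1"]], 0)
})

test_that("fitted coefficient matches the brute-force grid-search oracle", {
  # 6-cell landscape, one linear feature, beta = 1
  bg <- matrix(c(0, 0.2, 0.4, 0.6, 0.8, 1), 6, 1, dimnames = list(NULL, "v1"))
  pres <- bg[c(4, 5, 6, 6), , drop = FALSE]
  m <- maxent_sdm(pres, bg, classes = "l", beta = 1,
                  control = list(tol = 1e-12, gtol = 1e-9, maxit = 50000))
  s <- m$reg_scales
  lam_star <- oracle_maxent_1d(feature_design(m$features, pres),
                               feature_design(m$features, bg),
                               beta = 1, s = s)
  expect_equal(unname(m$lambda[1]), lam_star, tolerance = 1e-3)
})

test_that("unpenalized fit satisfies maxent moment matching", {
  bg <- make_env(300, 2, seed = 5)
  pres <- make_env(40, 2, seed = 6)^2 # skewed towards low values
  m <- maxent_sdm(pres, bg, classes = "l", beta = 0,
                  control = list(tol = 1e-13, gtol = 1e-8, maxit = 50000))
  Xp <- feature_design(m$features, pres)
  Xb <- feature_design(m$features, bg)
  q <- predict(m, bg, type = "raw")
  expect_lt(max(abs(colMeans(Xp) - colSums(Xb * q))), 1e-6)
})

test_that("the penalized objective trace is monotone non-decreasing", {
  bg <- make_env(200, 3, seed = 8)
  pres <- make_env(25, 3, seed = 9)
  m <- maxent_sdm(pres, bg, classes = "lqh", beta = 1, n_hinge_knots = 10)
  expect_true(all(diff(m$trace) >= -1e-10))
  expect_true(m$converged)
})

test_that("non-convergence raises an error carrying the objective trace", {
  bg <- make_env(200, 2, seed = 2)
  pres <- make_env(30, 2, seed = 3)
  err <- tryCatch(
    maxent_sdm(pres, bg, classes = "l", beta = 0.1,
               control = list(tol = 1e-300, maxit = 3)),
    error = function(e) e)
  expect_match(conditionMessage(err), "converge")
  expect_true(length(err$trace) >= 2)
})

test_that("raw probabilities normalize over the training background", {
  bg <- make_env(150, 2, seed = 10)
  pres <- make_env(25, 2, seed = 11)
  m <- maxent_sdm(pres, bg, classes = "lq", beta = 1)
  q <- predict(m, bg, type = "raw")
  expect_equal(sum(q), 1, tolerance = 1e-12)
  eta <- predict(m, bg, type = "link")
  expect_equal(order(q), order(eta))
  # weighted raw output sums to 1 with the training weights
  w <- runif(150)
  mw <- maxent_sdm(pres, bg, classes = "lq", beta = 1, bg_weights = w)
  qw <- predict(mw, bg, type = "raw", weights = w)
  expect_equal(sum(qw), 1, tolerance = 1e-12)
})

test_that("logistic output is bounded, rank-preserving and 0.5 when uniform", {
  bg <- make_env(120, 2, seed = 12)
  pres <- make_env(20, 2, seed = 13)
  m <- maxent_sdm(pres, bg, classes = "l", beta = 1e6) # uniform model
  expect_equal(predict(m, bg), rep(0.5, 120), tolerance = 1e-12)
  m2 <- maxent_sdm(pres, bg, classes = "lq", beta = 0.5)
  s <- predict(m2, bg)
  expect_true(all(s > 0 & s < 1))
  expect_equal(order(s), order(predict(m2, bg, type = "raw")))
})

test_that("raster prediction equals pointwise prediction with clamping", {
  set.seed(14)
  v1 <- matrix(runif(48), 6, 8); v2 <- matrix(runif(48), 6, 8)
  v1[3, 3] <- NA
  stack <- raster_stack(v1 = raster_grid(v1), v2 = raster_grid(v2))
  tab <- na.omit(cbind(v1 = as.vector(v1), v2 = as.vector(v2)))
  pres <- tab[sample(nrow(tab), 12), ]
  m <- maxent_sdm(pres, tab, classes = "lq", beta = 1)
  r <- predict(m, stack)
  ok <- !is.na(v1)
  expect_equal(as.vector(r$values)[as.vector(ok)],
               predict(m, cbind(v1 = v1[ok], v2 = v2[ok])),
               tolerance = 1e-12)
  expect_true(is.na(r$values[3, 3])) # nodata propagates
  # a value beyond the training bounds predicts as at the bound
  top <- max(tab[, "v1"])
  beyond <- cbind(v1 = c(top + 10, top), v2 = c(0.5, 0.5))
  p <- predict(m, beyond)
  expect_equal(p[1], p[2], tolerance = 1e-12)
  # clamped prediction is idempotent
  expect_equal(predict(m, pmin(pmax(beyond, 0), 1)), predict(m, beyond),
               tolerance = 1e-12)
  expect_error(predict(m, raster_stack(v1 = raster_grid(v1))), "missing")
})

test_that("permutation importance splits between duplicated variables", {
  set.seed(15)
  x <- runif(400)
  bg <- cbind(a = x, b = x + rnorm(400, 0, 1e-3))
  pres_x <- sort(runif(40, 0.6, 1))
  pres <- cbind(a = pres_x, b = pres_x + rnorm(40, 0, 1e-3))
  m <- maxent_sdm(pres, bg, classes = "l", beta = 1)
  imp <- variable_importance(m, pres, bg, seed = 4, jackknife = FALSE)
  expect_equal(sum(imp$contribution), 100)
  expect_true(all(abs(imp$contribution - 50) < 10))
  # a single informative variable takes everything
  m1 <- maxent_sdm(pres[, "a", drop = FALSE], bg[, "a", drop = FALSE],
                   classes = "l", beta = 1)
  imp1 <- variable_importance(m1, pres[, "a", drop = FALSE],
                              bg[, "a", drop = FALSE], jackknife = TRUE)
  expect_equal(imp1$contribution, 100)
  expect_gt(imp1$gain_only, 0)
})

test_that("response curves count interior modes like a brute-force scan", {
  bg <- make_env(300, 2, seed = 16)
  pres <- make_env(40, 2, seed = 17)
  m_lin <- maxent_sdm(pres, bg, classes = "l", beta = 0.5)
  rc <- response_curve(m_lin, "v1")
  expect_equal(attr(rc, "interior_modes"), 0L)
  expect_true(all(diff(rc$suitability) >= 0) || all(diff(rc$suitability) <= 0))
  # quadratic niche model: one interior mode
  set.seed(18)
  bgq <- make_env(400, 1, seed = 18)
  presq <- cbind(v1 = rnorm(60, 0.5, 0.08))
  mq <- maxent_sdm(presq, bgq, classes = "lq", beta = 0.2)
  rcq <- response_curve(mq, "v1")
  expect_equal(attr(rcq, "interior_modes"), 1L)
  # the counter agrees with an independent local-maxima scan
  scan_modes <- function(y) {
    sum(vapply(2:(length(y) - 1), function(i) {
      left <- max(y[max(1, i - 5):(i - 1)])
      right <- max(y[(i + 1):min(length(y), i + 5)])
      y[i] > left && y[i] > right
    }, logical(1)))
  }
  for (m in list(m_lin, mq)) {
    y <- response_curve(m, "v1")$suitability
    expect_equal(attr(response_curve(m, "v1"), "interior_modes"),
                 scan_modes(y))
  }
})

test_that("AICc arithmetic and candidate ranking follow the definitions", {
  # direct arithmetic check: k = 3, n = 30, lnL = -100
  k <- 3; n <- 30; lnL <- -100
  expect_equal(2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1), 206.923,
               tolerance = 5e-4)
  bg <- make_env(250, 2, seed = 19)
  pres <- make_env(30, 2, seed = 20)
  models <- maxent_candidates(pres, bg,
                              grid = list(simple = list(classes = "l", beta = 1),
                                          rich = list(classes = "lqh", beta = 0.1)),
                              n_hinge_knots = 10)
  tab <- rank_candidates(models, pres, bg)
  expect_equal(sort(tab$rank[!tab$excluded]), seq_len(sum(!tab$excluded)))
  a <- aicc(models$simple, pres, bg)
  expect_equal(a$aicc,
               2 * a$k - 2 * a$lnL + 2 * a$k * (a$k + 1) / (a$n - a$k - 1))
  # k >= n - 1 is excluded from ranking
  pres_tiny <- make_env(4, 2, seed = 21)
  m_over <- suppressWarnings(
    maxent_sdm(pres_tiny, bg, classes = "lqph", beta = 1e-4,
               n_hinge_knots = 10,
               control = list(tol = 1e-5, maxit = 2000)))
  if (sum(m_over$lambda != 0) >= 3) {
    expect_true(is.na(aicc(m_over, pres_tiny, bg)$aicc))
  }
  # equal log-likelihood with fewer parameters ranks first
  aicc_val <- function(k, n, lnL) 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
  expect_lt(aicc_val(2, 30, -100), aicc_val(5, 30, -100))
})
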