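pc_cloud <- function(n, mu = c(0, 0), sd = 1, seed = 1) {
  set.seed(seed)
  cbind(rnorm(n, mu[1], sd), rnorm(n, mu[2], sd))
}

test_that("background PCA is an orthonormal ordination", {
  set.seed(1)
  bg1 <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  bg2 <- matrix(rnorm(600, 1), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- pca_env(bg1, bg2)
  rot <- p$prcomp$rotation
  expect_equal(crossprod(rot), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(p$explained) <= 1e-12))
  # two variables: the PC plane is a rotation, pairwise distances preserved
  b1 <- bg1[, 1:2]; b2 <- bg2[, 1:2]
  p2 <- pca_env(b1, b2)
  z <- scale(rbind(b1, b2), center = p2$prcomp$center, scale = p2$prcomp$scale)
  d_orig <- dist(z[1:50, ])
  d_proj <- dist(project_pca(p2, rbind(b1, b2))[1:50, ])
  expect_equal(as.vector(d_proj), as.vector(d_orig), tolerance = 1e-10)
  # constant variable dropped with a warning
  expect_warning(pca_env(cbind(bg1, k = 1), cbind(bg2, k = 1)), "constant")
})

test_that("occupancy grids are normalized availability-corrected densities", {
  occ <- pc_cloud(120, seed = 2)
  bg <- pc_cloud(2000, sd = 2, seed = 3)
  g <- occupancy_grid(occ, bg)
  expect_equal(sum(g$occupancy), 1, tolerance = 1e-9)
  expect_true(all(g$occupancy >= 0))
  # single occurrence: the occupancy mode sits at its grid cell
  one <- matrix(c(0.3, -0.2), 1, 2)
  g1 <- occupancy_grid(one, bg, R = 51)
  idx <- which(g1$occupancy == max(g1$occupancy), arr.ind = TRUE)
  expect_equal(g1$x[idx[1]], 0.3, tolerance = diff(g1$x[1:2]) * 1.5)
  expect_equal(g1$y[idx[2]], -0.2, tolerance = diff(g1$y[1:2]) * 1.5)
  # uniform occurrences over a uniform background: flat occupancy
  set.seed(4)
  u_occ <- cbind(runif(10000), runif(10000))
  u_bg <- cbind(runif(10000), runif(10000))
  gu <- occupancy_grid(u_occ, u_bg, R = 40,
                       frame = list(xlim = c(0, 1), ylim = c(0, 1)))
  inner <- gu$occupancy[5:36, 5:36] # away from kernel edge effects
  expect_lt(stats::sd(inner) / mean(inner), 0.1)
  expect_error(occupancy_grid(matrix(c(99, 99), 1, 2), bg,
                              frame = list(xlim = c(0, 1), ylim = c(0, 1))),
               "outside")
})

test_that("Schoener's D identities hold exactly", {
  o <- c(0.2, 0.3, 0.5)
  expect_equal(schoeners_d(o, o), 1)
  expect_equal(schoeners_d(c(1, 0, 0), c(0, 0, 1)), 0)
  expect_equal(schoeners_d(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 0.5)
  # symmetry and cell-permutation invariance
  set.seed(5)
  a <- runif(100); b <- runif(100)
  expect_identical(schoeners_d(a, b), schoeners_d(b, a))
  p <- sample(100)
  expect_equal(schoeners_d(a[p], b[p]), schoeners_d(a, b))
  # frame mismatch between grids is an error
  g1 <- occupancy_grid(pc_cloud(30, seed = 6), pc_cloud(500, sd = 2, seed = 7),
                       frame = list(xlim = c(-4, 4), ylim = c(-4, 4)))
  g2 <- occupancy_grid(pc_cloud(30, seed = 8), pc_cloud(500, sd = 2, seed = 9),
                       frame = list(xlim = c(-5, 4), ylim = c(-4, 4)))
  expect_error(schoeners_d(g1, g2), "frames")
})

test_that("randomization tests bound p-values and respect the seed", {
  occ1 <- pc_cloud(40, seed = 10)
  occ2 <- pc_cloud(40, mu = c(0.5, 0), seed = 11)
  bg1 <- pc_cloud(800, sd = 2, seed = 12)
  bg2 <- pc_cloud(800, sd = 2, seed = 13)
  eq <- niche_equivalency_test(occ1, occ2, bg1, bg2, R = 60, reps = 19,
                               seed = 14)
  expect_gte(eq$p_lower, 1 / 20)
  expect_lte(eq$p_lower, 1)
  expect_equal(length(eq$null), 19)
  eq2 <- niche_equivalency_test(occ1, occ2, bg1, bg2, R = 60, reps = 19,
                                seed = 14)
  expect_identical(eq$null, eq2$null)
  sim <- niche_similarity_test(occ1, occ2, bg1, bg2, R = 60, reps = 19,
                               seed = 15)
  expect_gte(sim$p_lower, 1 / 20)
  expect_lte(sim$p_upper, 1)
  expect_error(niche_equivalency_test(occ1[1, , drop = FALSE], occ2,
                                      bg1, bg2, reps = 5), "at least 2")
})

test_that("niche dynamics indices satisfy the subset and disjoint identities", {
  R <- 10
  o_nat <- matrix(0, R, R); o_nat[3:8, 3:8] <- 1
  o_sub <- matrix(0, R, R); o_sub[4:6, 4:6] <- 1
  g_nat <- make_toy_grid(o_nat)
  g_sub <- make_toy_grid(o_sub)
  dyn <- niche_dynamics(g_nat, g_sub)
  expect_equal(dyn$expansion, 0)
  expect_equal(dyn$stability, 1)
  o_dis <- matrix(0, R, R); o_dis[1:2, 1:2] <- 1
  dyn2 <- niche_dynamics(g_nat, make_toy_grid(o_dis))
  expect_equal(dyn2$expansion, 1)
  expect_equal(dyn2$unfilling, 1)
  # centroid shift equals the known displacement of a shifted block
  o_a <- matrix(0, R, R); o_a[2:4, 2:4] <- 1
  o_b <- matrix(0, R, R); o_b[6:8, 2:4] <- 1 # shifted 4 cells along x
  dyn3 <- niche_dynamics(make_toy_grid(o_a), make_toy_grid(o_b))
  step <- diff(make_toy_grid(o_a)$x[1:2])
  expect_equal(dyn3$centroid_shift, c(4 * step, 0), tolerance = 1e-12)
})

test_that("overlap decreases as two niches are pulled apart", {
  bg1 <- pc_cloud(1500, sd = 2, seed = 16)
  bg2 <- pc_cloud(1500, sd = 2, seed = 17)
  d_vals <- vapply(c(0, 1, 2, 3), function(shift) {
    occ1 <- pc_cloud(100, seed = 18)
    occ2 <- pc_cloud(100, mu = c(shift, 0), seed = 19)
    frame <- list(xlim = c(-7, 9), ylim = c(-7, 7))
    schoeners_d(occupancy_grid(occ1, bg1, R = 60, frame = frame),
                occupancy_grid(occ2, bg2, R = 60, frame = frame))
  }, numeric(1))
  expect_true(all(diff(d_vals) < 0))
})

test_that("the high-level contrast wires PCA, grids, D and tests together", {
  set.seed(20)
  mk <- function(n, mu) {
    cbind(t1 = rnorm(n, mu[1], 1), t2 = rnorm(n, mu[2], 1),
          t3 = rnorm(n, 0, 1))
  }
  ov <- niche_overlap(mk(60, c(0, 0)), mk(60, c(1.5, 0)),
                      mk(1200, c(0, 0)) * 2, mk(1200, c(0.5, 0)) * 2,
                      R = 60, reps = 19, seed = 21)
  expect_s3_class(ov, "niche_overlap")
  expect_true(ov$d >= 0 && ov$d <= 1)
  expect_equal(ov$dynamics$stability, 1 - ov$dynamics$expansion)
  expect_length(ov$dynamics$centroid_shift, 2)
  expect_output(print(ov), "Schoener's D")
})
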