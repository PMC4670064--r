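#' PCA of background environments (PCA-env)
#'
#' Correlation-matrix principal component analysis fitted on the pooled
#' backgrounds of the two ranges being contrasted; the first two axes
#' define the environmental space in which occurrence densities are
#' compared. Variables are standardized because they mix units (degrees C,
#' mm, degree-days); constant variables are dropped with a warning.
#'
#' @param bg1,bg2 background environment tables (same columns).
#' @return Object of class `pca_env`: the `prcomp` fit, retained variable
#'   names and explained-variance fractions.
#' @export
pca_env <- function(bg1, bg2) {
  pooled <- rbind(as.matrix(bg1), as.matrix(bg2))
  if (nrow(pooled) < 3L) stop_named("need at least 3 pooled background rows")
  sds <- apply(pooled, 2L, stats::sd)
  if (any(sds == 0)) {
    warn_named("dropping constant variable(s): %s",
               paste(colnames(pooled)[sds == 0], collapse = ", "))
    pooled <- pooled[, sds > 0, drop = FALSE]
  }
  if (ncol(pooled) < 2L) stop_named("need at least 2 varying variables")
  fit <- stats::prcomp(pooled, center = TRUE, scale. = TRUE)
  structure(list(prcomp = fit, vars = colnames(pooled),
                 explained = fit$sdev^2 / sum(fit$sdev^2)),
            class = "pca_env")
}

#' @export
print.pca_env <- function(x, ...) {
  cat(sprintf("pca_env on %d variables; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$vars), 100 * x$explained[1L], 100 * x$explained[2L]))
  invisible(x)
}

#' Project environment data onto the first two PCA-env axes
#'
#' @param pca a [pca_env()] fit.
#' @param env environment table containing the fitted variables.
#' @return Matrix with columns `PC1`, `PC2`.
#' @export
project_pca <- function(pca, env) {
  stopifnot(inherits(pca, "pca_env"))
  scores <- stats::predict(pca$prcomp,
                           as.matrix(env)[, pca$vars, drop = FALSE])
  scores[, 1:2, drop = FALSE]
}

#' Kernel-smoothed occupancy grid in environmental space
#'
#' Gaussian kernel densities of the occurrences (`z_occ`) and of the
#' available background (`z_env`) on a shared `R x R` grid frame spanning
#' the PC1/PC2 plane. The occupancy surface corrects the occurrence
#' density for availability: `o = z_occ / z_env` on cells where the
#' background density is above `env_floor` of its maximum (zero
#' elsewhere), renormalized to sum to 1. The floor protects the density
#' ratio from exploding in the far tails of the availability surface,
#' where both densities underflow at different kernel rates; cells that
#' faint are treated as environment unavailable to the range. Bandwidths default to the bivariate normal
#' reference rule ([MASS::bandwidth.nrd()]) on the occurrence coordinates,
#' falling back to the background's bandwidth when the occurrences are too
#' few or degenerate.
#'
#' @param occ_pc,bg_pc two-column matrices of PC coordinates.
#' @param R grid resolution per axis (default 100).
#' @param frame list with `xlim`, `ylim`; defaults to the joint range of
#'   the inputs expanded by 5 percent.
#' @param bandwidth optional length-2 kernel bandwidth (as in
#'   [MASS::kde2d()]).
#' @param env_floor fraction of the maximum background density below
#'   which cells count as unavailable environment (default `1e-4`).
#' @param env_density optional precomputed background density (the
#'   `kde2d` result for `bg_pc` on this frame), reused across
#'   randomization replicates to avoid recomputing the expensive
#'   background surface.
#' @return Object of class `niche_grid`: grid axes `x`, `y`, matrices
#'   `z_occ`, `z_env`, `occupancy`, the `frame` and `n_occ`.
#' @export
occupancy_grid <- function(occ_pc, bg_pc, R = 100, frame = NULL,
                           bandwidth = NULL, env_floor = 1e-4,
                           env_density = NULL) {
  occ_pc <- as.matrix(occ_pc); bg_pc <- as.matrix(bg_pc)
  if (!nrow(occ_pc)) stop_named("no occurrences to grid")
  frame <- frame %||% default_frame(rbind(occ_pc, bg_pc))
  inside <- occ_pc[, 1L] >= frame$xlim[1L] & occ_pc[, 1L] <= frame$xlim[2L] &
    occ_pc[, 2L] >= frame$ylim[1L] & occ_pc[, 2L] <= frame$ylim[2L]
  if (!any(inside)) stop_named("all occurrences fall outside the grid frame")
  h_env <- kde_bandwidth(bg_pc)
  h_occ <- bandwidth %||% kde_bandwidth(occ_pc, fallback = h_env)
  z_occ <- MASS::kde2d(occ_pc[inside, 1L], occ_pc[inside, 2L], h = h_occ,
                       n = R, lims = c(frame$xlim, frame$ylim))
  z_env <- env_density %||% MASS::kde2d(bg_pc[, 1L], bg_pc[, 2L], h = h_env,
                                        n = R, lims = c(frame$xlim, frame$ylim))
  occ_d <- z_occ$z / sum(z_occ$z)
  env_d <- z_env$z / sum(z_env$z)
  valid <- env_d > env_floor * max(env_d)
  o <- ifelse(valid, occ_d / pmax(env_d, .Machine$double.xmin), 0)
  if (sum(o) <= 0) stop_named("no occupancy mass on available environment")
  o <- o / sum(o)
  structure(list(x = z_occ$x, y = z_occ$y, z_occ = occ_d, z_env = env_d,
                 occupancy = o, frame = frame, n_occ = sum(inside),
                 env_floor = env_floor,
                 bandwidth_occ = h_occ, bandwidth_env = h_env),
            class = "niche_grid")
}

default_frame <- function(pc, margin = 0.05) {
  xr <- range(pc[, 1L]); yr <- range(pc[, 2L])
  list(xlim = xr + c(-1, 1) * margin * diff(xr),
       ylim = yr + c(-1, 1) * margin * diff(yr))
}

env_kde <- function(bg_pc, R, frame) {
  MASS::kde2d(bg_pc[, 1L], bg_pc[, 2L], h = kde_bandwidth(bg_pc), n = R,
              lims = c(frame$xlim, frame$ylim))
}

kde_bandwidth <- function(pc, fallback = NULL) {
  h <- tryCatch(c(MASS::bandwidth.nrd(pc[, 1L]), MASS::bandwidth.nrd(pc[, 2L])),
                error = function(e) c(0, 0))
  if (any(!is.finite(h)) || any(h <= 0)) {
    if (is.null(fallback)) stop_named("cannot select a kernel bandwidth")
    h <- fallback
  }
  h
}

same_frame <- function(a, b, tol = 1e-9) {
  all(abs(unlist(a$frame) - unlist(b$frame)) < tol) &&
    length(a$x) == length(b$x)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|o1 - o2|)` between two normalized occupancy
#' surfaces; 0 means disjoint niches, 1 identical niches. D is symmetric
#' and invariant to any permutation of cells applied to both surfaces.
#'
#' @param o1,o2 [occupancy_grid()] objects sharing one grid frame, or
#'   non-negative numeric vectors/matrices (normalized internally).
#' @return D in `[0, 1]`.
#' @export
schoeners_d <- function(o1, o2) {
  if (inherits(o1, "niche_grid") && inherits(o2, "niche_grid")) {
    if (!same_frame(o1, o2)) stop_named("occupancy grids use different frames")
    o1 <- o1$occupancy; o2 <- o2$occupancy
  }
  o1 <- as.vector(o1); o2 <- as.vector(o2)
  if (length(o1) != length(o2)) stop_named("surfaces differ in length")
  if (any(o1 < 0) || any(o2 < 0) || sum(o1) <= 0 || sum(o2) <= 0) {
    stop_named("occupancy surfaces must be non-negative with positive mass")
  }
  o1 <- o1 / sum(o1); o2 <- o2 / sum(o2)
  1 - 0.5 * sum(abs(o1 - o2))
}

#' Niche equivalency randomization test
#'
#' Are the two ranges' occurrence niches interchangeable? The pooled
#' occurrences are randomly reassigned into two groups of the original
#' sizes, occupancy grids are rebuilt against each range's own background,
#' and Schoener's D is recomputed `reps` times.
#' `p_lower = (#\{D_null <= D_obs\} + 1)/(reps + 1)` asks whether the
#' observed overlap is lower than expected by chance (niche difference);
#' `p_upper` is the opposite tail.
#'
#' @param occ1_pc,occ2_pc occurrence PC coordinates (at least 2 rows each).
#' @param bg1_pc,bg2_pc background PC coordinates of the two ranges.
#' @param R grid resolution.
#' @param frame shared grid frame; defaults to the joint range of all
#'   inputs.
#' @param reps randomizations (default 100).
#' @param seed integer seed.
#' @return List: `d_obs`, `p_lower`, `p_upper`, `null` (the D
#'   distribution), `reps`.
#' @export
niche_equivalency_test <- function(occ1_pc, occ2_pc, bg1_pc, bg2_pc,
                                   R = 100, frame = NULL, reps = 100,
                                   seed = 1L) {
  stopifnot(reps >= 1L)
  occ1_pc <- as.matrix(occ1_pc); occ2_pc <- as.matrix(occ2_pc)
  n1 <- nrow(occ1_pc); n2 <- nrow(occ2_pc)
  if (n1 < 2L || n2 < 2L) stop_named("each group needs at least 2 occurrences")
  frame <- frame %||% default_frame(rbind(occ1_pc, occ2_pc, bg1_pc, bg2_pc))
  e1 <- env_kde(bg1_pc, R, frame)
  e2 <- env_kde(bg2_pc, R, frame)
  g1 <- occupancy_grid(occ1_pc, bg1_pc, R = R, frame = frame,
                       env_density = e1)
  g2 <- occupancy_grid(occ2_pc, bg2_pc, R = R, frame = frame,
                       env_density = e2)
  d_obs <- schoeners_d(g1, g2)
  pooled <- rbind(occ1_pc, occ2_pc)
  null <- with_seed(seed, vapply(seq_len(reps), function(r) {
    idx <- sample.int(n1 + n2, n1)
    gg1 <- occupancy_grid(pooled[idx, , drop = FALSE], bg1_pc, R = R,
                          frame = frame, env_density = e1)
    gg2 <- occupancy_grid(pooled[-idx, , drop = FALSE], bg2_pc, R = R,
                          frame = frame, env_density = e2)
    schoeners_d(gg1, gg2)
  }, numeric(1L)))
  list(d_obs = d_obs,
       p_lower = (sum(null <= d_obs) + 1) / (reps + 1),
       p_upper = (sum(null >= d_obs) + 1) / (reps + 1),
       null = null, reps = reps)
}

#' Niche similarity randomization test
#'
#' Is the overlap higher (or lower) than expected given the available
#' environments? Per randomization the second range's occurrence cloud is
#' rigidly translated so that its centroid lands on a random cell of the
#' second range's background support, the occupancy grid is rebuilt, and D
#' recomputed. Tails as in [niche_equivalency_test()].
#'
#' @inheritParams niche_equivalency_test
#' @return List: `d_obs`, `p_lower`, `p_upper`, `null`, `reps`.
#' @export
niche_similarity_test <- function(occ1_pc, occ2_pc, bg1_pc, bg2_pc,
                                  R = 100, frame = NULL, reps = 100,
                                  seed = 1L) {
  stopifnot(reps >= 1L)
  occ1_pc <- as.matrix(occ1_pc); occ2_pc <- as.matrix(occ2_pc)
  if (nrow(occ1_pc) < 2L || nrow(occ2_pc) < 2L) {
    stop_named("each group needs at least 2 occurrences")
  }
  frame <- frame %||% default_frame(rbind(occ1_pc, occ2_pc, bg1_pc, bg2_pc))
  e1 <- env_kde(bg1_pc, R, frame)
  e2 <- env_kde(bg2_pc, R, frame)
  g1 <- occupancy_grid(occ1_pc, bg1_pc, R = R, frame = frame,
                       env_density = e1)
  g2 <- occupancy_grid(occ2_pc, bg2_pc, R = R, frame = frame,
                       env_density = e2)
  d_obs <- schoeners_d(g1, g2)
  support <- which(g2$z_env > g2$env_floor * max(g2$z_env), arr.ind = TRUE)
  centroid <- colMeans(occ2_pc)
  null <- with_seed(seed, vapply(seq_len(reps), function(r) {
    cell <- support[sample.int(nrow(support), 1L), ]
    target <- c(g2$x[cell[1L]], g2$y[cell[2L]])
    shifted <- sweep(occ2_pc, 2L, target - centroid, `+`)
    # clamp the translated cloud into the frame so the density stays put
    shifted[, 1L] <- pmin(pmax(shifted[, 1L], g2$frame$xlim[1L]),
                          g2$frame$xlim[2L])
    shifted[, 2L] <- pmin(pmax(shifted[, 2L], g2$frame$ylim[1L]),
                          g2$frame$ylim[2L])
    gg2 <- occupancy_grid(shifted, bg2_pc, R = R, frame = g2$frame,
                          env_density = e2)
    schoeners_d(g1, gg2)
  }, numeric(1L)))
  list(d_obs = d_obs,
       p_lower = (sum(null <= d_obs) + 1) / (reps + 1),
       p_upper = (sum(null >= d_obs) + 1) / (reps + 1),
       null = null, reps = reps)
}

#' Niche dynamics indices and centroid shift
#'
#' Decomposes the invasive niche relative to the native one within the
#' analogue climate (cells available in both backgrounds). A niche is
#' considered present on the smallest set of highest-occupancy cells
#' holding 95 percent of its occupancy mass, and absent elsewhere: with
#' kernel-smoothed surfaces (positive everywhere) a value-based zero
#' threshold would never trigger, so the absence rule is mass-based.
#' \itemize{
#'   \item expansion: invasive occupancy mass on analogue cells where the
#'     native niche is absent (fraction of the invasive analogue mass);
#'   \item stability: `1 - expansion`;
#'   \item unfilling: native occupancy mass on analogue cells where the
#'     invasive niche is absent;
#'   \item centroid_shift: occupancy-weighted mean PC position of the
#'     invasive minus the native niche.
#' }
#'
#' @param grid_native,grid_invasive [occupancy_grid()] objects on one
#'   frame.
#' @return List with `expansion`, `stability`, `unfilling`,
#'   `centroid_shift` (length-2 vector in PC units).
#' @export
niche_dynamics <- function(grid_native, grid_invasive) {
  stopifnot(inherits(grid_native, "niche_grid"),
            inherits(grid_invasive, "niche_grid"))
  if (!same_frame(grid_native, grid_invasive)) {
    stop_named("occupancy grids use different frames")
  }
  o1 <- grid_native$occupancy; o2 <- grid_invasive$occupancy
  analogue <- grid_native$z_env > grid_native$env_floor * max(grid_native$z_env) &
    grid_invasive$z_env > grid_invasive$env_floor * max(grid_invasive$z_env)
  presence_mask <- function(o, mass = 0.95) {
    if (sum(o) <= 0) return(o > 0)
    v <- sort(o[o > 0], decreasing = TRUE)
    cutoff <- v[which(cumsum(v) >= mass * sum(o))[1L]]
    o >= cutoff
  }
  pres1 <- presence_mask(o1)
  pres2 <- presence_mask(o2)
  m2 <- sum(o2[analogue]); m1 <- sum(o1[analogue])
  expansion <- if (m2 > 0) sum(o2[analogue & !pres1]) / m2 else 0
  unfilling <- if (m1 > 0) sum(o1[analogue & !pres2]) / m1 else 0
  cx <- outer(grid_native$x, rep(1, length(grid_native$y)))
  cy <- outer(rep(1, length(grid_native$x)), grid_native$y)
  centroid <- function(o) c(sum(o * cx), sum(o * cy)) / sum(o)
  list(expansion = expansion, stability = 1 - expansion,
       unfilling = unfilling,
       centroid_shift = centroid(o2) - centroid(o1))
}

#' Niche overlap analysis between two ranges
#'
#' High-level PCA-env contrast: fits the PCA on the pooled backgrounds of
#' the two ranges, projects occurrences and backgrounds, builds occupancy
#' grids on one shared frame, and returns Schoener's D with equivalency
#' and similarity randomization tests and the niche-dynamics indices.
#'
#' @param occ1,occ2 occurrence environment tables of the two ranges (raw
#'   variables).
#' @param bg1,bg2 background environment tables of the two ranges.
#' @param R grid resolution (default 100).
#' @param reps randomizations per test (default 100).
#' @param tests which randomization tests to run.
#' @param seed integer seed.
#' @return Object of class `niche_overlap`: `d`, `equivalency`,
#'   `similarity`, `dynamics`, the `pca`, both grids and the seed.
#' @export
niche_overlap <- function(occ1, occ2, bg1, bg2, R = 100, reps = 100,
                          tests = c("equivalency", "similarity"),
                          seed = 1L) {
  tests <- match.arg(tests, several.ok = TRUE)
  pca <- pca_env(bg1, bg2)
  p_occ1 <- project_pca(pca, occ1); p_occ2 <- project_pca(pca, occ2)
  p_bg1 <- project_pca(pca, bg1); p_bg2 <- project_pca(pca, bg2)
  frame <- default_frame(rbind(p_occ1, p_occ2, p_bg1, p_bg2))
  g1 <- occupancy_grid(p_occ1, p_bg1, R = R, frame = frame)
  g2 <- occupancy_grid(p_occ2, p_bg2, R = R, frame = frame)
  res <- list(d = schoeners_d(g1, g2), pca = pca, grid1 = g1, grid2 = g2,
              dynamics = niche_dynamics(g1, g2), reps = reps, seed = seed)
  if ("equivalency" %in% tests) {
    res$equivalency <- niche_equivalency_test(p_occ1, p_occ2, p_bg1, p_bg2,
                                              R = R, frame = frame,
                                              reps = reps,
                                              seed = derive_seed(seed, "eq"))
  }
  if ("similarity" %in% tests) {
    res$similarity <- niche_similarity_test(p_occ1, p_occ2, p_bg1, p_bg2,
                                            R = R, frame = frame,
                                            reps = reps,
                                            seed = derive_seed(seed, "sim"))
  }
  class(res) <- "niche_overlap"
  res
}

#' @export
print.niche_overlap <- function(x, ...) {
  cat("PCA-env niche overlap\n")
  cat(sprintf("  Schoener's D = %.3f\n", x$d))
  if (!is.null(x$equivalency)) {
    cat(sprintf("  equivalency test:  p(lower) = %.3f, p(higher) = %.3f (%d reps)\n",
                x$equivalency$p_lower, x$equivalency$p_upper,
                x$equivalency$reps))
  }
  if (!is.null(x$similarity)) {
    cat(sprintf("  similarity test:   p(lower) = %.3f, p(higher) = %.3f (%d reps)\n",
                x$similarity$p_lower, x$similarity$p_upper, x$similarity$reps))
  }
  dyn <- x$dynamics
  cat(sprintf("  expansion = %.3f, stability = %.3f, unfilling = %.3f\n",
              dyn$expansion, dyn$stability, dyn$unfilling))
  cat(sprintf("  centroid shift = (%.2f, %.2f) PC units\n",
              dyn$centroid_shift[1L], dyn$centroid_shift[2L]))
  invisible(x)
}

#' Plot a niche-overlap contrast
#'
#' Two occupancy density surfaces in PC space with contour lines at 100
#' percent and 50 percent of the available background environment for each
#' range, and the occupancy centroids joined by an arrow showing the niche
#' shift.
#'
#' @param x a [niche_overlap()] result.
#' @param cols fill colors for the two ranges.
#' @param ... unused.
#' @export
plot.niche_overlap <- function(x, cols = c("#1b7837", "#b2182b"), ...) {
  g1 <- x$grid1; g2 <- x$grid2
  graphics::plot(NA, xlim = g1$frame$xlim, ylim = g1$frame$ylim,
                 xlab = sprintf("PC1 (%.0f%%)", 100 * x$pca$explained[1L]),
                 ylab = sprintf("PC2 (%.0f%%)", 100 * x$pca$explained[2L]))
  shade <- function(g, col) {
    z <- g$occupancy / max(g$occupancy)
    graphics::image(g$x, g$y, z, add = TRUE,
                    col = grDevices::adjustcolor(
                      grDevices::colorRampPalette(c("white", col))(32),
                      alpha.f = 0.5),
                    useRaster = TRUE)
  }
  shade(g1, cols[1L]); shade(g2, cols[2L])
  env_contours <- function(g, col) {
    z <- g$z_env
    graphics::contour(g$x, g$y, z, levels = g$env_floor * max(z),
                      drawlabels = FALSE, add = TRUE, col = col, lty = 1)
    graphics::contour(g$x, g$y, z, levels = stats::quantile(z[z > 0], 0.5),
                      drawlabels = FALSE, add = TRUE, col = col, lty = 2)
  }
  env_contours(g1, cols[1L]); env_contours(g2, cols[2L])
  cx <- function(g) {
    o <- g$occupancy
    c(sum(o * outer(g$x, rep(1, length(g$y)))),
      sum(o * outer(rep(1, length(g$x)), g$y))) / sum(o)
  }
  c1 <- cx(g1); c2 <- cx(g2)
  graphics::arrows(c1[1L], c1[2L], c2[1L], c2[2L], col = "red", lwd = 2,
                   length = 0.1)
  invisible(x)
}
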