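# shared fixture builders and independent oracles, all generated in code

# monthly climate where every month is constant over a small grid;
# per-month values may be vectors of length 12
make_constant_monthly <- function(tmin = 15, tmax = 25, prec = 100,
                                  tmean = NULL, nr = 3, nc = 4) {
  expand12 <- function(v) if (length(v) == 1L) rep(v, 12L) else v
  tmin <- expand12(tmin); tmax <- expand12(tmax); prec <- expand12(prec)
  arr <- function(v) {
    a <- array(NA_real_, c(nr, nc, 12L))
    for (m in 1:12) a[, , m] <- v[m]
    a
  }
  tmean_arr <- if (is.null(tmean)) NULL else arr(expand12(tmean))
  monthly_climate(arr(tmin), arr(tmax), tmean_arr, arr(prec),
                  template = raster_grid(matrix(0, nr, nc)))
}

# random but valid monthly climate over n cells (1 x n grid)
make_random_monthly <- function(n = 100, seed = 1) {
  set.seed(seed)
  tmean <- array(rnorm(n * 12, 15, 8), c(1L, n, 12L))
  half_range <- array(runif(n * 12, 0.5, 6), c(1L, n, 12L))
  prec <- array(rexp(n * 12, 1 / 80), c(1L, n, 12L))
  monthly_climate(tmean - half_range, tmean + half_range, tmean, prec,
                  template = raster_grid(matrix(0, 1L, n)))
}

# independent scalar oracle for the bioclim variables of one cell: plain
# loops and stats on the 12 monthly values, no shared code with the
# package implementation
oracle_bioclim_cell <- function(tmin, tmax, tmean, prec) {
  stopifnot(length(tmin) == 12)
  windows <- lapply(1:12, function(s) ((s - 1):(s + 1)) %% 12 + 1)
  psum <- sapply(windows, function(w) sum(prec[w]))
  tqm <- sapply(windows, function(w) mean(tmean[w]))
  wet <- which.max(psum); dry <- which.min(psum)
  warm <- which.max(tqm); cold <- which.min(tqm)
  b <- numeric(19)
  b[1] <- mean(tmean)
  b[2] <- mean(tmax - tmin)
  b[4] <- sd(tmean) * 100
  b[5] <- max(tmax); b[6] <- min(tmin); b[7] <- b[5] - b[6]
  b[3] <- if (b[7] == 0) 0 else b[2] / b[7] * 100
  b[8] <- tqm[wet]; b[9] <- tqm[dry]; b[10] <- tqm[warm]; b[11] <- tqm[cold]
  b[12] <- sum(prec); b[13] <- max(prec); b[14] <- min(prec)
  b[15] <- 100 * sd(prec) / (1 + b[12] / 12)
  b[16] <- psum[wet]; b[17] <- psum[dry]; b[18] <- psum[warm]
  b[19] <- psum[cold]
  names(b) <- paste0("bio", 1:19)
  b
}

oracle_degree_days_cell <- function(tmean, base = 10) {
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  sum(days * pmax(tmean - base, 0))
}

# brute-force 1-d grid search oracle over the penalized maxent likelihood
# for a single feature; independent of the package optimizer
oracle_maxent_1d <- function(f_pres, f_bg, beta, s, w = NULL,
                             lims = c(-20, 20), step = 1e-4) {
  w <- if (is.null(w)) rep(1 / length(f_bg), length(f_bg)) else w / sum(w)
  obj <- function(l) {
    mean(f_pres * l) - log(sum(w * exp(f_bg * l))) - beta * s * abs(l)
  }
  grid <- seq(lims[1], lims[2], by = step)
  vals <- vapply(grid, obj, numeric(1))
  grid[which.max(vals)]
}

# tiny hand-built occupancy grids for the dynamics identities
make_toy_grid <- function(occupancy, z_env = NULL, x = NULL, y = NULL) {
  R <- nrow(occupancy)
  x <- x %||% seq(0, 1, length.out = R)
  y <- y %||% seq(0, 1, length.out = ncol(occupancy))
  z_env <- z_env %||% matrix(1 / length(occupancy), R, ncol(occupancy))
  structure(list(x = x, y = y, z_occ = occupancy / sum(occupancy),
                 z_env = z_env / sum(z_env),
                 occupancy = occupancy / sum(occupancy),
                 frame = list(xlim = range(x), ylim = range(y)),
                 n_occ = 1L, env_floor = 1e-4,
                 bandwidth_occ = c(1, 1), bandwidth_env = c(1, 1)),
            class = "niche_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simple occurrence table builder
make_occ_df <- function(lon, lat, label = "native") {
  data.frame(id = sprintf("r%03d", seq_along(lon)), longitude = lon,
             latitude = lat, range_label = rep_len(label, length(lon)),
             source = rep_len("test", length(lon)),
             stringsAsFactors = FALSE)
}

# Moran's I with rook neighbours on a matrix (for smoothness checks)
morans_i <- function(m) {
  z <- m - mean(m)
  num <- sum(z[-1, ] * z[-nrow(m), ]) + sum(z[, -1] * z[, -ncol(m)])
  w <- (nrow(m) - 1) * ncol(m) + nrow(m) * (ncol(m) - 1)
  (length(m) / w) * (num / sum(z^2))
}
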