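#' Virtual-species study configuration
#'
#' Parameters of the synthetic invasion study: paired native and invaded
#' landscapes with smooth correlated monthly climate, a known logistic-
#' quadratic suitability function, a controllable niche shift between
#' ranges, and optionally spatially biased sampling. All randomness flows
#' from `seed`.
#'
#' The niche is defined on `names(optimum)` (bioclim-layer names). The
#' invaded-range optimum equals the native optimum plus a shift of
#' `delta_sd` native-background standard deviations along the unit
#' direction `delta_dir`; the configured `optimum` is the midpoint of the
#' two, so both optima sit symmetrically inside the available climate. A
#' second invaded range uses `delta2_sd` along `delta2_dir` (defaults:
#' 1.5 times the first shift, same direction, mirroring a stronger shift
#' outside the focal invaded region).
#'
#' @param nrow,ncol landscape size in cells (default 200 x 200; at least
#'   10 x 10).
#' @param cellsize cell size in degrees (default 0.01, about 1 km).
#' @param smoothness spatial smoothness of the climate fields in (0, 1];
#'   higher is smoother (default 0.7).
#' @param seasonal_amplitude seasonal temperature half-range, degrees C.
#' @param optimum named vector of niche optima in variable units.
#' @param breadth named vector of niche breadths (same variables).
#' @param plateau logistic plateau parameter `a` of the suitability
#'   `1/(1 + exp(-(a - sum(((x - mu)/sigma)^2))))`.
#' @param delta_sd,delta_dir niche-shift magnitude (native-background SD
#'   units) and direction for the first invaded range.
#' @param delta2_sd,delta2_dir shift for the second invaded range.
#' @param n_presences occurrence records sampled per range (default 250).
#' @param bias_strength sampling-bias intensity (0 = unbiased).
#' @param seed master integer seed.
#' @return Object of class `virtual_species_config`.
#' @export
virtual_species_config <- function(nrow = 200, ncol = 200, cellsize = 0.01,
                                   smoothness = 0.7, seasonal_amplitude = 8,
                                   optimum = c(bio1 = 20, bio12 = 1200),
                                   breadth = c(bio1 = 2, bio12 = 300),
                                   plateau = 4,
                                   delta_sd = 0, delta_dir = NULL,
                                   delta2_sd = NULL, delta2_dir = NULL,
                                   n_presences = 250, bias_strength = 0,
                                   seed = 1L) {
  if (nrow < 10 || ncol < 10) stop_named("landscape must be at least 10 x 10")
  stopifnot(all(breadth > 0), n_presences >= 1,
            identical(names(optimum), names(breadth)))
  dir <- delta_dir %||% c(1, rep(0, length(optimum) - 1L))
  dir <- dir / sqrt(sum(dir^2))
  dir2 <- delta2_dir %||% dir
  dir2 <- dir2 / sqrt(sum(dir2^2))
  structure(list(nrow = nrow, ncol = ncol, cellsize = cellsize,
                 smoothness = smoothness,
                 seasonal_amplitude = seasonal_amplitude,
                 optimum = optimum, breadth = breadth, plateau = plateau,
                 delta_sd = delta_sd, delta_dir = dir,
                 delta2_sd = delta2_sd %||% (1.5 * delta_sd),
                 delta2_dir = dir2,
                 n_presences = n_presences, bias_strength = bias_strength,
                 seed = as.integer(seed)),
            class = "virtual_species_config")
}

# band-limited random field: seeded superposition of sinusoids,
# standardized to mean 0 / sd 1 over the landscape. Smoother fields use
# lower maximum spatial frequency.
smooth_field <- function(nr, nc, smoothness, seed, n_harmonics = 14L) {
  with_seed(seed, {
    fmax <- 1 + 7 * (1 - smoothness)
    x <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
    y <- matrix(rep(seq_len(nr) / nr, nc), nr, nc)
    f <- matrix(0, nr, nc)
    for (k in seq_len(n_harmonics)) {
      fr <- stats::runif(1L, 0.4, fmax)
      th <- stats::runif(1L, 0, 2 * pi)
      ph <- stats::runif(1L, 0, 2 * pi)
      amp <- stats::rnorm(1L, 0, 1) / sqrt(fr)
      f <- f + amp * sin(2 * pi * fr * (cos(th) * x + sin(th) * y) + ph)
    }
    (f - mean(f)) / stats::sd(f)
  })
}

#' Generate one synthetic landscape of monthly climate
#'
#' Builds smooth correlated monthly climate from four seeded latent
#' fields: thermal level (annual mean temperature), continentality
#' (diurnal range and seasonal amplitude), precipitation level, and
#' precipitation seasonality. The monthly cycle peaks in July for
#' temperature; `tmin <= tmean <= tmax` holds by construction. Also
#' returns an all-accessible mask and the latent fields (including the
#' sampling-bias field).
#'
#' @param config a [virtual_species_config()].
#' @param tag landscape tag entering the derived seed (e.g. the range
#'   name), so native and invaded landscapes differ but are reproducible.
#' @param origin lon/lat of the lower-left corner.
#' @return List: `monthly` ([monthly_climate()]), `mask` (raster of 1s),
#'   `fields` (latent fields), `bias_field`.
#' @export
generate_landscape <- function(config, tag = "native", origin = c(-60, -30)) {
  stopifnot(inherits(config, "virtual_species_config"))
  nr <- config$nrow; nc <- config$ncol
  fld <- lapply(1:5, function(i) {
    smooth_field(nr, nc, config$smoothness,
                 derive_seed(config$seed, paste0("field", i, "_", tag)))
  })
  names(fld) <- c("thermal", "continental", "pluvial", "prec_season", "bias")
  tann <- 20 + 5 * fld$thermal
  amp <- pmax(config$seasonal_amplitude * (1 + 0.25 * fld$continental), 1)
  diurnal <- pmax(9 + 2.5 * fld$continental, 2)
  pann <- 1100 * exp(0.45 * fld$pluvial)
  psea <- pmin(pmax(0.5 + 0.35 * fld$prec_season, 0), 0.95)
  tmean <- array(NA_real_, c(nr, nc, 12L))
  tmin <- tmean; tmax <- tmean; prec <- tmean
  for (m in 1:12) {
    cyc <- cos(2 * pi * (m - 7) / 12)
    tmean[, , m] <- tann + amp * cyc
    tmin[, , m] <- tmean[, , m] - diurnal / 2
    tmax[, , m] <- tmean[, , m] + diurnal / 2
    prec[, , m] <- pann / 12 * (1 + psea * cos(2 * pi * (m - 1) / 12))
  }
  tmpl <- raster_grid(matrix(0, nr, nc), xmin = origin[1L], ymin = origin[2L],
                      cellsize = config$cellsize)
  monthly <- monthly_climate(tmin, tmax, tmean, prec, template = tmpl)
  mask <- raster_grid(matrix(1, nr, nc), xmin = origin[1L], ymin = origin[2L],
                      cellsize = config$cellsize)
  list(monthly = monthly, mask = mask, fields = fld[1:4],
       bias_field = fld$bias)
}

#' True suitability surface of the virtual species
#'
#' Logistic of a negative quadratic form around the niche optimum:
#' `s = 1/(1 + exp(-(a - sum_v ((x_v - mu_v)/sigma_v)^2)))`, symmetric in
#' the scaled distance from the optimum and maximal at the optimum.
#'
#' @param stack [raster_stack()] containing the niche variables.
#' @param optimum,breadth named vectors (`mu`, `sigma` per variable).
#' @param plateau logistic plateau parameter `a`.
#' @return A [raster_grid()] of suitability in (0, 1).
#' @export
true_suitability <- function(stack, optimum, breadth, plateau = 4) {
  miss <- setdiff(names(optimum), names(stack))
  if (length(miss)) {
    stop_named("stack missing niche variable(s): %s",
               paste(miss, collapse = ", "))
  }
  qform <- 0
  for (v in names(optimum)) {
    qform <- qform + ((stack[[v]]$values - optimum[[v]]) / breadth[[v]])^2
  }
  out <- stack[[1L]]
  out$values <- stats::plogis(plateau - qform)
  out
}

#' Sample presence records from a suitability surface
#'
#' Cells are drawn with replacement with probability proportional to
#' `suitability * bias` (bias optional) and records are jittered uniformly
#' within their cell. Deterministic given the seed.
#'
#' @param suitability a [raster_grid()] in `[0, 1]`.
#' @param n number of records.
#' @param bias optional aligned [raster_grid()] of sampling weights.
#' @param seed integer seed.
#' @param range_label label attached to the records.
#' @param id_prefix prefix of the generated record ids.
#' @return An [occurrence_set()].
#' @export
sample_presences <- function(suitability, n, bias = NULL, seed = 1L,
                             range_label = "native",
                             id_prefix = range_label) {
  stopifnot(is_raster_grid(suitability), n >= 1)
  w <- as.vector(suitability$values)
  if (!is.null(bias)) {
    if (!same_geometry(bias, suitability)) {
      stop_named("bias raster does not align with the suitability raster")
    }
    w <- w * as.vector(bias$values)
  }
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop_named("suitability (x bias) is zero everywhere")
  cells <- with_seed(seed, sample.int(length(w), n, replace = TRUE, prob = w))
  xy <- xy_from_cell(suitability, cells)
  jit <- with_seed(derive_seed(seed, "jitter"), {
    matrix(stats::runif(2L * n, -0.5, 0.5), ncol = 2L)
  })
  occurrence_set(data.frame(
    id = sprintf("%s_%05d", id_prefix, seq_len(n)),
    longitude = xy$x + jit[, 1L] * suitability$cellsize,
    latitude = xy$y + jit[, 2L] * suitability$cellsize,
    range_label = range_label,
    source = "synthetic", stringsAsFactors = FALSE))
}

#' Generate a complete synthetic invasion study
#'
#' The full fixture: a native landscape and two invaded landscapes
#' (emulating a focal invaded region and a second, further-shifted invaded
#' region), each with monthly climate, the 20 derived climate predictors,
#' an accessible-area mask, the true suitability surface, and sampled
#' occurrences. The invaded-range niche optima equal the native optimum
#' plus the configured shift, expressed in native-background standard
#' deviations of the niche variables. The truth record retains everything
#' needed to score recovery of downstream estimates.
#'
#' @param config a [virtual_species_config()].
#' @return Object of class `synthetic_study`: `config`, per-range lists
#'   (`monthly`, `predictors`, `mask`, `suitability`, `occurrences`,
#'   `bias`) under `ranges`, and `truth` (`optima`, `shift_vars`,
#'   `native_sd`, `delta_sd`, `delta2_sd`).
#' @export
generate_invasion_study <- function(config = virtual_species_config()) {
  stopifnot(inherits(config, "virtual_species_config"))
  origins <- list(native = c(-60, -30), invasive_conus = c(-95, 28),
                  invasive_nonconus = c(-75, 5))
  nat <- generate_landscape(config, "native", origins$native)
  nat_pred <- climate_predictors(nat$monthly)
  nv <- names(config$optimum)
  nat_tab <- stack_table(nat_pred)[, nv, drop = FALSE]
  nat_sd <- apply(nat_tab, 2L, stats::sd)
  shift1 <- config$delta_sd * config$delta_dir * nat_sd
  shift2 <- config$delta2_sd * config$delta2_dir * nat_sd
  # the configured optimum is the midpoint of the native/invaded optima, so
  # both sit symmetrically inside the available climate; the invaded-range
  # optimum still equals the native optimum plus the configured shift
  optima <- list(native = config$optimum - shift1 / 2,
                 invasive_conus = config$optimum + shift1 / 2,
                 invasive_nonconus = config$optimum - shift1 / 2 + shift2)
  build_range <- function(range) {
    land <- if (range == "native") nat else
      generate_landscape(config, range, origins[[range]])
    pred <- if (range == "native") nat_pred else climate_predictors(land$monthly)
    suit <- true_suitability(pred, optima[[range]], config$breadth,
                             config$plateau)
    bias <- NULL
    if (config$bias_strength > 0) {
      bias <- land$mask
      bias$values <- exp(config$bias_strength * land$bias_field)
      bias$values <- bias$values / max(bias$values)
    }
    occ <- sample_presences(suit, config$n_presences, bias = bias,
                            seed = derive_seed(config$seed,
                                               paste0("occ_", range)),
                            range_label = range)
    list(monthly = land$monthly, predictors = pred, mask = land$mask,
         suitability = suit, occurrences = occ, bias = bias)
  }
  ranges <- lapply(stats::setNames(nm = range_labels()), build_range)
  structure(list(config = config, ranges = ranges,
                 truth = list(optima = optima,
                              shift_vars = list(invasive_conus = shift1,
                                                invasive_nonconus = shift2),
                              native_sd = nat_sd,
                              delta_sd = config$delta_sd,
                              delta2_sd = config$delta2_sd)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("synthetic_study: %d x %d cells, %d presences/range, seed %d\n",
              cfg$nrow, cfg$ncol, cfg$n_presences, cfg$seed))
  cat(sprintf("  niche on %s; shift %.2g SD (second range %.2g SD)\n",
              paste(names(cfg$optimum), collapse = ", "), cfg$delta_sd,
              cfg$delta2_sd))
  invisible(x)
}
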