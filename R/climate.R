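#' Monthly climate container
#'
#' Holds twelve monthly layers each of minimum, maximum and mean
#' temperature (degrees C) and precipitation (mm), all on one shared grid.
#' `tmean` defaults to the midpoint of `tmin` and `tmax`. The constructor
#' enforces `tmin <= tmean <= tmax` cellwise and a consistent nodata mask.
#'
#' @param tmin,tmax,tmean,prec either lists of 12 [raster_grid()] layers or
#'   three-dimensional arrays (rows x cols x 12).
#' @param template a [raster_grid()] supplying the geometry when arrays are
#'   passed; ignored when lists of grids are given.
#' @return Object of class `monthly_climate`: arrays `tmin`, `tmax`,
#'   `tmean`, `prec` plus the geometry `template`.
#' @export
monthly_climate <- function(tmin, tmax, tmean = NULL, prec, template = NULL) {
  to_array <- function(x, what) {
    if (is.array(x) && length(dim(x)) == 3L) {
      if (dim(x)[3L] != 12L) stop_named("%s must have 12 monthly layers", what)
      return(x)
    }
    if (is.list(x)) {
      if (length(x) != 12L) {
        miss <- setdiff(1:12, seq_along(x))
        stop_named("%s missing month(s): %s", what,
                   paste(miss, collapse = ", "))
      }
      if (is.null(template)) template <<- x[[1L]]
      for (m in 1:12) {
        if (!same_geometry(x[[m]], template)) {
          stop_named("%s month %d does not share the grid geometry", what, m)
        }
      }
      a <- array(NA_real_, c(dim(template$values), 12L))
      for (m in 1:12) a[, , m] <- x[[m]]$values
      return(a)
    }
    stop_named("%s must be a 3-d array or a list of 12 raster_grid layers",
               what)
  }
  tmin <- to_array(tmin, "tmin")
  tmax <- to_array(tmax, "tmax")
  prec <- to_array(prec, "prec")
  if (is.null(tmean)) tmean <- (tmin + tmax) / 2 else
    tmean <- to_array(tmean, "tmean")
  if (is.null(template)) template <- raster_grid(tmin[, , 1L])
  d <- dim(tmin)
  if (!all(dim(tmax) == d, dim(tmean) == d, dim(prec) == d)) {
    stop_named("monthly climate elements must share dimensions")
  }
  bad <- which(tmin > tmean + 1e-9 | tmean > tmax + 1e-9)
  if (length(bad)) {
    stop_named("tmin <= tmean <= tmax violated at %d cell-months", length(bad))
  }
  # unify nodata mask across elements and months
  mask <- is.na(tmin[, , 1L])
  for (m in 1:12) {
    mask <- mask | is.na(tmin[, , m]) | is.na(tmax[, , m]) |
      is.na(tmean[, , m]) | is.na(prec[, , m])
  }
  if (any(mask)) {
    for (m in 1:12) {
      tmin[, , m][mask] <- NA; tmax[, , m][mask] <- NA
      tmean[, , m][mask] <- NA; prec[, , m][mask] <- NA
    }
  }
  structure(list(tmin = tmin, tmax = tmax, tmean = tmean, prec = prec,
                 template = template),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  d <- dim(x$tmin)
  cat(sprintf("monthly_climate: %d x %d cells, 12 months\n", d[1L], d[2L]))
  cat(sprintf("  annual tmean %.1f..%.1f degC, annual prec %.0f..%.0f mm\n",
              min(apply(x$tmean, c(1, 2), mean), na.rm = TRUE),
              max(apply(x$tmean, c(1, 2), mean), na.rm = TRUE),
              min(apply(x$prec, c(1, 2), sum), na.rm = TRUE),
              max(apply(x$prec, c(1, 2), sum), na.rm = TRUE)))
  invisible(x)
}

# ncell x 12 matrix view of one element
.month_matrix <- function(a) matrix(a, ncol = 12L)

# vectorized row statistics (avoids apply() on large landscapes)
.row_sd <- function(m) {
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (ncol(m) - 1L))
}
.row_max <- function(m) do.call(pmax, as.data.frame(m))
.row_min <- function(m) do.call(pmin, as.data.frame(m))

# 3-consecutive-month window aggregates with December-January wrap-around.
# Returns ncell x 12 matrices of window sums (FUN = sum) or means.
.quarter_windows <- function(mm, mean = FALSE) {
  idx <- cbind(1:12, c(2:12, 1L), c(3:12, 1L, 2L))
  out <- matrix(NA_real_, nrow(mm), 12L)
  for (w in 1:12) {
    s <- mm[, idx[w, 1L]] + mm[, idx[w, 2L]] + mm[, idx[w, 3L]]
    out[, w] <- if (mean) s / 3 else s
  }
  out
}

#' Derive the 19 bioclim variables from monthly climate
#'
#' Standard bioclim summaries computed cellwise from monthly temperature and
#' precipitation. Quarters are every 3-consecutive-month window with
#' wrap-around (Dec-Jan-Feb allowed); the wettest/driest/warmest/coldest
#' window is chosen per cell, ties resolved to the earliest start month.
#'
#' Definitions used (temperature in degrees C, precipitation in mm):
#' \describe{
#'   \item{bio1}{annual mean of monthly mean temperature}
#'   \item{bio2}{mean diurnal range, mean of monthly (tmax - tmin)}
#'   \item{bio3}{isothermality, (bio2 / bio7) x 100 (0 where bio7 = 0)}
#'   \item{bio4}{temperature seasonality, sample SD of the 12 monthly
#'     means x 100}
#'   \item{bio5/bio6}{max tmax / min tmin of any month}
#'   \item{bio7}{annual temperature range, bio5 - bio6}
#'   \item{bio8/bio9}{mean temperature of the wettest / driest quarter}
#'   \item{bio10/bio11}{mean temperature of the warmest / coldest quarter}
#'   \item{bio12}{annual precipitation sum}
#'   \item{bio13/bio14}{precipitation of the wettest / driest month}
#'   \item{bio15}{precipitation seasonality, 100 x SD of monthly
#'     precipitation / (1 + bio12/12)}
#'   \item{bio16/bio17}{precipitation of the wettest / driest quarter}
#'   \item{bio18/bio19}{precipitation of the warmest / coldest quarter}
#' }
#'
#' @param monthly a [monthly_climate()] object.
#' @return A [raster_stack()] with layers `bio1` ... `bio19`.
#' @seealso [degree_days()], [climate_predictors()]
#' @export
derive_bioclim <- function(monthly) {
  stopifnot(inherits(monthly, "monthly_climate"))
  tmn <- .month_matrix(monthly$tmin)
  tmx <- .month_matrix(monthly$tmax)
  tav <- .month_matrix(monthly$tmean)
  pre <- .month_matrix(monthly$prec)

  n <- nrow(tav)
  b <- matrix(NA_real_, n, 19L,
              dimnames = list(NULL, paste0("bio", 1:19)))
  b[, 1L] <- rowMeans(tav)
  b[, 2L] <- rowMeans(tmx - tmn)
  b[, 4L] <- .row_sd(tav) * 100
  b[, 5L] <- .row_max(tmx)
  b[, 6L] <- .row_min(tmn)
  b[, 7L] <- b[, 5L] - b[, 6L]
  b[, 3L] <- ifelse(b[, 7L] == 0, 0, b[, 2L] / b[, 7L] * 100)

  pq <- .quarter_windows(pre)            # quarter precip sums
  tq <- .quarter_windows(tav, mean = TRUE) # quarter mean temperature
  wettest <- max.col(pq, ties.method = "first")
  driest  <- max.col(-pq, ties.method = "first")
  warmest <- max.col(tq, ties.method = "first")
  coldest <- max.col(-tq, ties.method = "first")
  pick <- function(m, w) m[cbind(seq_len(n), w)]

  b[, 8L]  <- pick(tq, wettest)
  b[, 9L]  <- pick(tq, driest)
  b[, 10L] <- pick(tq, warmest)
  b[, 11L] <- pick(tq, coldest)
  b[, 12L] <- rowSums(pre)
  b[, 13L] <- .row_max(pre)
  b[, 14L] <- .row_min(pre)
  b[, 15L] <- 100 * .row_sd(pre) / (1 + b[, 12L] / 12)
  b[, 16L] <- pick(pq, wettest)
  b[, 17L] <- pick(pq, driest)
  b[, 18L] <- pick(pq, warmest)
  b[, 19L] <- pick(pq, coldest)

  tmpl <- monthly$template
  d <- dim(monthly$tmean)[1:2]
  layers <- lapply(colnames(b), function(nm) {
    raster_grid(matrix(b[, nm], d[1L], d[2L]), xmin = tmpl$xmin,
                ymin = tmpl$ymin, cellsize = tmpl$cellsize, crs = tmpl$crs)
  })
  names(layers) <- colnames(b)
  raster_stack(layers)
}

#' Annual degree-days above a base temperature
#'
#' Cellwise sum over months of `days_in_month * max(0, tmean - base)`,
#' using calendar month lengths of a 365-day (non-leap) year. This is the
#' monthly-mean approximation of a thermal sum: a month contributes only
#' when its mean temperature is at or above the base.
#'
#' @param monthly a [monthly_climate()] object.
#' @param base base temperature in degrees C (default 10).
#' @return A [raster_grid()] of degree-days (degC x day), `>= 0` everywhere.
#' @export
degree_days <- function(monthly, base = 10) {
  stopifnot(inherits(monthly, "monthly_climate"))
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  tav <- .month_matrix(monthly$tmean)
  dd <- as.vector(pmax(tav - base, 0) %*% days)
  d <- dim(monthly$tmean)[1:2]
  tmpl <- monthly$template
  raster_grid(matrix(dd, d[1L], d[2L]), xmin = tmpl$xmin, ymin = tmpl$ymin,
              cellsize = tmpl$cellsize, crs = tmpl$crs)
}

#' Full 20-variable climate predictor stack
#'
#' Convenience wrapper returning the 19 bioclim layers plus `degdays10`
#' (degree-days above 10 degrees C), the predictor set used throughout the
#' modelling functions.
#'
#' @inheritParams derive_bioclim
#' @return A [raster_stack()] with layers `bio1`..`bio19`, `degdays10`.
#' @export
climate_predictors <- function(monthly) {
  stack <- derive_bioclim(monthly)
  layers <- c(unclass(stack), list(degdays10 = degree_days(monthly, 10)))
  raster_stack(layers)
}

#' Pearson correlation matrix of an environmental table
#'
#' Pairwise Pearson correlations between predictor columns, with
#' zero-variance columns flagged: their pairwise coefficients are set to
#' `NA` and their names returned in the `"zero_variance"` attribute.
#'
#' @param env numeric matrix or data frame (rows = points, columns =
#'   variables); at least 3 rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
env_correlation <- function(env) {
  env <- as.matrix(env)
  if (nrow(env) < 3L) stop_named("need at least 3 rows for correlations")
  sds <- apply(env, 2L, stats::sd)
  zv <- colnames(env)[sds == 0]
  if (length(zv)) {
    warn_named("zero-variance column(s): %s", paste(zv, collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(env))
  diag(r) <- 1
  attr(r, "zero_variance") <- zv
  r
}

#' Collinearity pruning of a predictor set
#'
#' Greedy screen over a priority-ordered variable list: a variable is
#' retained only if its absolute Pearson correlation with every
#' already-retained variable is strictly below `threshold`. Among a set of
#' mutually correlated variables the highest-priority one survives; the
#' result is idempotent.
#'
#' @param corr symmetric correlation matrix with dimnames (see
#'   [env_correlation()]).
#' @param keep_priority character vector of variable names, most important
#'   first; defaults to the column order of `corr`.
#' @param threshold pairs with `|r| >= threshold` are considered collinear
#'   (default 0.80).
#' @return Character vector of retained variable names, in priority order.
#' @export
prune_collinear <- function(corr, keep_priority = NULL, threshold = 0.80) {
  stopifnot(threshold > 0, threshold <= 1)
  vars <- colnames(corr)
  if (is.null(vars)) stop_named("correlation matrix must have dimnames")
  if (is.null(keep_priority) || !length(keep_priority)) keep_priority <- vars
  keep_priority <- c(keep_priority, setdiff(vars, keep_priority))
  kept <- character(0L)
  for (v in keep_priority) {
    if (!v %in% vars) next
    r <- abs(corr[v, kept])
    if (!length(kept) || all(is.na(r) | r < threshold)) kept <- c(kept, v)
  }
  kept
}

#' Extract environmental values at points
#'
#' Nearest-cell lookup of every stack layer at point locations. Points that
#' fall outside the grid extent or on nodata cells are dropped and listed
#' in the `"dropped"` attribute (row index and reason).
#'
#' @param points data frame with coordinate columns `longitude`/`latitude`
#'   or `x`/`y`.
#' @param stack a [raster_stack()].
#' @return Data frame of extracted values (one column per layer) with
#'   attributes `cell` (linear cell index), `kept` (input row indices) and
#'   `dropped`.
#' @export
extract_env_values <- function(points, stack) {
  stopifnot(inherits(stack, "raster_stack"))
  xy <- if (all(c("x", "y") %in% names(points))) {
    points[, c("x", "y")]
  } else if (all(c("longitude", "latitude") %in% names(points))) {
    stats::setNames(points[, c("longitude", "latitude")], c("x", "y"))
  } else stop_named("points must have x/y or longitude/latitude columns")
  cell <- cell_from_xy(stack[[1L]], xy$x, xy$y)
  nodata <- stack_nodata(stack)
  reason <- rep(NA_character_, nrow(points))
  reason[is.na(cell)] <- "outside_extent"
  on_nd <- !is.na(cell) & nodata[cell]
  reason[on_nd] <- "nodata"
  keep <- is.na(reason)
  if (!any(keep)) stop_named("all points fell outside the grid or on nodata")
  tab <- stack_table(stack)
  env <- as.data.frame(tab[cell[keep], , drop = FALSE])
  rownames(env) <- NULL
  attr(env, "cell") <- cell[keep]
  attr(env, "kept") <- which(keep)
  attr(env, "dropped") <- data.frame(row = which(!keep),
                                     reason = reason[!keep])
  env
}
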