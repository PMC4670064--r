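#' Occurrence set with provenance log
#'
#' Georeferenced presence records with a closed range-label vocabulary
#' (`native`, `invasive_conus`, `invasive_nonconus`) and a provenance log:
#' every filtering step appends one entry recording how many records came
#' in, were kept, and were removed, so counts reconcile exactly.
#'
#' @param records data frame with columns `id`, `longitude`, `latitude`,
#'   `range_label` and optionally `species`, `source`.
#' @param log optional existing provenance log to extend.
#' @return Object of class `occurrence_set`.
#' @export
occurrence_set <- function(records, log = NULL) {
  need <- c("id", "longitude", "latitude", "range_label")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_named("missing required column(s): %s", paste(miss, collapse = ", "))
  }
  if (!"source" %in% names(records)) records$source <- NA_character_
  if (anyDuplicated(records$id)) stop_named("occurrence ids must be unique")
  labs <- unique(records$range_label)
  bad <- setdiff(labs, range_labels())
  if (length(bad)) {
    stop_named("unknown range_label(s): %s", paste(bad, collapse = ", "))
  }
  if (nrow(records) &&
      (any(abs(records$longitude) > 180) || any(abs(records$latitude) > 90))) {
    stop_named("coordinates out of range")
  }
  rownames(records) <- NULL
  structure(list(records = records,
                 log = log %||% data.frame(step = character(), n_in = integer(),
                                           n_kept = integer(),
                                           n_removed = integer())),
            class = "occurrence_set")
}

#' @export
range_labels <- function() c("native", "invasive_conus", "invasive_nonconus")

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records\n", nrow(x$records)))
  print(table(x$records$range_label))
  if (nrow(x$log)) {
    cat("provenance:\n")
    print(x$log, row.names = FALSE)
  }
  invisible(x)
}

log_step <- function(occ, step, n_in, n_kept) {
  occ$log <- rbind(occ$log,
                   data.frame(step = step, n_in = n_in, n_kept = n_kept,
                              n_removed = n_in - n_kept))
  occ
}

#' Read occurrence records from CSV
#'
#' Parses a comma-separated table with columns `id`, `species`,
#' `longitude`, `latitude`, `range_label`, `source`. Rows with
#' unparseable or out-of-range coordinates or an unknown range label are
#' rejected; their file row numbers are reported in the provenance log and
#' the `"rejected"` attribute. A missing required column is a hard error.
#'
#' @param path path to the CSV file.
#' @return An [occurrence_set()]; empty (with a warning) if the file has no
#'   valid rows.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "longitude", "latitude", "range_label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_named("occurrence file missing required column(s): %s",
               paste(miss, collapse = ", "))
  }
  if (!"source" %in% names(df)) df$source <- NA_character_
  lon <- suppressWarnings(as.numeric(df$longitude))
  lat <- suppressWarnings(as.numeric(df$latitude))
  ok <- !is.na(lon) & !is.na(lat) & abs(lon) <= 180 & abs(lat) <= 90 &
    df$range_label %in% range_labels() & nzchar(df$id)
  rejected <- which(!ok)
  if (!nrow(df)) warn_named("empty occurrence file: %s", path)
  rec <- data.frame(id = df$id[ok], longitude = lon[ok], latitude = lat[ok],
                    range_label = df$range_label[ok], source = df$source[ok],
                    stringsAsFactors = FALSE)
  if ("species" %in% names(df)) rec$species <- df$species[ok]
  occ <- occurrence_set(rec)
  occ <- log_step(occ, "read", nrow(df), sum(ok))
  attr(occ, "rejected") <- rejected
  occ
}

#' Deduplicate occurrences to the climate grid
#'
#' Keeps at most one record per grid cell; the first record in input order
#' wins (stable tie-break). Records falling outside the grid are removed as
#' well and counted in the provenance log.
#'
#' @param occ an [occurrence_set()].
#' @param grid a [raster_grid()] defining the cell tessellation.
#' @return The deduplicated `occurrence_set`.
#' @export
dedupe_to_grid <- function(occ, grid) {
  stopifnot(inherits(occ, "occurrence_set"), is_raster_grid(grid))
  n_in <- nrow(occ$records)
  cell <- cell_from_xy(grid, occ$records$longitude, occ$records$latitude)
  keep <- !is.na(cell) & !duplicated(cell)
  occ$records <- occ$records[keep, , drop = FALSE]
  rownames(occ$records) <- NULL
  log_step(occ, "dedupe_to_grid", n_in, sum(keep))
}

# symmetric pairwise distance (km) in equal-area coordinates
.pairdist_km <- function(lon, lat) {
  p <- project_cea(lon, lat)
  as.matrix(stats::dist(p)) / 1000
}

#' Spatial thinning of occurrence records
#'
#' Enforces a minimum pairwise distance between retained records (distances
#' in the equal-area projection, [project_cea()]). Uses the greedy
#' maximal-retention heuristic: while any pair is closer than
#' `min_dist_km`, one record among those with the largest number of
#' too-close neighbours is removed, chosen at random under `seed`, so the
#' same seed reproduces the same thinned set.
#'
#' @param occ an [occurrence_set()].
#' @param min_dist_km minimum allowed pairwise distance in kilometres.
#' @param seed integer seed fixing the randomized removal order.
#' @return The thinned `occurrence_set`; all retained pairwise distances
#'   are `>= min_dist_km`.
#' @export
spatial_thin <- function(occ, min_dist_km = 10, seed = 1L) {
  stopifnot(inherits(occ, "occurrence_set"), min_dist_km > 0)
  n_in <- nrow(occ$records)
  if (n_in > 1L) {
    d <- .pairdist_km(occ$records$longitude, occ$records$latitude)
    diag(d) <- Inf
    alive <- rep(TRUE, n_in)
    with_seed(seed, {
      repeat {
        close <- d < min_dist_km & outer(alive, alive, `&`)
        counts <- rowSums(close)
        if (!any(counts > 0)) break
        worst <- which(counts == max(counts))
        drop <- if (length(worst) == 1L) worst else sample(worst, 1L)
        alive[drop] <- FALSE
      }
    })
    occ$records <- occ$records[alive, , drop = FALSE]
    rownames(occ$records) <- NULL
  }
  log_step(occ, sprintf("spatial_thin_%gkm", min_dist_km), n_in,
           nrow(occ$records))
}

#' Sampling-bias surface from occurrence density
#'
#' Gaussian kernel density of occurrence locations, evaluated at cell
#' centres in equal-area coordinates and rescaled so the maximum weight is
#' 1 with a floor of `1e-6` on valid cells. Used to weight background
#' sampling towards comparably surveyed environment.
#'
#' @param occ an [occurrence_set()] (zero records give a uniform surface
#'   with a warning).
#' @param grid [raster_grid()] on which the surface is evaluated; its
#'   nodata cells propagate.
#' @param bandwidth_km Gaussian kernel standard deviation in kilometres.
#' @return A `raster_grid` of relative sampling weights in `[1e-6, 1]`.
#' @export
bias_surface <- function(occ, grid, bandwidth_km = 20) {
  stopifnot(inherits(occ, "occurrence_set"), is_raster_grid(grid),
            bandwidth_km > 0)
  nd <- is.na(grid$values)
  out <- grid
  if (!nrow(occ$records)) {
    warn_named("no occurrence records: uniform bias surface returned")
    out$values[] <- 1
    out$values[nd] <- NA
    return(out)
  }
  cc <- xy_from_cell(grid)
  # geographic grids carry lon/lat; project both points and cells
  pc <- project_cea(cc$x, cc$y)
  po <- project_cea(occ$records$longitude, occ$records$latitude)
  h <- bandwidth_km * 1000
  dens <- rep(0, nrow(pc))
  for (i in seq_len(nrow(po))) {
    d2 <- (pc$x - po$x[i])^2 + (pc$y - po$y[i])^2
    dens <- dens + exp(-d2 / (2 * h^2))
  }
  dens <- dens / max(dens)
  out$values[] <- pmax(dens, 1e-6)
  out$values[nd] <- NA
  out
}

#' Draw background points from an accessible-area mask
#'
#' Samples cells without replacement from the valid (non-nodata, non-zero)
#' cells of `mask`, with probability proportional to the bias surface when
#' one is given and uniformly otherwise. If `n` exceeds the number of
#' available cells, all cells are returned with a warning.
#'
#' @param mask [raster_grid()]; cells with value 1 (and not `NA`) are
#'   accessible.
#' @param n number of background points (default 50000).
#' @param bias optional [bias_surface()] aligned with `mask`.
#' @param seed integer seed; sampling is reproducible bit-for-bit.
#' @return Object of class `background_sample`: data frame of `cell`, `x`,
#'   `y` plus the draw weights and seed used.
#' @export
sample_background <- function(mask, n = 50000, bias = NULL, seed = 1L) {
  stopifnot(is_raster_grid(mask))
  valid <- which(!is.na(mask$values) & mask$values != 0)
  if (!length(valid)) stop_named("accessible-area mask is empty")
  w <- rep(1, length(valid))
  if (!is.null(bias)) {
    if (!same_geometry(bias, mask)) {
      stop_named("bias surface does not align with the mask")
    }
    w <- bias$values[valid]
    w[is.na(w)] <- 1e-6
  }
  if (n >= length(valid)) {
    if (n > length(valid)) {
      warn_named("requested %d background points but only %d cells; using all",
                 n, length(valid))
    }
    cells <- valid
  } else {
    cells <- with_seed(seed, sample(valid, n, replace = FALSE, prob = w))
  }
  xy <- xy_from_cell(mask, cells)
  structure(list(points = data.frame(cell = cells, x = xy$x, y = xy$y),
                 weights = w[match(cells, valid)], seed = seed),
            class = "background_sample")
}

#' @export
print.background_sample <- function(x, ...) {
  cat(sprintf("background_sample: %d cells (seed %d)\n", nrow(x$points),
              x$seed))
  invisible(x)
}
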