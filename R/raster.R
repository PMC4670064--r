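#' Gridded raster layer
#'
#' A minimal in-memory single-band raster: a numeric matrix whose first row
#' is the northernmost (top) row, a geotransform given by the lower-left
#' corner and a square cell size, and `NA` as the nodata value. All layers
#' of a [raster_stack()] must share this geometry, and nodata cells are
#' excluded from every statistic computed on a grid.
#'
#' Cells are addressed by the usual R matrix linear index
#' (`values[row, col]`, index `row + (col - 1) * nrow`).
#'
#' @param values numeric matrix; row 1 is the top (maximum y) row.
#' @param xmin,ymin coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length (degrees or metres, per `crs`).
#' @param crs free-text coordinate reference tag, e.g. `"EPSG:4326"`.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                        crs = "EPSG:4326") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(cellsize > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize, crs = crs),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d rows x %d cols, cell %g, origin (%g, %g), crs %s\n",
              nrow(v), ncol(v), x$cellsize, x$xmin, x$ymin, x$crs))
  cat(sprintf("  values: [%g, %g], nodata cells: %d\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

is_raster_grid <- function(x) inherits(x, "raster_grid")

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Cell index from coordinates (nearest cell)
#'
#' Maps x/y coordinates to the linear index of the containing cell, or `NA`
#' for points outside the grid extent.
#'
#' @param grid a [raster_grid()].
#' @param x,y coordinate vectors.
#' @return Integer vector of linear cell indices (`NA` outside the extent).
#' @export
cell_from_xy <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$xmin) / grid$cellsize) + 1L
  row_from_bottom <- floor((y - grid$ymin) / grid$cellsize) + 1L
  # points exactly on the top/right edge belong to the last cell
  col[x == grid$xmin + nc * grid$cellsize] <- nc
  row_from_bottom[y == grid$ymin + nr * grid$cellsize] <- nr
  row <- nr - row_from_bottom + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr | is.na(x) | is.na(y)
  idx <- as.integer(row + (col - 1L) * nr)
  idx[bad] <- NA_integer_
  idx
}

#' Cell-centre coordinates from cell indices
#'
#' @param grid a [raster_grid()].
#' @param cell linear cell indices; default all cells.
#' @return Data frame with columns `x`, `y`.
#' @export
xy_from_cell <- function(grid, cell = seq_along(grid$values)) {
  nr <- nrow(grid$values)
  row <- (cell - 1L) %% nr + 1L
  col <- (cell - 1L) %/% nr + 1L
  data.frame(x = grid$xmin + (col - 0.5) * grid$cellsize,
             y = grid$ymin + (nr - row + 0.5) * grid$cellsize)
}

#' Stack of aligned raster layers
#'
#' A named list of [raster_grid()] layers sharing one geometry. The nodata
#' mask of the stack is the union of the layers' `NA` cells.
#'
#' @param ... named `raster_grid` layers, or a single named list of them.
#' @return Object of class `raster_stack` (a named list of layers).
#' @export
raster_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !is_raster_grid(layers[[1L]])) {
    layers <- layers[[1L]]
  }
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    stop_named("all raster_stack layers must be named")
  }
  if (!all(vapply(layers, is_raster_grid, logical(1L)))) {
    stop_named("raster_stack layers must be raster_grid objects")
  }
  tmpl <- layers[[1L]]
  for (nm in names(layers)) {
    if (!same_geometry(layers[[nm]], tmpl)) {
      stop_named("layer '%s' does not share the stack geometry", nm)
    }
  }
  structure(layers, class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack with %d layers: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  print(x[[1L]])
  invisible(x)
}

# union nodata mask over layers; TRUE = nodata
stack_nodata <- function(stack) {
  Reduce(`|`, lapply(stack, function(l) is.na(l$values)))
}

# matrix of per-cell variable values (all cells, nodata rows NA)
stack_table <- function(stack) {
  out <- vapply(stack, function(l) as.vector(l$values),
                numeric(length(stack[[1L]]$values)))
  colnames(out) <- names(stack)
  out
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster interchange. `write_esri_ascii()` stores one layer per
#' file; `read_esri_ascii()` returns a [raster_grid()]. Only square cells
#' are supported.
#'
#' @param path file path.
#' @param grid a [raster_grid()].
#' @param nodata numeric value written for `NA` cells.
#' @param crs coordinate tag attached to the grid on read.
#' @return `read_esri_ascii()` returns a `raster_grid`;
#'   `write_esri_ascii()` returns `path` invisibly.
#' @export
read_esri_ascii <- function(path, crs = "EPSG:4326") {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                         tolower(vapply(kv, `[`, "", 1L)))
  need <- c("ncols", "nrows", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop_named("malformed ESRI ASCII header in %s", path)
  }
  xmin <- if ("xllcorner" %in% names(hdr)) hdr[["xllcorner"]] else
    hdr[["xllcenter"]] - hdr[["cellsize"]] / 2
  ymin <- if ("yllcorner" %in% names(hdr)) hdr[["yllcorner"]] else
    hdr[["yllcenter"]] - hdr[["cellsize"]] / 2
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = hdr[["nrows"]], ncol = hdr[["ncols"]], byrow = TRUE)
  m[m == hdr[["nodata_value"]]] <- NA_real_
  raster_grid(m, xmin = xmin, ymin = ymin, cellsize = hdr[["cellsize"]],
              crs = crs)
}

#' @rdname read_esri_ascii
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid$xmin),
           sprintf("yllcorner %.10g", grid$ymin),
           sprintf("cellsize %.10g", grid$cellsize),
           sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' World Cylindrical Equal Area forward projection
#'
#' Projects longitude/latitude (degrees, WGS84) to equal-area metres with
#' the equator as standard parallel. Used for all distance and kernel
#' density computations on geographic coordinates so that areas are
#' preserved.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @return Data frame with columns `x`, `y` in metres.
#' @export
project_cea <- function(lon, lat) {
  R <- 6371007.181 # authalic Earth radius, m
  data.frame(x = R * lon * pi / 180, y = R * sin(lat * pi / 180))
}
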