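#' Regular space-time grid specification
#'
#' Defines the shared raster geometry of a scenario: a regular lon/lat lattice
#' (cell-center convention) and an ordered run of consecutive years. Every
#' raster, latent surface and draw array in a scenario refers to one
#' `grid_spec`. Cells are indexed row-major: `i = (row - 1) * n_cols + col`.
#'
#' @param origin_lon,origin_lat lower-left corner of the grid, degrees.
#' @param cell_size cell edge, degrees (> 0).
#' @param n_rows,n_cols grid dimensions.
#' @param years integer vector of consecutive, strictly increasing years.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(origin_lon, origin_lat, cell_size, n_rows, n_cols, years) {
  stopifnot(cell_size > 0, n_rows >= 1, n_cols >= 1, length(years) >= 1)
  years <- as.integer(years)
  if (length(years) > 1 && !all(diff(years) == 1L))
    stop("years must be strictly increasing and consecutive")
  structure(
    list(origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), years = years),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g deg, origin (%g, %g), years %d-%d\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat,
              min(x$years), max(x$years)))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell-center coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return data.frame with `cell`, `row`, `col`, `lon`, `lat` (cell centers).
#' @export
cell_centers <- function(grid) {
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  data.frame(
    cell = seq_len(n_cells(grid)), row = row, col = col,
    lon = grid$origin_lon + (col - 0.5) * grid$cell_size,
    lat = grid$origin_lat + (row - 0.5) * grid$cell_size)
}

#' Map lon/lat points to grid cell indices
#'
#' @param grid a [grid_spec()].
#' @param lon,lat coordinates, degrees.
#' @param strict error (rather than NA) for points outside the grid.
#' @return integer cell indices (row-major).
#' @export
cells_at <- function(grid, lon, lat, strict = TRUE) {
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1
  row <- floor((lat - grid$origin_lat) / grid$cell_size) + 1
  out <- row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols
  if (any(out)) {
    if (strict) stop("point(s) outside grid bounds")
    row[out] <- NA; col[out] <- NA
  }
  as.integer((row - 1) * grid$n_cols + col)
}

#' Raster backed by a grid_spec
#'
#' A raster is a numeric vector of length `n_rows * n_cols` (row-major cell
#' order) tagged with its grid. This is the package's in-memory stand-in for a
#' single-band GeoTIFF; [write_raster_csv()] / [read_raster_csv()] give a
#' portable plain-text representation.
#'
#' @param grid a [grid_spec()].
#' @param values numeric vector (length `n_cells`) or matrix
#'   (`n_rows x n_cols`, row 1 = southernmost).
#' @return object of class `grid_raster`.
#' @export
grid_raster <- function(grid, values) {
  if (is.matrix(values)) {
    stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
    values <- as.vector(t(values))  # row-major
  }
  stopifnot(length(values) == n_cells(grid))
  structure(list(grid = grid, values = as.numeric(values)), class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat("grid_raster over "); print(x$grid)
  cat(sprintf("  values: [%g, %g], %d NA\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' @rdname grid_raster
#' @param raster a `grid_raster`.
#' @param path CSV file path.
#' @export
write_raster_csv <- function(raster, path) {
  cc <- cell_centers(raster$grid)
  cc$value <- raster$values
  g <- raster$grid
  header <- sprintf("# grid origin_lon=%g origin_lat=%g cell_size=%g n_rows=%d n_cols=%d years=%s",
                    g$origin_lon, g$origin_lat, g$cell_size, g$n_rows, g$n_cols,
                    paste(g$years, collapse = ";"))
  writeLines(header, path)
  suppressWarnings(utils::write.table(cc, path, sep = ",", row.names = FALSE,
                                      append = TRUE, quote = FALSE))
  invisible(path)
}

#' @rdname grid_raster
#' @export
read_raster_csv <- function(path) {
  header <- readLines(path, n = 1)
  kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
  vals <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  grid <- grid_spec(as.numeric(vals["origin_lon"]), as.numeric(vals["origin_lat"]),
                    as.numeric(vals["cell_size"]), as.integer(vals["n_rows"]),
                    as.integer(vals["n_cols"]),
                    as.integer(strsplit(vals["years"], ";")[[1]]))
  df <- utils::read.csv(path, skip = 1)
  grid_raster(grid, df$value[order(df$cell)])
}

#' Bilinear interpolation weights from a knot lattice to points
#'
#' Builds the sparse projection matrix `A` (points x knots) that evaluates a
#' field defined on a regular knot lattice at arbitrary lon/lat points by
#' bilinear interpolation. Points outside the knot hull are clamped to the
#' hull edge, so the projection always sums to 1 per row.
#'
#' @param knots data.frame with `lon`, `lat` on a regular lattice, plus
#'   attributes `lons`, `lats` (sorted axis values).
#' @param lon,lat point coordinates.
#' @return sparse `dgCMatrix` of dimension `length(lon) x nrow(knots)`.
#' @keywords internal
bilinear_projector <- function(knots, lon, lat) {
  lons <- attr(knots, "lons"); lats <- attr(knots, "lats")
  nx <- length(lons); ny <- length(lats)
  stopifnot(nrow(knots) == nx * ny)
  fx <- findInterval(lon, lons, rightmost.closed = TRUE)
  fy <- findInterval(lat, lats, rightmost.closed = TRUE)
  fx <- pmin(pmax(fx, 1L), nx - 1L); fy <- pmin(pmax(fy, 1L), ny - 1L)
  if (nx == 1L) fx <- rep(1L, length(lon))
  if (ny == 1L) fy <- rep(1L, length(lat))
  tx <- if (nx > 1) (lon - lons[fx]) / (lons[fx + 1] - lons[fx]) else rep(0, length(lon))
  ty <- if (ny > 1) (lat - lats[fy]) / (lats[fy + 1] - lats[fy]) else rep(0, length(lat))
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  # knot index: column-within-row lattice, row-major over lat rows
  idx <- function(ix, iy) (iy - 1L) * nx + ix
  np <- length(lon)
  ii <- rep(seq_len(np), 4)
  jj <- c(idx(fx, fy), idx(pmin(fx + 1L, nx), fy),
          idx(fx, pmin(fy + 1L, ny)), idx(pmin(fx + 1L, nx), pmin(fy + 1L, ny)))
  ww <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(np, nrow(knots)))
}

#' Regular knot lattice over a grid
#'
#' Low-rank support set for the space-time Gaussian process: an
#' `n_knots_x x n_knots_y` lattice spanning the grid extent (inclusive of the
#' outermost cell centers). Returned with `lons`/`lats` attributes used by
#' [bilinear_projector()].
#'
#' @param grid a [grid_spec()].
#' @param n_knots_x,n_knots_y lattice dimensions (>= 2 unless the grid is 1-wide).
#' @return data.frame of knot coordinates with lattice attributes.
#' @export
make_knots <- function(grid, n_knots_x, n_knots_y = n_knots_x) {
  cc <- cell_centers(grid)
  lons <- seq(min(cc$lon), max(cc$lon), length.out = n_knots_x)
  lats <- seq(min(cc$lat), max(cc$lat), length.out = n_knots_y)
  k <- expand.grid(lon = lons, lat = lats, KEEP.OUT.ATTRS = FALSE)
  attr(k, "lons") <- lons; attr(k, "lats") <- lats
  k
}
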