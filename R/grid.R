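#' Grid specification for a projected km lattice
#'
#' All model fields live on a regular lattice in projected kilometres. The
#' lon/lat mapping is an equirectangular transform with cosine-corrected
#' longitude scaling at the domain-centre latitude; geographic coordinates
#' appear only at I/O boundaries (site tables, initialization centres).
#'
#' Cells are indexed 0-based conceptually but returned 1-based in R,
#' row-major, with cell-centred coordinates. A point at a cell boundary
#' belongs to the cell containing it under the half-open convention
#' `[x_edge, x_edge + cell_size)`.
#'
#' @param nx,ny number of cells in x and y (>= 2)
#' @param cell_size cell edge length in km (default 20)
#' @param origin_x,origin_y km coordinates of the lower-left corner of cell
#'   (1,1) (the domain corner, not the first cell centre)
#' @param lon0,lat0 geographic coordinates (degrees) mapped to the domain
#'   centre, used by the lon/lat transform
#' @return an object of class `grid_spec`
#' @export
grid_spec <- function(nx, ny, cell_size = 20, origin_x = 0, origin_y = 0,
                      lon0 = 0, lat0 = 45) {
  if (cell_size <= 0) stopf("cell_size must be > 0")
  if (nx < 2 || ny < 2) stopf("nx and ny must be >= 2")
  g <- list(nx = as.integer(nx), ny = as.integer(ny),
            cell_size = as.numeric(cell_size),
            origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
            lon0 = as.numeric(lon0), lat0 = as.numeric(lat0))
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g km, origin (%g, %g) km, centre (%g E, %g N)\n",
              x$nx, x$ny, x$cell_size, x$origin_x, x$origin_y, x$lon0, x$lat0))
  invisible(x)
}

# km per degree latitude; longitude scaled by cos(lat0)
.KM_PER_DEG <- 111.32

#' Convert lon/lat degrees to projected km and back
#'
#' @param grid a [grid_spec()]
#' @param lon,lat degrees
#' @return `lonlat_to_km`: a list with numeric vectors `x`, `y` (km).
#' @export
lonlat_to_km <- function(grid, lon, lat) {
  cx <- grid$origin_x + grid$nx * grid$cell_size / 2
  cy <- grid$origin_y + grid$ny * grid$cell_size / 2
  list(x = cx + (lon - grid$lon0) * .KM_PER_DEG * cos(grid$lat0 * pi / 180),
       y = cy + (lat - grid$lat0) * .KM_PER_DEG)
}

#' @rdname lonlat_to_km
#' @param x,y projected km
#' @return `km_to_lonlat`: a list with numeric vectors `lon`, `lat` (degrees).
#' @export
km_to_lonlat <- function(grid, x, y) {
  cx <- grid$origin_x + grid$nx * grid$cell_size / 2
  cy <- grid$origin_y + grid$ny * grid$cell_size / 2
  list(lon = grid$lon0 + (x - cx) / (.KM_PER_DEG * cos(grid$lat0 * pi / 180)),
       lat = grid$lat0 + (y - cy) / .KM_PER_DEG)
}

#' Degree-to-km scale factors of the grid's transform
#'
#' Used to convert an initialization standard deviation stated in degrees
#' into km along each axis.
#' @param grid a [grid_spec()]
#' @return list with `kx` (km per degree longitude) and `ky` (km per degree
#'   latitude)
#' @export
deg_to_km_scale <- function(grid) {
  list(kx = .KM_PER_DEG * cos(grid$lat0 * pi / 180), ky = .KM_PER_DEG)
}

#' Bin point coordinates to grid cells
#'
#' Half-open binning: a point exactly on an edge belongs to the cell whose
#' interval `[edge, edge + cell_size)` contains it.
#'
#' @param grid a [grid_spec()]
#' @param x,y km coordinates
#' @return list with integer vectors `ix`, `iy` (1-based; NA when outside the
#'   domain) and `cell` (linear index `iy + ny * (ix - 1)`, NA outside)
#' @export
cell_index <- function(grid, x, y) {
  ix <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  iy <- floor((y - grid$origin_y) / grid$cell_size) + 1L
  bad <- ix < 1L | ix > grid$nx | iy < 1L | iy > grid$ny
  ix[bad] <- NA_integer_; iy[bad] <- NA_integer_
  list(ix = as.integer(ix), iy = as.integer(iy),
       cell = as.integer(iy + grid$ny * (ix - 1L)))
}

#' Cell-centre coordinates
#' @param grid a [grid_spec()]
#' @param ix,iy 1-based cell indices
#' @return list with km coordinates `x`, `y` of the cell centres
#' @export
cell_center <- function(grid, ix, iy) {
  list(x = grid$origin_x + (ix - 0.5) * grid$cell_size,
       y = grid$origin_y + (iy - 0.5) * grid$cell_size)
}

#' Gridded scalar field with units and validity mask
#'
#' @param grid a [grid_spec()]
#' @param values numeric matrix of shape (ny, nx); row = y index
#' @param units unit string (e.g. "degC", "mm", "PDU", "")
#' @param mask logical matrix (ny, nx); TRUE = valid (land). Default: all
#'   non-NA cells. Masked (sea) cells are excluded from all statistics.
#' @return an object of class `raster_field`
#' @export
raster_field <- function(grid, values, units = "", mask = NULL) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$ny, grid$nx))) {
    stopf("values shape (%d, %d) does not match grid (ny=%d, nx=%d)",
          nrow(values), ncol(values), grid$ny, grid$nx)
  }
  if (is.null(mask)) mask <- !is.na(values)
  if (!all(dim(mask) == dim(values))) stopf("mask shape does not match values")
  f <- list(grid = grid, values = values, units = units, mask = mask)
  class(f) <- "raster_field"
  f
}

#' @export
print.raster_field <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("raster_field [%s]: %d x %d, %d valid cells, range [%g, %g]\n",
              x$units, x$grid$ny, x$grid$nx, sum(x$mask),
              if (length(v)) min(v, na.rm = TRUE) else NA,
              if (length(v)) max(v, na.rm = TRUE) else NA))
  invisible(x)
}

#' Summary statistics over valid (land) cells only
#' @param field a [raster_field()]
#' @return named vector (mean, sd, min, max, n)
#' @export
field_stats <- function(field) {
  v <- field$values[field$mask]
  c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
    min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
    n = sum(!is.na(v)))
}

# bilinear interpolation of a cell-centred field at point coordinates;
# constant extrapolation within the outer half-cell margin
interp_bilinear <- function(grid, values, x, y) {
  cs <- grid$cell_size
  fx <- (x - grid$origin_x) / cs - 0.5  # 0 at centre of cell 1
  fy <- (y - grid$origin_y) / cs - 0.5
  fx <- pmin(pmax(fx, 0), grid$nx - 1)
  fy <- pmin(pmax(fy, 0), grid$ny - 1)
  j0 <- pmin(floor(fx) + 1L, grid$nx - 1L); j1 <- j0 + 1L
  i0 <- pmin(floor(fy) + 1L, grid$ny - 1L); i1 <- i0 + 1L
  tx <- fx - (j0 - 1L); ty <- fy - (i0 - 1L)
  v00 <- values[cbind(i0, j0)]; v01 <- values[cbind(i0, j1)]
  v10 <- values[cbind(i1, j0)]; v11 <- values[cbind(i1, j1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}
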