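#' Grid geometry for lon/lat raster stacks
#'
#' A `niche_grid` describes a regular longitude/latitude raster: the
#' north-west corner, a square cell size in decimal degrees, and the number
#' of rows and columns. Row 1 is the northernmost row, column 1 the
#' westernmost column. Cells are half-open: a point on a cell's western
#' boundary belongs to that cell, a point on its eastern boundary to the
#' next cell east; a point on a cell's northern boundary belongs to that
#' cell, a point on its southern boundary to the next cell south.
#'
#' @param xmin western edge (decimal degrees, WGS84 longitude)
#' @param ymax northern edge (decimal degrees, WGS84 latitude)
#' @param cellsize cell size in decimal degrees (same in both axes)
#' @param nrow,ncol grid dimensions
#' @return an object of class `niche_grid`
#' @export
niche_grid <- function(xmin, ymax, cellsize, nrow, ncol) {
  stopifnot(cellsize > 0, nrow >= 1, ncol >= 1)
  ymin <- ymax - nrow * cellsize
  xmax <- xmin + ncol * cellsize
  if (ymax > 90 + 1e-9 || ymin < -90 - 1e-9)
    stop("grid latitude range [", ymin, ", ", ymax, "] outside [-90, 90]")
  structure(
    list(xmin = xmin, ymax = ymax, cellsize = cellsize,
         nrow = as.integer(nrow), ncol = as.integer(ncol),
         crs = "EPSG:4326"),
    class = "niche_grid"
  )
}

#' @method print niche_grid
#' @export
print.niche_grid <- function(x, ...) {
  cat(sprintf("<niche_grid> %d x %d cells of %.6f deg, x [%.4f, %.4f], y [%.4f, %.4f]\n",
              x$nrow, x$ncol, x$cellsize,
              x$xmin, x$xmin + x$ncol * x$cellsize,
              x$ymax - x$nrow * x$cellsize, x$ymax))
  invisible(x)
}

grid_identical <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Cell centres of grid cells
#'
#' @param grid a [niche_grid()]
#' @param rows,cols integer vectors of 1-based cell indices (recycled)
#' @return data.frame with columns `longitude`, `latitude`
#' @export
cell_centres <- function(grid, rows, cols) {
  data.frame(
    longitude = grid$xmin + (cols - 0.5) * grid$cellsize,
    latitude  = grid$ymax - (rows - 0.5) * grid$cellsize
  )
}

#' Map lon/lat points to grid cells
#'
#' Points outside the grid get NA row/col. Boundary convention: cells are
#' `[west, east) x (south, north]`.
#'
#' @param grid a [niche_grid()]
#' @param lon,lat coordinate vectors in decimal degrees
#' @return data.frame with integer columns `row`, `col` (NA when outside)
#' @export
lonlat_to_cell <- function(grid, lon, lat) {
  col <- floor((lon - grid$xmin) / grid$cellsize) + 1
  row <- floor((grid$ymax - lat) / grid$cellsize) + 1
  # north boundary of row 1 is inclusive
  row[lat == grid$ymax] <- 1L
  bad <- col < 1 | col > grid$ncol | row < 1 | row > grid$nrow
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

EARTH_RADIUS_KM <- 6371

#' Spherical areas of grid cells, by row
#'
#' Cell area from the closed form for a spherical band segment:
#' `R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))`, with R = 6371 km.
#'
#' @param grid a [niche_grid()]
#' @return numeric vector of length `grid$nrow`: the area in km^2 of one
#'   cell in each row (all cells in a row share a latitude band)
#' @export
cell_area_by_row <- function(grid) {
  top <- grid$ymax - (seq_len(grid$nrow) - 1) * grid$cellsize
  bot <- top - grid$cellsize
  dlam <- grid$cellsize * pi / 180
  EARTH_RADIUS_KM^2 * dlam * (sin(top * pi / 180) - sin(bot * pi / 180))
}

#' Great-circle distance in km (haversine, R = 6371 km)
#'
#' Thin wrapper over [geosphere::distHaversine()] fixing the sphere radius
#' used throughout the package.
#'
#' @param p,q two-column matrices or data.frames of (longitude, latitude);
#'   the shorter argument is recycled
#' @return numeric vector of distances in kilometres
#' @export
haversine_km <- function(p, q) {
  geosphere::distHaversine(as.matrix(p), as.matrix(q), r = EARTH_RADIUS_KM)
}
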