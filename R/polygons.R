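#' Named polygon layers
#'
#' Minimal polygon support for overlap accounting: a `polygon_set` is a
#' list of named polygons, each a list of rings (closed lon/lat coordinate
#' matrices; the first ring is the outer boundary, further rings are
#' holes). Point-in-polygon uses the even-odd ray-casting rule, so holes
#' need no special treatment.
#'
#' @param polygons list of `list(name =, rings = list(matrix lon/lat))`
#' @return object of class `polygon_set`
#' @export
polygon_set <- function(polygons) {
  for (p in polygons) {
    stopifnot(is.character(p$name), is.list(p$rings), length(p$rings) >= 1)
    for (r in p$rings) stopifnot(is.matrix(r), ncol(r) == 2, nrow(r) >= 3)
  }
  structure(list(polygons = polygons), class = "polygon_set")
}

#' @method print polygon_set
#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set> %d polygon(s): %s\n", length(x$polygons),
              paste(vapply(x$polygons, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' Read polygons from a GeoJSON file
#'
#' Supports FeatureCollections of Polygon and MultiPolygon geometries in
#' WGS84; each feature's `name` property labels the polygon.
#'
#' @param path GeoJSON file path
#' @return a [polygon_set()]
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  polys <- list()
  for (feat in gj$features) {
    nm <- feat$properties$name %||% paste0("polygon", length(polys) + 1)
    geom <- feat$geometry
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates, function(pg)
        lapply(pg, ring_mat)), recursive = FALSE),
      stop("unsupported geometry type: ", geom$type))
    polys[[length(polys) + 1]] <- list(name = nm, rings = rings)
  }
  polygon_set(polys)
}

#' Even-odd point-in-polygon test
#'
#' @param x,y point coordinate vectors (lon, lat)
#' @param rings list of closed ring matrices (lon, lat); even-odd over all
#'   rings, so interior rings act as holes
#' @return logical vector
#' @export
points_in_polygon <- function(x, y, rings) {
  inside <- rep(FALSE, length(x))
  for (ring in rings) {
    rx <- ring[, 1]; ry <- ring[, 2]
    n <- length(rx)
    if (rx[1] == rx[n] && ry[1] == ry[n]) n <- n - 1  # drop closing vertex
    j <- n
    for (i in seq_len(n)) {
      crosses <- ((ry[i] > y) != (ry[j] > y)) &
        (x < (rx[j] - rx[i]) * (y - ry[i]) / (ry[j] - ry[i]) + rx[i])
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}
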