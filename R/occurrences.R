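#' Presence records and spatial thinning
#'
#' Occurrence records are point coordinates in decimal degrees (WGS84).
#' Because clustered field records carry pseudo-replicated information, the
#' pipeline thins them to spatially unique grid cells of the analysis
#' raster before modelling: one representative record per occupied cell.
#'
#' @name occurrences
NULL

#' Load presence records from a table or CSV file
#'
#' Rows with unparsable or out-of-range coordinates are dropped with a
#' warning reporting the count; duplicate points are kept (thinning deals
#' with them).
#'
#' @param table a data.frame with `longitude` and `latitude` columns
#'   (decimal degrees; optional `source` column), or the path of a CSV
#'   file with those header columns
#' @return an object of class `occurrence_set`
#' @export
load_records <- function(table) {
  if (is.character(table)) {
    if (!file.exists(table)) stop("no such file: ", table)
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  if (!all(c("longitude", "latitude") %in% names(table)))
    stop("input must have 'longitude' and 'latitude' columns")
  lon <- suppressWarnings(as.numeric(table$longitude))
  lat <- suppressWarnings(as.numeric(table$latitude))
  ok <- !is.na(lon) & !is.na(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(n_bad, " record(s) dropped: unparsable or out-of-range coordinates")
  if (!any(ok)) stop("no valid occurrence records")
  src <- if ("source" %in% names(table)) as.character(table$source) else
    rep(NA_character_, nrow(table))
  structure(
    list(records = data.frame(longitude = lon[ok], latitude = lat[ok],
                              source = src[ok], stringsAsFactors = FALSE),
         thinned = FALSE, cells = NULL),
    class = "occurrence_set"
  )
}

#' @method print occurrence_set
#' @export
print.occurrence_set <- function(x, ...) {
  if (x$thinned)
    cat(sprintf("<occurrence_set> %d record(s) thinned to %d spatially unique cell(s)\n",
                nrow(x$records), nrow(x$cells)))
  else
    cat(sprintf("<occurrence_set> %d raw record(s)\n", nrow(x$records)))
  invisible(x)
}

#' Thin occurrence records to spatially unique grid cells
#'
#' Maps each record to its analysis-grid cell and keeps one representative
#' (the first in input order) per occupied cell, mirroring the tally of
#' records into ~10 km cells. Records outside the grid are dropped with a
#' warning. Thinning is idempotent and order-stable.
#'
#' @param occ an `occurrence_set` from [load_records()]
#' @param grid a [niche_grid()] (the analysis raster grid)
#' @return a thinned `occurrence_set` with a `cells` data.frame of unique
#'   (row, col) indices and the representative record coordinates
#' @export
thin_to_cells <- function(occ, grid) {
  stopifnot(inherits(occ, "occurrence_set"))
  rc <- lonlat_to_cell(grid, occ$records$longitude, occ$records$latitude)
  inside <- !is.na(rc$row)
  if (sum(!inside) > 0)
    warning(sum(!inside), " record(s) outside the grid dropped")
  if (!any(inside)) stop("all occurrence records fall outside the grid")
  rec <- occ$records[inside, , drop = FALSE]
  rc <- rc[inside, , drop = FALSE]
  key <- paste(rc$row, rc$col)
  keep <- !duplicated(key)
  structure(
    list(records = rec,
         thinned = TRUE,
         cells = data.frame(row = rc$row[keep], col = rc$col[keep],
                            longitude = rec$longitude[keep],
                            latitude = rec$latitude[keep])),
    class = "occurrence_set"
  )
}

#' Number of spatially unique presence cells
#'
#' @param occ a thinned `occurrence_set`
#' @return integer cell count
#' @export
n_presence_cells <- function(occ) {
  stopifnot(inherits(occ, "occurrence_set"), isTRUE(occ$thinned))
  nrow(occ$cells)
}
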