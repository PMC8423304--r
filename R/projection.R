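#' Binarization, consensus mapping and area accounting
#'
#' Continuous suitability is cut at a threshold into a 0/1 presence map
#' (1 wherever suitability >= threshold). Per-replicate binary maps are
#' combined into a consensus: only replicates that successfully predicted
#' their withheld presence contribute; the frequency surface is their
#' per-cell mean and the consensus cell is 1 where the frequency reaches
#' 0.5 (majority, ties to presence). Suitable areas are summed with the
#' spherical-band cell-area closed form and compared across scenarios.
#'
#' @name projection_consensus
NULL

#' Threshold a suitability map into a 0/1 presence map
#'
#' @param map a `suitability_map`
#' @param threshold cut point in [0, 1]; cells with suitability >=
#'   threshold become 1
#' @return object of class `binary_map` (values 0/1, NA preserved)
#' @export
binarize <- function(map, threshold) {
  stopifnot(inherits(map, "suitability_map"))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  v <- ifelse(map$values >= threshold, 1, 0)
  binary_map(v, map$grid, threshold = threshold, scenario = map$scenario)
}

#' Construct a binary presence/absence map
#'
#' @param values matrix of 0/1 (NA = NoData)
#' @param grid a [niche_grid()]
#' @param threshold threshold that produced the map (NA if none)
#' @param scenario scenario label
#' @export
binary_map <- function(values, grid, threshold = NA_real_,
                       scenario = "current") {
  u <- unique(as.vector(values))
  if (!all(u %in% c(0, 1, NA)))
    stop("binary map values must be 0, 1 or NA")
  structure(list(values = values, grid = grid, threshold = threshold,
                 scenario = scenario),
            class = "binary_map")
}

#' @method print binary_map
#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> scenario '%s', threshold %.3f, %d of %d valid cells present\n",
              x$scenario, x$threshold, sum(x$values == 1, na.rm = TRUE),
              sum(!is.na(x$values))))
  invisible(x)
}

#' Consensus of per-replicate binary maps
#'
#' @param binary_maps list of `binary_map`s on one grid
#' @param qualifying logical/0-1 vector, one flag per map: whether that
#'   replicate successfully predicted its withheld presence (only
#'   qualifying maps contribute)
#' @param rule consensus rule; `"majority"` marks cells with contributing
#'   frequency >= 0.5 (ties to presence)
#' @return list with `consensus` (a `binary_map`), `frequency` (matrix of
#'   per-cell contributing-map means) and `n_contributing`
#' @export
consensus <- function(binary_maps, qualifying, rule = "majority") {
  stopifnot(length(binary_maps) >= 1,
            length(qualifying) == length(binary_maps))
  rule <- match.arg(rule, "majority")
  g <- binary_maps[[1]]$grid
  for (m in binary_maps[-1])
    if (!grid_identical(m$grid, g)) stop("grid mismatch between binary maps")
  keep <- which(as.logical(qualifying))
  if (length(keep) == 0) stop("no valid replicates: zero qualifying maps")
  freq <- Reduce(`+`, lapply(binary_maps[keep], `[[`, "values")) /
    length(keep)
  cons <- ifelse(freq >= 0.5, 1, 0)
  list(consensus = binary_map(cons, g,
                              threshold = 0.5,
                              scenario = binary_maps[[1]]$scenario),
       frequency = freq, n_contributing = length(keep))
}

#' Suitable area of a binary map, in km^2
#'
#' Sums the spherical-band closed-form cell areas (R = 6371 km) over the
#' predicted-present cells.
#'
#' @param map a `binary_map`
#' @return area in km^2
#' @export
suitable_area_km2 <- function(map) {
  a <- cell_area_by_row(map$grid)
  present <- rowSums(map$values == 1, na.rm = TRUE)
  sum(a * present)
}

#' Compare suitable areas across scenarios
#'
#' For each future scenario, reports the suitable area, the percentage
#' change in total area relative to the current scenario (loss when the
#' future total is smaller, gain when larger), and the cellwise stable /
#' lost / gained areas.
#'
#' @param current a `binary_map` for the current scenario
#' @param futures named list of future-scenario `binary_map`s
#' @return object of class `scenario_comparison`: a data.frame with one
#'   row per scenario (current first) and columns `scenario`, `area_km2`,
#'   `loss_pct`, `gain_pct`, `stable_km2`, `lost_km2`, `gained_km2`
#' @export
change_stats <- function(current, futures) {
  stopifnot(inherits(current, "binary_map"))
  a_cur <- suitable_area_km2(current)
  area_rows <- cell_area_by_row(current$grid)
  row_of <- function(expr) rowSums(expr, na.rm = TRUE)
  out <- data.frame(scenario = current$scenario, area_km2 = a_cur,
                    loss_pct = 0, gain_pct = 0, stable_km2 = a_cur,
                    lost_km2 = 0, gained_km2 = 0,
                    stringsAsFactors = FALSE)
  for (nm in names(futures)) {
    f <- futures[[nm]]
    if (!grid_identical(f$grid, current$grid))
      stop("grid mismatch between scenarios")
    a_fut <- suitable_area_km2(f)
    if (a_cur == 0) {
      loss <- NA_real_; gain <- NA_real_
    } else {
      delta <- 100 * (a_cur - a_fut) / a_cur
      loss <- max(delta, 0); gain <- max(-delta, 0)
    }
    stable <- sum(area_rows * row_of(current$values == 1 & f$values == 1))
    lost   <- sum(area_rows * row_of(current$values == 1 & f$values == 0))
    gained <- sum(area_rows * row_of(current$values == 0 & f$values == 1))
    out <- rbind(out, data.frame(scenario = nm, area_km2 = a_fut,
                                 loss_pct = loss, gain_pct = gain,
                                 stable_km2 = stable, lost_km2 = lost,
                                 gained_km2 = gained,
                                 stringsAsFactors = FALSE))
  }
  class(out) <- c("scenario_comparison", "data.frame")
  out
}

#' Overlap of the suitable area with named polygons
#'
#' A present cell counts toward a polygon when its centre falls inside
#' (even-odd rule; holes supported). Also reports the percentage of the
#' total suitable area inside the polygon union.
#'
#' @param map a `binary_map`
#' @param polygons a `polygon_set` from [read_geojson()] or
#'   [polygon_set()]
#' @return data.frame with columns `name`, `overlap_km2`, `overlap_pct`
#'   (share of total suitable area); attribute `union_pct` gives the
#'   suitable-area share inside the union of all polygons
#' @export
overlap_with_polygons <- function(map, polygons) {
  total <- suitable_area_km2(map)
  if (length(polygons$polygons) == 0) {
    out <- data.frame(name = character(), overlap_km2 = numeric(),
                      overlap_pct = numeric())
    attr(out, "union_pct") <- 0
    return(out)
  }
  idx <- which(map$values == 1)
  if (length(idx) == 0) {
    out <- data.frame(name = vapply(polygons$polygons, `[[`, "", "name"),
                      overlap_km2 = 0, overlap_pct = 0)
    attr(out, "union_pct") <- 0
    return(out)
  }
  g <- map$grid
  rows <- ((idx - 1) %% g$nrow) + 1
  cols <- ((idx - 1) %/% g$nrow) + 1
  ctr <- cell_centres(g, rows, cols)
  areas <- cell_area_by_row(g)[rows]
  inside_any <- rep(FALSE, length(idx))
  out <- do.call(rbind, lapply(polygons$polygons, function(poly) {
    inside <- points_in_polygon(ctr$longitude, ctr$latitude, poly$rings)
    inside_any <<- inside_any | inside
    data.frame(name = poly$name, overlap_km2 = sum(areas[inside]),
               overlap_pct = if (total > 0) 100 * sum(areas[inside]) / total
                             else 0)
  }))
  attr(out, "union_pct") <- if (total > 0)
    100 * sum(areas[inside_any]) / total else 0
  out
}
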