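#' Disk-constrained pseudo-absence sampling
#'
#' With presence-only data, background "pseudo-absence" (PA) cells stand in
#' for absences during calibration. PA cells are drawn uniformly without
#' replacement from the cells whose great-circle distance to the *nearest*
#' presence cell centre lies inside a distance band (the "disk"): far
#' enough from every presence not to contaminate the absence class, close
#' enough to stay in the reachable landscape. By default the band is the
#' minimum and maximum over all presence-pair distances.
#'
#' @name pseudo_absence
NULL

#' Distance band from the presence cells themselves
#'
#' Computes the minimum and maximum great-circle (haversine, R = 6371 km)
#' distance over all pairs of presence cell centres.
#'
#' @param occ a thinned `occurrence_set` with >= 2 unique cells
#' @param grid the analysis [niche_grid()]
#' @return named numeric vector `c(d_min_km, d_max_km)`
#' @export
presence_distance_bounds <- function(occ, grid) {
  stopifnot(inherits(occ, "occurrence_set"), isTRUE(occ$thinned))
  n <- nrow(occ$cells)
  if (n < 2) stop("need >= 2 unique presence cells to define distance bounds")
  ctr <- cell_centres(grid, occ$cells$row, occ$cells$col)
  d <- numeric(0)
  for (i in seq_len(n - 1)) {
    d <- c(d, haversine_km(ctr[i, ], ctr[(i + 1):n, , drop = FALSE]))
  }
  c(d_min_km = min(d), d_max_km = max(d))
}

# nearest-presence distance (km) for a set of cells, vectorized over cells
nearest_presence_km <- function(grid, cells, presence_cells) {
  ctr <- cell_centres(grid, cells$row, cells$col)
  pc <- cell_centres(grid, presence_cells$row, presence_cells$col)
  d <- matrix(Inf, nrow(cells), nrow(pc))
  for (j in seq_len(nrow(pc)))
    d[, j] <- haversine_km(ctr, pc[j, , drop = FALSE])
  apply(d, 1, min)
}

#' Cells eligible for disk pseudo-absence sampling
#'
#' Eligible cells are valid (unmasked) cells that are not presence cells
#' (and not in `exclude_cells`) whose nearest-presence distance lies in
#' `[d_min_km, d_max_km]` (inclusive).
#'
#' @param grid the analysis [niche_grid()]
#' @param mask logical valid-cell matrix
#' @param presence_cells data.frame of presence (row, col)
#' @param bounds numeric `c(d_min_km, d_max_km)`
#' @param exclude_cells optional extra (row, col) cells barred from
#'   eligibility (e.g. a left-out jackknife presence)
#' @return data.frame of eligible (row, col)
#' @export
disk_eligible_cells <- function(grid, mask, presence_cells, bounds,
                                exclude_cells = NULL) {
  idx <- which(mask)
  all_cells <- data.frame(row = ((idx - 1) %% grid$nrow) + 1,
                          col = ((idx - 1) %/% grid$nrow) + 1)
  barred <- rbind(presence_cells[, c("row", "col")],
                  if (!is.null(exclude_cells)) exclude_cells[, c("row", "col")])
  is_barred <- paste(all_cells$row, all_cells$col) %in%
    paste(barred$row, barred$col)
  cand <- all_cells[!is_barred, , drop = FALSE]
  d <- nearest_presence_km(grid, cand, presence_cells)
  cand[d >= bounds[1] & d <= bounds[2], , drop = FALSE]
}

#' Sample a disk-constrained pseudo-absence set
#'
#' @param grid the analysis [niche_grid()]
#' @param occ a thinned `occurrence_set` (its cells are the presences)
#' @param n number of PA cells to draw
#' @param bounds `c(d_min_km, d_max_km)`; defaults to
#'   [presence_distance_bounds()]
#' @param seed RNG seed (sampling is reproducible given the seed)
#' @param mask logical valid-cell matrix (default: all cells valid)
#' @param exclude_cells optional cells barred from eligibility
#' @param cap_at_eligible if TRUE, an `n` exceeding the eligible-cell count
#'   is capped with a warning instead of erroring (used for the fixed
#'   10000-PA designs on small grids)
#' @return object of class `pa_sample` with fields `cells` (row, col,
#'   longitude, latitude), `n_requested`, `strategy`, `d_min_km`,
#'   `d_max_km`, `seed`
#' @export
sample_disk_pas <- function(grid, occ, n, bounds = NULL, seed = 1,
                            mask = NULL, exclude_cells = NULL,
                            cap_at_eligible = FALSE) {
  stopifnot(n >= 1)
  if (is.null(bounds)) bounds <- presence_distance_bounds(occ, grid)
  if (is.null(mask)) mask <- matrix(TRUE, grid$nrow, grid$ncol)
  elig <- disk_eligible_cells(grid, mask, occ$cells, bounds, exclude_cells)
  if (nrow(elig) == 0) stop("no cells eligible for pseudo-absence sampling")
  if (n > nrow(elig)) {
    if (!cap_at_eligible)
      stop("requested ", n, " pseudo-absences but only ", nrow(elig),
           " eligible cells")
    warning("pseudo-absence count capped at ", nrow(elig), " eligible cells")
    n <- nrow(elig)
  }
  set.seed(seed)
  take <- sample.int(nrow(elig), n)
  cells <- elig[take, , drop = FALSE]
  ctr <- cell_centres(grid, cells$row, cells$col)
  structure(
    list(cells = data.frame(row = cells$row, col = cells$col,
                            longitude = ctr$longitude, latitude = ctr$latitude),
         n_requested = as.integer(n), strategy = "disk",
         d_min_km = unname(bounds[1]), d_max_km = unname(bounds[2]),
         seed = seed),
    class = "pa_sample"
  )
}

LEARNER_FAMILIES <- c("GBM", "CTA", "RF", "GLM", "GAM", "ANN", "FDA",
                      "MARS", "MAXENT")
PRESENCE_MATCHED_FAMILIES <- c("GBM", "CTA", "RF")

#' Pseudo-absence count for a learner family
#'
#' Classification-tree families (GBM, CTA, RF) use as many pseudo-absences
#' as presences; the remaining families use 10000 PAs, capped at the
#' eligible-cell count with a warning when the landscape is smaller.
#'
#' @param family one of GBM, CTA, RF, GLM, GAM, ANN, FDA, MARS, MAXENT
#' @param n_presences number of (training) presence cells
#' @param n_eligible eligible-cell count used for the cap (default Inf)
#' @return integer PA count
#' @export
pa_count_for_family <- function(family, n_presences, n_eligible = Inf) {
  family <- match.arg(toupper(family), LEARNER_FAMILIES)
  n <- if (family %in% PRESENCE_MATCHED_FAMILIES) n_presences else 10000L
  if (n > n_eligible) {
    warning("pseudo-absence count for ", family, " capped at ",
            n_eligible, " eligible cells")
    n <- n_eligible
  }
  as.integer(n)
}
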