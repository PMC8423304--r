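#' Small-sample jackknife validation
#'
#' With far fewer than the ~25 spatially unique records that conventional
#' data-splitting evaluation needs, the pipeline validates by
#' leave-one-out: each presence cell is withheld in turn, the full
#' ensemble is recalibrated on the rest, its continuous surface is
#' binarized at the threshold maximizing sensitivity + specificity, and
#' the replicate succeeds if the withheld cell is predicted present. Under
#' the null hypothesis of a model no better than random, replicate i
#' succeeds with probability p_i = the area-weighted proportion of the
#' landscape its map predicts present, so the observed success count D is
#' a draw from a Poisson-binomial distribution; its exact upper tail
#' P(X >= D) is the test's p-value.
#'
#' @name evaluation
NULL

#' Threshold maximizing sensitivity plus specificity
#'
#' sensitivity(t) = fraction of presence scores >= t; specificity(t) =
#' fraction of absence scores < t. The maximizing t is searched over the
#' midpoints of adjacent distinct pooled scores plus the extremes (and one
#' candidate above the maximum, classifying everything absent); ties break
#' toward the smallest maximizing t.
#'
#' @param presence_scores,absence_scores non-empty numeric vectors in [0,1]
#' @return list with `threshold`, `sensitivity`, `specificity`
#' @export
maxsensspec_threshold <- function(presence_scores, absence_scores) {
  if (length(presence_scores) == 0 || length(absence_scores) == 0)
    stop("presence and absence score lists must be non-empty")
  pooled <- sort(unique(c(presence_scores, absence_scores)))
  cand <- pooled
  if (length(pooled) > 1)
    cand <- c(cand, (pooled[-1] + pooled[-length(pooled)]) / 2)
  cand <- sort(c(cand, pooled[length(pooled)] + 1e-9))
  sp <- sort(presence_scores)
  sa <- sort(absence_scores)
  # counts of scores < t via binary search on the sorted vectors
  sens <- 1 - findInterval(cand, sp, left.open = TRUE) / length(sp)
  spec <- findInterval(cand, sa, left.open = TRUE) / length(sa)
  best <- which.max(sens + spec)  # which.max takes the first (smallest t) tie
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best])
}

#' Area-weighted proportion of the landscape predicted present
#'
#' Cell areas come from the spherical-band closed form
#' `R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))`, so high-latitude
#' cells count less than equatorial ones.
#'
#' @param binary_map a [binary_map()] on a lon/lat grid
#' @return proportion in [0, 1]
#' @export
area_weighted_presence_proportion <- function(binary_map) {
  v <- binary_map$values
  if (!any(!is.na(v))) stop("no valid cells in binary map")
  a <- cell_area_by_row(binary_map$grid)
  valid <- rowSums(!is.na(v))
  present <- rowSums(v == 1, na.rm = TRUE)
  sum(a * present) / sum(a * valid)
}

#' Exact Poisson-binomial upper-tail probability
#'
#' P(X >= D) where X is the sum of independent Bernoulli(p_i) trials with
#' heterogeneous success probabilities, computed exactly by
#' dynamic-programming convolution of the per-trial distributions.
#'
#' @param p_list vector of per-trial success probabilities in [0, 1]
#' @param D integer success count, 0 <= D <= length(p_list)
#' @return exact tail probability in [0, 1]
#' @export
poisson_binomial_pvalue <- function(p_list, D) {
  n <- length(p_list)
  if (any(p_list < 0 | p_list > 1)) stop("probabilities must lie in [0, 1]")
  if (D < 0 || D > n) stop("D must lie in [0, ", n, "]")
  if (D == 0) return(1)
  dist <- c(1, rep(0, n))  # dist[k+1] = P(X = k) over trials so far
  for (p in p_list) {
    dist <- dist * (1 - p) + c(0, dist[-(n + 1)]) * p
  }
  min(1, sum(dist[(D + 1):(n + 1)]))
}

#' Run the leave-one-out jackknife over all presence cells
#'
#' For each unique presence cell: the remaining cells are the training
#' presences; the distance band and both pseudo-absence designs are drawn
#' from them (the withheld cell is barred from PA eligibility); the
#' ensemble is calibrated and its current-scenario surface thresholded by
#' [maxsensspec_threshold()] on the training-presence scores versus the
#' replicate's distinct pseudo-absence-cell scores; all scenarios are
#' binarized at that replicate threshold. The replicate succeeds when the
#' withheld cell is predicted present.
#'
#' @param occ thinned `occurrence_set` with >= 3 unique cells
#' @param score_stacks named list of predictor stacks (first = current)
#' @param config run configuration (see [default_config()]); uses the
#'   `families`, `pa` and `n_runs`, `seed` entries
#' @return object of class `jackknife_report`: `replicates` data.frame
#'   (left_out_row/col, threshold, sensitivity, specificity,
#'   presence_proportion, success), `D`, `n`, `p_value`, and
#'   `binary_maps` — a per-scenario list of per-replicate [binary_map()]s
#' @export
jackknife_run <- function(occ, score_stacks, config = default_config()) {
  stopifnot(inherits(occ, "occurrence_set"), isTRUE(occ$thinned))
  n <- nrow(occ$cells)
  if (n < 3) stop("jackknife needs >= 3 unique presence cells")
  grid <- score_stacks[[1]]$grid
  mask <- score_stacks[[1]]$mask
  scen_names <- names(score_stacks)
  families <- config$families
  n_sets <- config$pa$n_sets
  rows <- vector("list", n)
  bin_maps <- lapply(scen_names, function(s) vector("list", n))
  names(bin_maps) <- scen_names
  for (i in seq_len(n)) {
    left_out <- occ$cells[i, , drop = FALSE]
    train <- structure(list(records = occ$records, thinned = TRUE,
                            cells = occ$cells[-i, , drop = FALSE]),
                       class = "occurrence_set")
    if (nrow(train$cells) < 2)
      stop("replicate with < 2 training presences")
    bounds <- c(config$pa$d_min_km %||% NA, config$pa$d_max_km %||% NA)
    if (any(is.na(bounds))) bounds <- presence_distance_bounds(train, grid)
    elig <- disk_eligible_cells(grid, mask, train$cells, bounds,
                                exclude_cells = left_out)
    if (nrow(elig) == 0)
      stop("replicate ", i, ": no cells eligible for pseudo-absence ",
           "sampling in the distance band [", round(bounds[1], 1), ", ",
           round(bounds[2], 1), "] km; consider overriding pa$d_min_km/",
           "pa$d_max_km")
    n_matched <- pa_count_for_family("CTA", nrow(train$cells), nrow(elig))
    n_large <- suppressWarnings(
      pa_count_for_family("GLM", nrow(train$cells), nrow(elig)))
    draw <- function(n_pa, s, tag) {
      seed <- derive_seed(config$seed, 101, i, s, tag)
      set.seed(seed)
      take <- sample.int(nrow(elig), n_pa)
      ctr <- cell_centres(grid, elig$row[take], elig$col[take])
      structure(list(cells = data.frame(row = elig$row[take],
                                        col = elig$col[take],
                                        longitude = ctr$longitude,
                                        latitude = ctr$latitude),
                     n_requested = n_pa, strategy = "disk",
                     d_min_km = unname(bounds[1]),
                     d_max_km = unname(bounds[2]), seed = seed),
                class = "pa_sample")
    }
    pa_matched <- lapply(seq_len(n_sets), function(s) draw(n_matched, s, 1))
    pa_large <- lapply(seq_len(n_sets), function(s) draw(n_large, s, 2))
    cal <- calibrate_replicate(train$cells, pa_matched, pa_large,
                               score_stacks, families,
                               n_runs = config$n_runs,
                               seed_base = derive_seed(config$seed, 202, i),
                               hyper = config$hyper %||% list())
    cur <- cal$ensembles[[1]]
    lin <- function(cells) (cells$col - 1) * grid$nrow + cells$row
    pres_scores <- cur$values[lin(train$cells)]
    pa_cells_all <- unique(do.call(rbind, lapply(c(pa_matched, pa_large),
                                                 function(p) p$cells[, c("row", "col")])))
    abs_scores <- cur$values[lin(pa_cells_all)]
    thr <- maxsensspec_threshold(pres_scores, abs_scores)
    for (sc in scen_names) {
      bin_maps[[sc]][[i]] <- binarize(cal$ensembles[[sc]], thr$threshold)
    }
    cur_bin <- bin_maps[[scen_names[1]]][[i]]
    p_i <- area_weighted_presence_proportion(cur_bin)
    success <- as.integer(cur_bin$values[lin(left_out)] == 1)
    rows[[i]] <- data.frame(
      replicate = i, left_out_row = left_out$row, left_out_col = left_out$col,
      threshold = thr$threshold, sensitivity = thr$sensitivity,
      specificity = thr$specificity, presence_proportion = p_i,
      success = success)
  }
  reps <- do.call(rbind, rows)
  D <- sum(reps$success)
  p_value <- if (identical(config$test %||% "poisson_binomial", "binomial")) {
    stats::pbinom(D - 1, n, mean(reps$presence_proportion),
                  lower.tail = FALSE)
  } else {
    poisson_binomial_pvalue(reps$presence_proportion, D)
  }
  structure(list(replicates = reps, n = n, D = D, p_value = p_value,
                 binary_maps = bin_maps),
            class = "jackknife_report")
}

#' @method print jackknife_report
#' @export
print.jackknife_report <- function(x, ...) {
  cat(sprintf("<jackknife_report> %d replicates, D = %d successes, exact p = %.4g\n",
              x$n, x$D, x$p_value))
  cat(sprintf("mean threshold %.3f, mean predicted-present proportion %.3f\n",
              mean(x$replicates$threshold),
              mean(x$replicates$presence_proportion)))
  invisible(x)
}

#' Write a jackknife report as CSV (rows) and JSON (summary)
#'
#' @param report a `jackknife_report`
#' @param csv_path,json_path output file paths (NULL to skip either)
#' @export
write_jackknife_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$replicates, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(n = report$n, D = report$D, p_value = report$p_value,
           mean_threshold = mean(report$replicates$threshold)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
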