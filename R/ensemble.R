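#' Ensemble calibration and suitability surfaces
#'
#' Each learner family is calibrated on every (pseudo-absence set, run)
#' combination; every fitted model predicts a continuous suitability
#' surface, and the ensemble is their unweighted per-cell arithmetic mean.
#' With the reference design of nine families, 10 PA sets and 10 runs this
#' is 900 models per jackknife replicate.
#'
#' @name ensemble_model
NULL

#' Assemble a presence/pseudo-absence training table
#'
#' @param presence_cells data.frame of presence (row, col)
#' @param pa_cells data.frame of pseudo-absence (row, col)
#' @param score_stack predictor [env_stack()] (retained PCA scores)
#' @return object of class `training_table`: data.frame with `response`
#'   (1/0) and one column per predictor, plus a `weights` attribute
#'   equalizing total class weights
#' @export
build_training_table <- function(presence_cells, pa_cells, score_stack) {
  cells <- rbind(presence_cells[, c("row", "col")],
                 pa_cells[, c("row", "col")])
  if (anyDuplicated(paste(cells$row, cells$col)))
    stop("duplicated cell between presences and pseudo-absences")
  y <- c(rep(1L, nrow(presence_cells)), rep(0L, nrow(pa_cells)))
  lin <- (cells$col - 1) * score_stack$grid$nrow + cells$row
  X <- vapply(score_stack$layers, function(m) m[lin], numeric(length(lin)))
  if (length(lin) == 1L)
    X <- matrix(X, nrow = 1, dimnames = list(NULL, names(score_stack$layers)))
  if (any(!is.finite(X)))
    stop("non-finite predictor values in training table (cell outside mask?)")
  if (length(unique(y)) < 2) stop("single class in training table")
  tab <- data.frame(response = y, X)
  w <- ifelse(y == 1, sum(y == 0) / sum(y == 1), 1)
  attr(tab, "weights") <- w
  class(tab) <- c("training_table", "data.frame")
  tab
}

#' Fit one learner on a training table
#'
#' Fitting is deterministic given the seed (stochastic learners are
#' reseeded; deterministic ones ignore it).
#'
#' @param table a [build_training_table()] result
#' @param family registered learner family name
#' @param seed integer RNG seed
#' @param hyper named list of family hyperparameter overrides
#' @return object of class `niche_model`
#' @export
fit_learner <- function(table, family, seed = 1, hyper = list()) {
  if (length(unique(table$response)) < 2) stop("single class in training table")
  entry <- get_learner(family)
  preds <- setdiff(names(table), "response")
  x <- as.matrix(table[, preds, drop = FALSE])
  fit <- entry$fit(x, table$response, attr(table, "weights"), seed, hyper)
  structure(list(family = toupper(family), fit = fit, predictors = preds,
                 seed = seed),
            class = "niche_model")
}

#' Predict presence probabilities for arbitrary predictor rows
#'
#' @param model a `niche_model`
#' @param newdata matrix or data.frame with the model's predictor columns
#' @return numeric vector of probabilities in [0, 1]
#' @export
predict_learner <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  missing_p <- setdiff(model$predictors, colnames(newdata))
  if (length(missing_p))
    stop("predictor mismatch; missing: ", paste(missing_p, collapse = ", "))
  x <- newdata[, model$predictors, drop = FALSE]
  p <- get_learner(model$family)$predict(model$fit, x)
  clamp01(as.numeric(p))
}

#' Predict a continuous suitability surface
#'
#' @param model a `niche_model` from [fit_learner()]
#' @param score_stack predictor [env_stack()] sharing the model's layers
#' @return object of class `suitability_map`: the grid, a values matrix in
#'   [0, 1] on valid cells (NA elsewhere), and a provenance character
#'   vector of contributing model identifiers
#' @export
predict_surface <- function(model, score_stack) {
  X <- stack_matrix(score_stack)
  p <- predict_learner(model, X)
  vals <- matrix(NA_real_, score_stack$grid$nrow, score_stack$grid$ncol)
  vals[attr(X, "cell_index")] <- p
  suitability_map(vals, score_stack$grid,
                  provenance = paste0(model$family, "#", model$seed),
                  scenario = score_stack$scenario)
}

#' Construct a suitability map
#'
#' @param values matrix of suitabilities in [0,1] (NA = NoData)
#' @param grid a [niche_grid()]
#' @param provenance character vector of contributing model ids
#' @param scenario scenario label
#' @return object of class `suitability_map`
#' @export
suitability_map <- function(values, grid, provenance = character(),
                            scenario = "current") {
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("suitability values outside [0, 1]")
  structure(list(values = values, grid = grid, provenance = provenance,
                 scenario = scenario),
            class = "suitability_map")
}

#' @method print suitability_map
#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> scenario '%s', %d x %d grid, %d contributing model(s), mean %.3f\n",
              x$scenario, x$grid$nrow, x$grid$ncol, length(x$provenance),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Unweighted per-cell mean of suitability maps
#'
#' @param maps list of `suitability_map`s on the same grid
#' @return a `suitability_map` whose provenance is the union of members'
#' @export
ensemble_mean <- function(maps) {
  stopifnot(length(maps) >= 1)
  g <- maps[[1]]$grid
  for (m in maps[-1])
    if (!grid_identical(m$grid, g)) stop("grid mismatch between member maps")
  vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  suitability_map(clamp01_keepna(vals), g,
                  provenance = unique(unlist(lapply(maps, `[[`, "provenance"))),
                  scenario = maps[[1]]$scenario)
}

clamp01_keepna <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }

#' Calibrate one jackknife replicate's ensemble
#'
#' Fits `|families| x |pa_sets| x n_runs` models on the training scenario
#' and predicts the ensemble-mean surface for every supplied scenario with
#' the same fitted models (so future projections correspond axis-for-axis
#' to the current fit). Presence-matched families (GBM, CTA, RF) train
#' against PA sets of presence-count size; the remaining families against
#' the large PA sets. Individual fit failures are skipped with a warning
#' and excluded from the mean.
#'
#' @param presence_cells data.frame of training presence (row, col)
#' @param pa_sets_matched,pa_sets_large lists of `pa_sample`s for the two
#'   PA-count designs (same length = number of PA sets)
#' @param score_stacks named list of predictor [env_stack()]s; the first is
#'   the training (current) scenario
#' @param families character vector of registered families
#' @param n_runs repeated calibration runs per PA set (runs differ only in
#'   the stochastic-learner seed)
#' @param seed_base integer from which all fit seeds are derived
#' @param hyper named list (by family) of hyperparameter overrides
#' @return list with `ensembles` (named list of `suitability_map`s, one
#'   per scenario), `n_models` fitted, `n_failed`, and `provenance`
#' @export
calibrate_replicate <- function(presence_cells, pa_sets_matched,
                                pa_sets_large, score_stacks, families,
                                n_runs = 10, seed_base = 1, hyper = list()) {
  stopifnot(length(score_stacks) >= 1, length(families) >= 1,
            length(pa_sets_matched) == length(pa_sets_large))
  scen_names <- names(score_stacks)
  if (is.null(scen_names) || any(!nzchar(scen_names))) {
    scen_names <- paste0("scenario", seq_along(score_stacks))
    names(score_stacks) <- scen_names
  }
  sums <- lapply(score_stacks, function(s)
    matrix(0, s$grid$nrow, s$grid$ncol))
  prov <- character()
  n_models <- 0L
  n_failed <- 0L
  for (fam in families) {
    matched <- toupper(fam) %in% PRESENCE_MATCHED_FAMILIES
    pa_sets <- if (matched) pa_sets_matched else pa_sets_large
    for (s in seq_along(pa_sets)) {
      tab <- build_training_table(presence_cells, pa_sets[[s]]$cells,
                                  score_stacks[[1]])
      for (r in seq_len(n_runs)) {
        seed <- derive_seed(seed_base, match(toupper(fam), LEARNER_FAMILIES),
                            s, r)
        res <- tryCatch({
          model <- fit_learner(tab, fam, seed = seed,
                               hyper = hyper[[toupper(fam)]] %||% list())
          lapply(score_stacks, function(st) predict_surface(model, st))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          warning("fit failed (", fam, ", set ", s, ", run ", r, "): ",
                  conditionMessage(res))
          n_failed <- n_failed + 1L
          next
        }
        for (sc in scen_names)
          sums[[sc]] <- sums[[sc]] + res[[sc]]$values
        prov <- c(prov, sprintf("%s/set%d/run%d", toupper(fam), s, r))
        n_models <- n_models + 1L
      }
    }
  }
  if (n_models == 0L) stop("all model fits failed")
  ensembles <- lapply(scen_names, function(sc) {
    vals <- sums[[sc]] / n_models
    vals[!score_stacks[[sc]]$mask] <- NA_real_
    suitability_map(clamp01_keepna(vals), score_stacks[[sc]]$grid,
                    provenance = prov, scenario = sc)
  })
  names(ensembles) <- scen_names
  list(ensembles = ensembles, n_models = n_models, n_failed = n_failed,
       provenance = prov)
}

# deterministic stage-seed derivation from a base seed (32-bit safe)
derive_seed <- function(base, ...) {
  x <- as.double(base) %% 2147483647
  for (k in c(...)) {
    x <- (x * 69069 + as.double(k) * 2654435761) %% 2147483647
  }
  as.integer(x %% 2147483562) + 1L
}
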