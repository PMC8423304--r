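# shared fixtures, built in code at test time

# small co-registered stack of hand-made layers on an equatorial grid
toy_grid <- function(nrow = 10, ncol = 10, cellsize = 1 / 12,
                     xmin = 0, ymax = nrow * cellsize / 2) {
  niche_grid(xmin = xmin, ymax = ymax, cellsize = cellsize,
             nrow = nrow, ncol = ncol)
}

toy_stack <- function(nrow = 10, ncol = 10, n_layers = 2, seed = 1,
                      grid = toy_grid(nrow, ncol)) {
  set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(i)
    matrix(stats::rnorm(nrow * ncol), nrow, ncol))
  names(layers) <- paste0("bio", sprintf("%02d", seq_len(n_layers)))
  env_stack(layers, grid, "current")
}

# the frozen study species of the validation experiments
strong_species <- function() virtual_species_spec(c(6, 3, 0, 0), -4)
null_species <- function() virtual_species_spec(c(0, 0, 0, 0), 0)

# predictor score stack for a virtual environment (6 climate + 2 edaphic axes)
score_stack_of <- function(venv, n_climate_axes = 6, n_edaphic_axes = 2) {
  clim <- fit_pca(subset_layers(venv, grep("^bio", names(venv$layers),
                                           value = TRUE)),
                  n_axes = n_climate_axes, score_prefix = "climPC")
  eda <- fit_pca(subset_layers(venv, grep("^eda", names(venv$layers),
                                          value = TRUE)),
                 n_axes = n_edaphic_axes, score_prefix = "edaPC")
  merge_score_stacks(clim$scores, eda$scores)
}

subset_layers <- function(stack, nms)
  env_stack(stack$layers[nms], stack$grid, stack$scenario)

merge_score_stacks <- function(a, b)
  env_stack(c(a$layers, b$layers), a$grid, a$scenario)

# thinned occurrence_set straight from a cells data.frame
occ_from_cells <- function(cells, grid) {
  ctr <- cell_centres(grid, cells$row, cells$col)
  structure(list(records = data.frame(longitude = ctr$longitude,
                                      latitude = ctr$latitude,
                                      source = "fixture"),
                 thinned = TRUE,
                 cells = data.frame(row = cells$row, col = cells$col,
                                    longitude = ctr$longitude,
                                    latitude = ctr$latitude)),
            class = "occurrence_set")
}

# brute-force Poisson-binomial tail by full 2^n enumeration
enumerate_pb_tail <- function(p, D) {
  n <- length(p)
  if (D == 0) return(1)
  bits <- as.matrix(expand.grid(rep(list(0:1), n)))
  probs <- apply(bits, 1, function(b) prod(ifelse(b == 1, p, 1 - p)))
  sum(probs[rowSums(bits) >= D])
}

# independent fine-grid scan for the MaxSensSpec optimum
grid_scan_best_sum <- function(pres, abs, step = 1e-4) {
  ts <- seq(0, 1 + step, by = step)
  sp <- sort(pres); sa <- sort(abs)
  sens <- 1 - findInterval(ts, sp, left.open = TRUE) / length(sp)
  spec <- findInterval(ts, sa, left.open = TRUE) / length(sa)
  max(sens + spec)
}

# direct-summation broken-stick oracle (independent of the implementation)
broken_stick_oracle <- function(props) {
  p <- length(props)
  n <- 0
  for (k in seq_len(p)) {
    bk <- 0
    for (i in k:p) bk <- bk + 1 / i
    bk <- bk / p
    if (props[k] > bk) n <- n + 1 else break
  }
  max(n, 1L)
}
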