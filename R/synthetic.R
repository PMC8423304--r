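#' Virtual-species fixtures
#'
#' The generator builds a self-contained virtual-species study: a current
#' environmental stack of mutually correlated "climate" and
#' "edaphic/topographic" layers on a small lon/lat grid, a species whose
#' true suitability is a logistic function of the *latent* environmental
#' factors (so the PCA step genuinely has a signal subspace to recover),
#' sparse presence records sampled from that suitability, and future
#' scenarios produced by a known shift of the climate block. Because the
#' truth is known, every pipeline stage can be validated by parameter
#' recovery without any external data.
#'
#' @name synthetic_data
NULL

# smooth Gaussian random field: iid noise blurred by repeated 3x3 box means
smooth_field <- function(nr, nc, passes = 6) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (i in seq_len(passes)) {
    p <- m[c(1, seq_len(nr - 1)), ]         # shift down (edge replicate)
    q <- m[c(seq_len(nr - 1) + 1, nr), ]    # shift up
    m <- (m + p + q) / 3
    p <- m[, c(1, seq_len(nc - 1))]
    q <- m[, c(seq_len(nc - 1) + 1, nc)]
    m <- (m + p + q) / 3
  }
  m
}

standardize_field <- function(m) (m - mean(m)) / stats::sd(m)

#' Generate a correlated current-scenario environmental stack
#'
#' Latent factors are smooth spatial surfaces (broad gradients, a
#' low-frequency wave and smoothed noise, standardized to zero mean / unit
#' variance). Each observed climate variable is a random linear mix of the
#' climate latent factors plus independent cell noise, then given its own
#' offset and scale so variables arrive in heterogeneous units; edaphic
#' variables mix two separate latent factors the same way. The defaults
#' emulate the shape of a 19-bioclim + 10-edaphic stack at 5 arc-min.
#'
#' @param n_rows,n_cols grid size (>= 10)
#' @param n_climate,n_edaphic observed variable counts per block
#' @param latent_dim number of climate latent factors (>= 1; the species
#'   lives on these)
#' @param noise_sd sd of the independent per-variable cell noise, relative
#'   to the unit-variance latent mix
#' @param seed RNG seed; the stack is bit-reproducible given it
#' @param xmin,ymax,cellsize grid placement (defaults: a 5 arc-min grid in
#'   south-western Amazonia)
#' @return object of class `c("virtual_env", "env_stack")`: a normal
#'   environmental stack that additionally carries the latent surfaces,
#'   the mixing matrices and per-variable offsets/scales, enabling
#'   ground-truth computations
#' @export
generate_env <- function(n_rows = 100, n_cols = 100, n_climate = 19,
                         n_edaphic = 10, latent_dim = 4, noise_sd = 0.3,
                         seed = 1, xmin = -65, ymax = -7, cellsize = 1 / 12) {
  stopifnot(n_rows >= 10, n_cols >= 10, latent_dim >= 1,
            n_climate >= 1, n_edaphic >= 0)
  set.seed(seed)
  u <- matrix(rep((seq_len(n_cols) - 0.5) / n_cols, each = n_rows),
              n_rows, n_cols)
  v <- matrix(rep((seq_len(n_rows) - 0.5) / n_rows, n_cols),
              n_rows, n_cols)
  make_latent <- function() {
    a <- stats::rnorm(2, 0, 0.7)
    fr <- stats::runif(2, 0.5, 1.5); ph <- stats::runif(1)
    standardize_field(a[1] * u + a[2] * v +
                        0.5 * sin(2 * pi * (fr[1] * u + fr[2] * v + ph)) +
                        1.4 * smooth_field(n_rows, n_cols))
  }
  latents <- lapply(seq_len(latent_dim), function(k) make_latent())
  n_eda_latent <- if (n_edaphic > 0) 2L else 0L
  eda_latents <- lapply(seq_len(n_eda_latent), function(k) make_latent())

  mix_block <- function(n_var, lat, prefix) {
    M <- matrix(stats::rnorm(n_var * length(lat)), n_var, length(lat))
    offs <- stats::rnorm(n_var, 0, 50)
    scls <- exp(stats::rnorm(n_var, 0, 1))
    layers <- lapply(seq_len(n_var), function(j) {
      base <- Reduce(`+`, Map(function(L, m) m * L, lat, M[j, ]))
      offs[j] + scls[j] *
        (base + noise_sd * matrix(stats::rnorm(n_rows * n_cols),
                                  n_rows, n_cols))
    })
    names(layers) <- sprintf("%s%02d", prefix, seq_len(n_var))
    list(layers = layers, mixing = M, offset = offs, scale = scls)
  }
  clim <- mix_block(n_climate, latents, "bio")
  eda <- if (n_edaphic > 0) mix_block(n_edaphic, eda_latents, "eda") else
    list(layers = list(), mixing = NULL, offset = NULL, scale = NULL)

  grid <- niche_grid(xmin, ymax, cellsize, n_rows, n_cols)
  stack <- env_stack(c(clim$layers, eda$layers), grid, "current")
  stack$latents <- latents
  stack$eda_latents <- eda_latents
  stack$mixing <- clim$mixing
  stack$var_offset <- clim$offset
  stack$var_scale <- clim$scale
  stack$climate_names <- names(clim$layers)
  stack$edaphic_names <- names(eda$layers)
  stack$latent_delta <- rep(0, latent_dim)
  stack$seed <- seed
  class(stack) <- c("virtual_env", "env_stack")
  stack
}

#' A per-variable climate scenario shift
#'
#' @param shift_sd named numeric vector: additive shift for each climate
#'   variable, in sd units of the corresponding current layer
#' @param label scenario label
#' @param latent_delta optional latent-factor displacement that generated
#'   the shift (carried so ground truth stays computable)
#' @return object of class `scenario_shift`
#' @export
scenario_shift <- function(shift_sd, label = "future",
                           latent_delta = NULL) {
  stopifnot(is.numeric(shift_sd), !is.null(names(shift_sd)))
  structure(list(shift_sd = shift_sd, label = label,
                 latent_delta = latent_delta),
            class = "scenario_shift")
}

#' Build a climate shift from a latent-factor displacement
#'
#' Displacing latent factor k by `delta[k]` moves observed climate
#' variable j by `scale_j * (M delta)_j` raw units; expressed in sd units
#' of the current layers this is a plain per-variable additive shift, but
#' the latent displacement is retained so the species' true suitability
#' remains computable on the shifted scenario.
#'
#' @param venv a `virtual_env` from [generate_env()]
#' @param delta numeric displacement per climate latent factor
#' @param label scenario label
#' @return a [scenario_shift()]
#' @export
latent_shift <- function(venv, delta, label = "future") {
  stopifnot(inherits(venv, "virtual_env"),
            length(delta) == length(venv$latents))
  raw <- as.numeric(venv$mixing %*% delta) * venv$var_scale
  sds <- vapply(venv$layers[venv$climate_names],
                function(m) stats::sd(m[venv$mask]), numeric(1))
  scenario_shift(stats::setNames(raw / sds, venv$climate_names),
                 label = label, latent_delta = delta)
}

#' Apply a scenario shift to a stack
#'
#' Shifted climate layers, bit-identical edaphic/topographic layers
#' (geological change is not expected on the projection horizon), same
#' grid and mask.
#'
#' @param stack an [env_stack()] (or `virtual_env`)
#' @param shift a [scenario_shift()]
#' @return a stack of the same class, scenario set to the shift's label
#' @export
apply_shift <- function(stack, shift) {
  stopifnot(inherits(shift, "scenario_shift"))
  out <- stack
  for (nm in names(shift$shift_sd)) {
    if (!nm %in% names(out$layers)) stop("no such climate layer: ", nm)
    lay <- out$layers[[nm]]
    out$layers[[nm]] <- lay + shift$shift_sd[[nm]] *
      stats::sd(lay[stack$mask])
  }
  out$scenario <- shift$label
  if (inherits(stack, "virtual_env")) {
    if (!is.null(shift$latent_delta)) {
      out$latent_delta <- stack$latent_delta + shift$latent_delta
    } else {
      out$latents <- NULL  # truth no longer computable
    }
  }
  out
}

#' Define a virtual species
#'
#' True suitability is `plogis(intercept + sum_k weights[k] * latent_k)`;
#' the latent factors are the generator's standardized climate factors, so
#' a weight of w means an odds ratio of `exp(w)` per latent-factor
#' standard deviation.
#'
#' @param weights numeric weight per climate latent factor
#' @param intercept baseline log-odds
#' @return object of class `virtual_species`
#' @export
virtual_species_spec <- function(weights, intercept = 0) {
  stopifnot(is.numeric(weights), length(weights) >= 1)
  structure(list(weights = weights, intercept = intercept),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' @param species a [virtual_species_spec()]
#' @param venv a `virtual_env` (current or latent-shifted future)
#' @return matrix of suitabilities in (0, 1)
#' @export
true_suitability <- function(species, venv) {
  stopifnot(inherits(venv, "virtual_env"))
  if (is.null(venv$latents))
    stop("stack carries no latent surfaces (non-latent shift applied?)")
  stopifnot(length(species$weights) == length(venv$latents))
  eta <- species$intercept
  for (k in seq_along(venv$latents))
    eta <- eta + species$weights[k] *
      (venv$latents[[k]] + venv$latent_delta[k])
  stats::plogis(eta)
}

#' Sample presence records from the true suitability
#'
#' Valid cells are drawn without replacement with probability proportional
#' to true suitability; one record is placed at each drawn cell's centre,
#' optionally jittered inside the cell.
#'
#' @param species a [virtual_species_spec()]
#' @param venv a `virtual_env`
#' @param n number of presence cells to draw
#' @param seed RNG seed
#' @param jitter fraction of a cell (0..0.49) to jitter records off-centre
#' @return an `occurrence_set` of raw records
#' @export
sample_presences <- function(species, venv, n, seed = 1, jitter = 0) {
  stopifnot(n >= 1, jitter >= 0, jitter < 0.5)
  suit <- true_suitability(species, venv)
  idx <- which(venv$mask & suit > 0)
  if (n > length(idx))
    stop("n exceeds the ", length(idx), " cells with positive suitability")
  set.seed(seed)
  take <- idx[sample.int(length(idx), n, prob = suit[idx])]
  rows <- ((take - 1) %% venv$grid$nrow) + 1
  cols <- ((take - 1) %/% venv$grid$nrow) + 1
  ctr <- cell_centres(venv$grid, rows, cols)
  if (jitter > 0) {
    ctr$longitude <- ctr$longitude +
      stats::runif(n, -jitter, jitter) * venv$grid$cellsize
    ctr$latitude <- ctr$latitude +
      stats::runif(n, -jitter, jitter) * venv$grid$cellsize
  }
  structure(list(records = data.frame(longitude = ctr$longitude,
                                      latitude = ctr$latitude,
                                      source = "virtual",
                                      stringsAsFactors = FALSE),
                 thinned = FALSE, cells = NULL),
            class = "occurrence_set")
}

#' Ground-truth suitable area of a virtual species
#'
#' @param species a [virtual_species_spec()]
#' @param venv a `virtual_env`
#' @param cutoff suitability cutoff defining "suitable"
#' @return area in km^2 of cells with true suitability >= cutoff
#' @export
true_suitable_area <- function(species, venv, cutoff = 0.5) {
  suit <- true_suitability(species, venv)
  v <- ifelse(suit >= cutoff, 1, 0)
  v[!venv$mask] <- NA
  suitable_area_km2(binary_map(v, venv$grid, threshold = cutoff,
                               scenario = venv$scenario))
}

#' Find the latent shift producing a target fractional area loss
#'
#' Searches (by root finding) for a displacement along the species' weight
#' direction whose true suitable area equals `(1 - f)` times the current
#' true suitable area. Used to set up known-loss recovery experiments.
#'
#' @param species a [virtual_species_spec()]
#' @param venv the current `virtual_env`
#' @param f target fractional loss of true suitable area (0 < f < 1)
#' @param cutoff suitability cutoff
#' @param label scenario label for the resulting shift
#' @return a [scenario_shift()] whose `latent_delta` achieves the loss
#' @export
shift_for_loss <- function(species, venv, f, cutoff = 0.5,
                           label = sprintf("loss%.0f", 100 * f)) {
  stopifnot(f > 0, f < 1)
  dir <- species$weights / sqrt(sum(species$weights^2))
  a0 <- true_suitable_area(species, venv, cutoff)
  if (a0 <= 0) stop("species has no suitable area at this cutoff")
  area_at <- function(d) {
    shifted <- venv
    shifted$latent_delta <- venv$latent_delta + d * dir
    true_suitable_area(species, shifted, cutoff)
  }
  root <- stats::uniroot(function(d) area_at(d) - (1 - f) * a0,
                         lower = -40, upper = 0, tol = 1e-4)
  latent_shift(venv, root$root * dir, label = label)
}
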