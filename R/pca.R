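#' Principal component reduction of environmental blocks
#'
#' Environmental variables mix units (temperature, precipitation, soil
#' fractions, elevation), so components are always extracted from the
#' correlation matrix: each variable is standardized to zero mean and unit
#' variance over the valid cells before the rotation is fitted. The fitted
#' transform (means, sds, loadings, retained-axis count) is reusable on a
#' future-scenario stack of the same variables, so current and future
#' scores live on corresponding axes.
#'
#' @name pca_transform
NULL

#' Broken-stick selection of the number of PCA axes
#'
#' Under the broken-stick null model, the expected proportion of variance
#' for axis k of p is `b_k = (1/p) * sum_{i=k..p} 1/i`. Axes are retained
#' while the observed proportion strictly exceeds `b_k`; the count is the
#' length of that leading run, with a floor of one axis.
#'
#' @param eigenvalue_proportions non-increasing vector of variance
#'   proportions summing to ~1
#' @return integer number of axes to retain (>= 1)
#' @export
broken_stick_select <- function(eigenvalue_proportions) {
  p <- length(eigenvalue_proportions)
  if (p == 0) stop("empty eigenvalue proportions")
  bk <- rev(cumsum(rev(1 / seq_len(p)))) / p
  above <- eigenvalue_proportions > bk
  if (!above[1]) return(1L)
  first_fail <- which(!above)
  if (length(first_fail) == 0) return(as.integer(p))
  as.integer(first_fail[1] - 1L)
}

#' Fit a correlation-matrix PCA on an environmental stack
#'
#' @param stack an [env_stack()] with >= 2 layers and >= 2 valid cells
#' @param n_axes fixed integer count, or `"broken_stick"` to apply
#'   [broken_stick_select()] to the eigenvalue spectrum
#' @param block_label tag for the variable block (e.g. `"climate"`)
#' @param score_prefix prefix for score layer names (default `"PC"`)
#' @return list with `transform` (class `pca_transform`: standardization
#'   constants, full orthonormal loading matrix, eigenvalue proportions,
#'   `n_retained`) and `scores` (an [env_stack()] of the retained component
#'   score layers on the input grid)
#' @export
fit_pca <- function(stack, n_axes = "broken_stick", block_label = "climate",
                    score_prefix = "PC") {
  X <- stack_matrix(stack)
  if (nrow(X) < 2) stop("need >= 2 valid cells to fit a PCA")
  if (ncol(X) < 2) stop("need >= 2 layers to fit a PCA")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant layer (zero variance): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  props <- pr$sdev^2 / sum(pr$sdev^2)
  k <- if (identical(n_axes, "broken_stick")) {
    broken_stick_select(props)
  } else {
    n_axes <- as.integer(n_axes)
    if (is.na(n_axes) || n_axes < 1) stop("n_axes must be >= 1 or 'broken_stick'")
    min(n_axes, ncol(X))
  }
  transform <- structure(
    list(block_label = block_label,
         variable_names = colnames(X),
         variable_means = pr$center,
         variable_sds = pr$scale,
         loadings = pr$rotation,
         eigenvalue_proportions = props,
         n_retained = as.integer(k),
         score_prefix = score_prefix),
    class = "pca_transform"
  )
  scores <- pr$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0(score_prefix, seq_len(k))
  score_stack <- env_stack(matrix_to_layers(scores, stack), stack$grid,
                           stack$scenario)
  list(transform = transform, scores = score_stack)
}

#' @method print pca_transform
#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("<pca_transform> block '%s': %d variables, %d retained axes (%.1f%% of variance)\n",
              x$block_label, length(x$variable_names), x$n_retained,
              100 * sum(x$eigenvalue_proportions[seq_len(x$n_retained)])))
  invisible(x)
}

#' Project a fitted PCA onto another scenario's stack
#'
#' Applies the current-scenario standardization constants and loading
#' matrix to a future stack of the same variables, without re-fitting, so
#' the axes keep their meaning across scenarios. On the training stack
#' itself this reproduces the fitted scores exactly.
#'
#' @param transform a `pca_transform` from [fit_pca()]
#' @param stack an [env_stack()] carrying exactly the transform's variables
#' @return an [env_stack()] of `n_retained` score layers
#' @export
project_transform <- function(transform, stack) {
  have <- names(stack$layers)
  want <- transform$variable_names
  missing_v <- setdiff(want, have)
  extra_v <- setdiff(have, want)
  if (length(missing_v) || length(extra_v))
    stop("variable mismatch; missing: [",
         paste(missing_v, collapse = ", "), "], unexpected: [",
         paste(extra_v, collapse = ", "), "]")
  X <- stack_matrix(stack)[, want, drop = FALSE]
  Z <- sweep(sweep(X, 2, transform$variable_means, "-"),
             2, transform$variable_sds, "/")
  k <- transform$n_retained
  scores <- Z %*% transform$loadings[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0(transform$score_prefix, seq_len(k))
  env_stack(matrix_to_layers(scores, stack), stack$grid, stack$scenario)
}

# merge score stacks of several variable blocks into one predictor stack
combine_stacks <- function(stacks) {
  stopifnot(length(stacks) >= 1)
  g <- stacks[[1]]$grid
  for (s in stacks[-1])
    if (!grid_identical(s$grid, g)) stop("grid mismatch between score stacks")
  env_stack(do.call(c, lapply(stacks, function(s) s$layers)), g,
            stacks[[1]]$scenario)
}
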