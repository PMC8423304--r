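#' Co-registered environmental raster stacks
#'
#' An `env_stack` holds one scenario's environmental layers on a shared
#' lon/lat grid. Layers are `nrow x ncol` numeric matrices (row 1 = north)
#' with `NA` marking missing data; the stack's valid-cell mask is the
#' intersection of the per-layer valid cells, and every layer is masked to
#' it, so a cell invalid in any variable is invalid everywhere downstream.
#'
#' @param layers named list of numeric matrices with identical dimensions
#' @param grid a [niche_grid()] matching those dimensions
#' @param scenario_label free-text scenario tag (e.g. "current")
#' @return an object of class `env_stack` with fields `layers`, `grid`,
#'   `mask` (logical matrix) and `scenario`
#' @export
env_stack <- function(layers, grid, scenario_label = "current") {
  stopifnot(is.list(layers), length(layers) >= 1)
  nms <- names(layers)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("all layers must be named")
  if (anyDuplicated(nms))
    stop("duplicate layer name: ", nms[duplicated(nms)][1])
  for (nm in nms) {
    d <- dim(layers[[nm]])
    if (is.null(d) || d[1] != grid$nrow || d[2] != grid$ncol)
      stop("grid mismatch: layer '", nm, "' is ",
           paste(d, collapse = "x"), ", expected ",
           grid$nrow, "x", grid$ncol)
  }
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  layers <- lapply(layers, function(m) { m[!mask] <- NA_real_; m })
  structure(
    list(layers = layers, grid = grid, mask = mask,
         scenario = scenario_label),
    class = "env_stack"
  )
}

#' @method print env_stack
#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> scenario '%s': %d layers on a %d x %d grid, %d valid cells\n",
              x$scenario, length(x$layers), x$grid$nrow, x$grid$ncol,
              sum(x$mask)))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

n_layers <- function(stack) length(stack$layers)

#' Extract the valid-cell data matrix of a stack
#'
#' @param stack an [env_stack()]
#' @return numeric matrix, one row per valid cell (in `which(mask)` order),
#'   one named column per layer; the linear cell indices are attached as
#'   attribute `"cell_index"`
#' @export
stack_matrix <- function(stack) {
  idx <- which(stack$mask)
  m <- vapply(stack$layers, function(l) l[idx], numeric(length(idx)))
  if (length(idx) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  attr(m, "cell_index") <- idx
  m
}

# rebuild a named list of masked layer matrices from a valid-cell matrix
matrix_to_layers <- function(values, stack) {
  idx <- which(stack$mask)
  out <- lapply(seq_len(ncol(values)), function(j) {
    m <- matrix(NA_real_, stack$grid$nrow, stack$grid$ncol)
    m[idx] <- values[, j]
    m
  })
  names(out) <- colnames(values)
  out
}

#' Read an ESRI ASCII grid raster
#'
#' Parses the plain-text `.asc` single-band raster format (ncols/nrows/
#' xllcorner/yllcorner/cellsize/NODATA_value header followed by rows of
#' values, northernmost row first).
#'
#' @param path path to a `.asc` file
#' @return list with `values` (matrix, NA for NoData) and `grid`
#' @export
read_asc <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("missing header field '", k, "' in ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = line, quiet = TRUE)
  vals <- c(vals, scan(con, quiet = TRUE))
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values in ", path, ", found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid <- niche_grid(xmin = hdr$xllcorner,
                     ymax = hdr$yllcorner + nr * hdr$cellsize,
                     cellsize = hdr$cellsize, nrow = nr, ncol = nc)
  list(values = m, grid = grid)
}

#' Write an ESRI ASCII grid raster
#'
#' @param values numeric matrix (row 1 = north); NA written as NoData
#' @param grid a [niche_grid()]
#' @param path output path
#' @param nodata NoData sentinel value
#' @export
write_asc <- function(values, grid, path, nodata = -9999) {
  hdr <- c(
    paste("ncols", grid$ncol),
    paste("nrows", grid$nrow),
    paste("xllcorner", format(grid$xmin, digits = 15)),
    paste("yllcorner", format(grid$ymax - grid$nrow * grid$cellsize, digits = 15)),
    paste("cellsize", format(grid$cellsize, digits = 15)),
    paste("NODATA_value", nodata)
  )
  v <- values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(format(r, digits = 10, trim = TRUE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
}

#' Read and co-register a set of single-band rasters into a stack
#'
#' All files must already share grid geometry (resampling and reprojection
#' are preprocessing, not pipeline steps). Layer names are the file base
#' names without extension. The stack's valid-cell mask is the intersection
#' of the per-layer valid cells.
#'
#' @param paths character vector of `.asc` raster paths
#' @param scenario_label scenario tag for the stack
#' @return an [env_stack()]
#' @export
read_stack <- function(paths, scenario_label = "current") {
  stopifnot(length(paths) >= 1)
  nms <- sub("\\.[^.]+$", "", basename(paths))
  if (anyDuplicated(nms))
    stop("duplicate layer name: ", nms[duplicated(nms)][1])
  first <- read_asc(paths[1])
  layers <- list(first$values)
  for (i in seq_along(paths)[-1]) {
    r <- read_asc(paths[i])
    if (!grid_identical(r$grid, first$grid))
      stop("grid mismatch: layer '", nms[i], "' does not match '", nms[1], "'")
    layers[[i]] <- r$values
  }
  names(layers) <- nms
  env_stack(layers, first$grid, scenario_label)
}

#' Write every layer of a stack as ESRI ASCII grids
#'
#' @param stack an [env_stack()]
#' @param dir output directory (created if needed)
#' @return invisibly, the written paths
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(stack$layers), ".asc"))
  for (i in seq_along(paths))
    write_asc(stack$layers[[i]], stack$grid, paths[i])
  invisible(paths)
}
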