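#' Grid and zonal-statistics helpers
#'
#' Rasters in this package are plain numeric matrices (one year) or 3-D arrays
#' with dimensions (row, col, year) and the third dimname set to calendar
#' years. Cells are row-major, north-up, centre-registered; a cell belongs to
#' the admin unit covering its centre. These helpers provide the zonal
#' arithmetic every stage relies on.
#'
#' @name grids
NULL

#' Zonal sum of a raster over labelled units
#'
#' @param values numeric matrix, same shape as `labels`.
#' @param labels integer matrix of unit ids; `NA` cells are skipped.
#' @return named numeric vector, one element per unit id present in `labels`.
#' @export
zonal_sum <- function(values, labels) {
  stopifnot(all(dim(values) == dim(labels)))
  keep <- !is.na(labels) & !is.na(values)
  s <- rowsum(as.numeric(values[keep]), group = as.integer(labels[keep]))
  stats::setNames(as.numeric(s), rownames(s))
}

#' Zonal mean (optionally weighted) of a raster over labelled units
#'
#' @param values numeric matrix.
#' @param labels integer matrix of unit ids.
#' @param weights optional non-negative weight matrix (e.g. population); when
#'   supplied the weighted mean `sum(w*v)/sum(w)` is returned per unit.
#' @return named numeric vector of per-unit means.
#' @export
zonal_mean <- function(values, labels, weights = NULL) {
  if (is.null(weights)) {
    n <- zonal_sum(array(1, dim(values)), labels)
    zonal_sum(values, labels) / n
  } else {
    stopifnot(all(dim(weights) == dim(values)))
    sw <- zonal_sum(weights, labels)
    swv <- zonal_sum(values * weights, labels)
    swv / sw
  }
}

#' Geometric centroids of labelled units (in cell coordinates)
#'
#' @param labels integer matrix of unit ids.
#' @return data.frame with columns `unit_id`, `row`, `col` (mean cell indices).
#' @export
unit_centroids <- function(labels) {
  idx <- which(!is.na(labels), arr.ind = TRUE)
  ids <- labels[!is.na(labels)]
  data.frame(
    unit_id = as.integer(names(zonal_sum(labels * 0, labels))),
    row = as.numeric(tapply(idx[, 1], ids, mean)),
    col = as.numeric(tapply(idx[, 2], ids, mean)),
    row.names = NULL
  )
}

#' Rook adjacency among labelled units
#'
#' Two units are neighbours when at least one pair of edge-sharing cells
#' carries their two labels.
#'
#' @param labels integer matrix of unit ids.
#' @return named list: for each unit id (as character), an integer vector of
#'   neighbouring unit ids.
#' @export
neighbours_from_labels <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-h, ]), as.vector(labels[-1, ])),   # vertical
    cbind(as.vector(labels[, -w]), as.vector(labels[, -1]))    # horizontal
  )
  pairs <- pairs[!is.na(pairs[, 1]) & !is.na(pairs[, 2]) &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- unique(rbind(pairs, pairs[, 2:1, drop = FALSE]))
  ids <- sort(unique(as.vector(labels[!is.na(labels)])))
  out <- lapply(ids, function(i) sort(unique(pairs[pairs[, 1] == i, 2])))
  names(out) <- as.character(ids)
  out
}

#' Smooth a matrix with a separable Gaussian kernel
#'
#' Edge cells are renormalized by the kernel mass actually inside the grid, so
#' a constant field is exactly preserved.
#'
#' @param mat numeric matrix.
#' @param sigma kernel standard deviation in cells.
#' @return smoothed matrix, same dimensions.
#' @export
smooth_field <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    pv <- c(rep(0, r), v, rep(0, r))
    p1 <- c(rep(0, r), rep(1, n), rep(0, r))
    num <- stats::filter(pv, k, sides = 2)
    den <- stats::filter(p1, k, sides = 2)
    as.numeric(num / den)[(r + 1):(r + n)]
  }
  tmp <- apply(mat, 2, conv1)
  t(apply(tmp, 1, conv1))
}

#' Constructor for an annual raster stack
#'
#' @param data numeric vector/array of length `h*w*length(years)`.
#' @param h,w grid dimensions.
#' @param years calendar years for the third dimension.
#' @return 3-D array (row, col, year) with year dimnames.
#' @export
raster_stack <- function(data, h, w, years) {
  array(data, dim = c(h, w, length(years)),
        dimnames = list(NULL, NULL, as.character(years)))
}

#' Extract one year's matrix from a stack
#' @param stack 3-D array with year dimnames.
#' @param year calendar year (coerced to character).
#' @return numeric matrix.
#' @export
year_slice <- function(stack, year) {
  stack[, , as.character(year)]
}

# internal: extract one year's slice without dropping the grid dimensions
slice2d <- function(stack, year) {
  m <- stack[, , as.character(year), drop = FALSE]
  dim(m) <- dim(stack)[1:2]
  m
}

# internal: check that a set of rasters share geometry
check_coregistered <- function(...) {
  dims <- lapply(list(...), function(x) dim(x)[1:2])
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("rasters are not co-registered (differing grid dimensions)")
  invisible(TRUE)
}
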