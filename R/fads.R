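#' Frame preprocessing: pair averaging and last-frame removal
#'
#' 32-frame acquisitions are reduced to 16 frames by averaging
#' non-overlapping consecutive pairs (1&2, 3&4, ..., 31&32); the final frame
#' is then dropped (beat-window variability degrades it), so the result
#' always has 15 frames. 16-frame acquisitions only lose their last frame.
#'
#' @param series A [gated_series()] with 16 or 32 frames.
#' @return A [gated_series()] with 15 real-valued frames.
#' @export
preprocess_frames <- function(series) {
  stopifnot(inherits(series, "gated_series"))
  k <- series$frames
  if (!k %in% c(16L, 32L))
    stopf("preprocess_frames expects 16 or 32 frames, got %d", k)
  x <- series$counts
  if (k == 32L) {
    odd <- seq(1, 31, by = 2)
    x <- (x[odd, , , drop = FALSE] + x[odd + 1, , , drop = FALSE]) / 2
  }
  x <- x[seq_len(dim(x)[1] - 1L), , , drop = FALSE]
  out <- series
  out$counts <- x
  out$frames <- dim(x)[1]
  if (!is.na(series$frame_duration_ms) && k == 32L)
    out$frame_duration_ms <- series$frame_duration_ms * 2
  # retained frames cover 15/16 of the R-R interval; phase angles measured
  # by a DFT over them are in window degrees, not cardiac-cycle degrees
  out$meta$cycle_fraction <- (series$meta$cycle_fraction %||% 1) * 15 / 16
  out
}

#' Build the pixel-by-frame time-activity matrix
#'
#' Row `p` of `X` is the time-activity curve of pixel `(i, j)` with
#' `p = (i - 1) * N + j` under 1-based indices (`N` = number of columns);
#' each column holds one whole frame.
#'
#' @param series A [gated_series()] with at least 2 frames.
#' @return Object of class `tac_matrix`: list with `X` (`P x Q`), `grid`.
#' @export
build_tac_matrix <- function(series) {
  stopifnot(inherits(series, "gated_series"))
  if (series$frames < 2) stopf("need at least 2 frames")
  k <- series$frames
  X <- vapply(seq_len(k), function(q) as.vector(t(series$counts[q, , ])),
              numeric(prod(series$grid)))
  structure(list(X = X, grid = series$grid), class = "tac_matrix")
}

#' Rebuild image frames from a TAC matrix
#'
#' Inverse of [build_tac_matrix()].
#'
#' @param tac A `tac_matrix` (or a plain `P x Q` matrix plus `grid`).
#' @param grid Image grid, taken from `tac` when available.
#' @return A `k x rows x cols` array.
#' @export
tac_to_frames <- function(tac, grid = NULL) {
  X <- if (inherits(tac, "tac_matrix")) tac$X else tac
  grid <- grid %||% tac$grid
  k <- ncol(X)
  arr <- array(0, c(k, grid[1], grid[2]))
  for (q in seq_len(k))
    arr[q, , ] <- matrix(X[, q], grid[1], grid[2], byrow = TRUE)
  arr
}

# Stable ordering for ties: among exactly equal eigenvalues, order columns
# by their first differing coefficient entry (descending), so repeated
# decompositions of the same data agree element for element.
order_tied_columns <- function(lambda, C) {
  groups <- split(seq_along(lambda), match(lambda, unique(lambda)))
  unlist(lapply(groups, function(g) {
    if (length(g) < 2) return(g)
    key <- apply(C[, g, drop = FALSE], 2, paste, collapse = ",")
    g[order(key, decreasing = TRUE)]
  }), use.names = FALSE)
}

#' Factor analysis of dynamic structures (FADS)
#'
#' Eigen-decomposition of the TAC matrix `X` into temporal coefficient
#' curves and spatial factor images, `X = Gamma %*% t(C)`. In the default
#' uncentered mode, `C` holds the eigenvectors of the frame-by-frame second
#' moment matrix `t(X) %*% X` and the reconstruction identity is exact; in
#' centered mode the per-frame (column) means are removed first and stored
#' so reconstruction adds them back.
#'
#' Eigenvalues are sorted nonincreasing; each coefficient column's sign is
#' fixed so its largest-magnitude element is positive, making the curves
#' reproducible features.
#'
#' @param tac A `tac_matrix` from [build_tac_matrix()].
#' @param mode `"uncentered"` (default) or `"centered"`.
#' @return Object of class `fads_result`: `coefficients` (`Q x Q`
#'   orthonormal `C`), `factors` (`P x Q` `Gamma`), `eigenvalues`,
#'   `contributions` (percent of eigenvalue mass, summing to 100), `center`
#'   (column means, centered mode only), `grid`, `mode`.
#' @export
fads_decompose <- function(tac, mode = c("uncentered", "centered")) {
  stopifnot(inherits(tac, "tac_matrix"))
  mode <- match.arg(mode)
  X <- tac$X
  if (ncol(X) < 2) stopf("need at least 2 frames (columns)")
  if (any(!is.finite(X))) stopf("TAC matrix contains non-finite entries")
  center <- NULL
  if (mode == "centered") {
    center <- colMeans(X)
    X <- sweep(X, 2, center)
  }
  e <- eigen(crossprod(X), symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  C <- e$vectors
  ord <- order_tied_columns(lambda, C)
  lambda <- lambda[ord]
  C <- C[, ord, drop = FALSE]
  # sign convention: largest-magnitude element of each column positive
  for (j in seq_len(ncol(C))) {
    i <- which.max(abs(C[, j]))
    if (C[i, j] < 0) C[, j] <- -C[, j]
  }
  total <- sum(lambda)
  contributions <- if (total > 0) 100 * lambda / total else
    rep(NA_real_, length(lambda))
  structure(list(coefficients = C, factors = X %*% C, eigenvalues = lambda,
                 contributions = contributions, eigenvalue_total = total,
                 center = center, grid = tac$grid, mode = mode),
            class = "fads_result")
}

#' Reconstruct the TAC matrix from a FADS result
#'
#' @param result A `fads_result`.
#' @return The reconstructed `P x Q` matrix (`Gamma %*% t(C)`, plus the
#'   stored column means in centered mode).
#' @export
fads_reconstruct <- function(result) {
  stopifnot(inherits(result, "fads_result"))
  X <- result$factors %*% t(result$coefficients)
  if (!is.null(result$center)) X <- sweep(X, 2, result$center, `+`)
  X
}

#' Cumulative factor contribution
#'
#' Percentage of total eigenvalue mass carried by the `top_k` leading
#' factors.
#'
#' @param result A `fads_result` (possibly truncated by [top_factors()]).
#' @param top_k Number of leading factors, `1 <= top_k <= Q`.
#' @return A single percentage.
#' @export
factor_contributions <- function(result, top_k) {
  stopifnot(inherits(result, "fads_result"))
  if (top_k < 1 || top_k > length(result$contributions))
    stopf("top_k must be between 1 and %d", length(result$contributions))
  if (is.na(result$eigenvalue_total) || result$eigenvalue_total <= 0)
    stopf("degenerate series: all-zero eigenvalue spectrum")
  100 * sum(result$eigenvalues[seq_len(top_k)]) / result$eigenvalue_total
}

#' Restrict a FADS result to its leading factors
#'
#' Keeps the `k` most significant coefficient curves, factor images and
#' eigenvalues. Contributions stay expressed against the full spectrum (not
#' renormalized), so [factor_contributions()] remains consistent.
#'
#' @param result A `fads_result`.
#' @param k Number of factors to keep (default 3, the dominant-information
#'   subset used by the severity classifier).
#' @return A truncated `fads_result`.
#' @export
top_factors <- function(result, k = 3) {
  stopifnot(inherits(result, "fads_result"))
  if (k > length(result$eigenvalues))
    stopf("k = %d exceeds the %d available factors", k,
          length(result$eigenvalues))
  out <- result
  keep <- seq_len(k)
  out$coefficients <- result$coefficients[, keep, drop = FALSE]
  out$factors <- result$factors[, keep, drop = FALSE]
  out$eigenvalues <- result$eigenvalues[keep]
  out$contributions <- result$contributions[keep]
  out
}

#' Render a factor image as a matrix
#'
#' @param result A `fads_result` carrying the source grid.
#' @param j Factor index.
#' @return A `rows x cols` matrix of factor loadings.
#' @export
factor_image <- function(result, j) {
  stopifnot(inherits(result, "fads_result"))
  matrix(result$factors[, j], result$grid[1], result$grid[2], byrow = TRUE)
}
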