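#' Per-subject feature vector for the severity cascade
#'
#' Concatenates the three clinical covariates with two FADS coefficient
#' curves from the subject's own decomposition: curves 1 and 2 for the
#' intra-LV (`iLV`) axis, curves 2 and 3 for the interventricular (`LVRV`)
#' axis. With the default 15 retained frames the vector has
#' `3 + 2 * 15 = 33` entries, laid out
#' `[lvef, qrs, pr, curve_a(1..Q), curve_b(1..Q)]`. Values are raw here;
#' scaling is the normalizer's job ([fit_normalizer()]).
#'
#' @param record One-row data frame or list with `lvef` (percent), `qrs_ms`
#'   and `pr_ms`.
#' @param fads A `fads_result` with at least 3 coefficient curves.
#' @param axis `"iLV"` or `"LVRV"`.
#' @return Named numeric vector with attribute `axis`.
#' @export
build_feature_vector <- function(record, fads, axis = c("iLV", "LVRV")) {
  axis <- match.arg(axis)
  stopifnot(inherits(fads, "fads_result"))
  if (ncol(fads$coefficients) < 3)
    stopf("FADS result must retain at least 3 coefficient curves")
  for (f in c("lvef", "qrs_ms", "pr_ms")) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v))
      stopf("missing clinical value: %s", f)
  }
  idx <- if (axis == "iLV") c(1L, 2L) else c(2L, 3L)
  Q <- nrow(fads$coefficients)
  a <- fads$coefficients[, idx[1]]
  b <- fads$coefficients[, idx[2]]
  v <- c(record$lvef, record$qrs_ms, record$pr_ms, a, b)
  names(v) <- c("lvef", "qrs", "pr",
                sprintf("c%d_f%02d", idx[1], seq_len(Q)),
                sprintf("c%d_f%02d", idx[2], seq_len(Q)))
  attr(v, "axis") <- axis
  v
}

#' Assemble the cohort feature matrix for one axis
#'
#' @param table Cohort data frame (one row per subject).
#' @param fads_list List of `fads_result`, parallel to `table` rows.
#' @param axis `"iLV"` or `"LVRV"`.
#' @return Numeric matrix, one row per subject.
#' @export
build_feature_matrix <- function(table, fads_list, axis) {
  stopifnot(nrow(table) == length(fads_list))
  rows <- lapply(seq_len(nrow(table)), function(i)
    build_feature_vector(table[i, ], fads_list[[i]], axis))
  X <- do.call(rbind, rows)
  rownames(X) <- table$subject_id
  X
}

#' Fit / apply a per-dimension z-score normalizer
#'
#' `fit_normalizer()` learns a per-dimension affine map on training vectors
#' only: subtract the mean and divide by the population standard deviation,
#' so the training set maps to mean 0, SD 1 per dimension. Zero-variance
#' dimensions are centered only (scale 1). `apply_normalizer()` applies a
#' fitted map to new vectors; applying is idempotent in the sense that the
#' parameters never change after fitting.
#'
#' @param X Numeric matrix of training vectors (rows = subjects).
#' @return `fit_normalizer`: object of class `normalizer` (`center`,
#'   `scale`).
#' @export
fit_normalizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("need at least 2 training vectors")
  center <- colMeans(X)
  scale <- sqrt(colMeans(sweep(X, 2, center)^2))
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale), class = "normalizer")
}

#' @rdname fit_normalizer
#' @param params A fitted `normalizer`.
#' @param x Numeric vector or matrix to transform.
#' @export
apply_normalizer <- function(params, x) {
  stopifnot(inherits(params, "normalizer"))
  if (is.matrix(x)) {
    if (ncol(x) != length(params$center)) stopf("dimension mismatch")
    sweep(sweep(x, 2, params$center), 2, params$scale, `/`)
  } else {
    if (length(x) != length(params$center)) stopf("dimension mismatch")
    (x - params$center) / params$scale
  }
}

#' Write a feature matrix as CSV
#'
#' @param X Feature matrix from [build_feature_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(subject_id = rownames(X) %||% seq_len(nrow(X)), X,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
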