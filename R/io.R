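#' Gated image series container
#'
#' A cardiac-cycle-synchronized stack of count maps. Internal axis order is
#' `(t, y, x)`: `counts[q, i, j]` is frame `q`, image row `i`, column `j`.
#'
#' @param counts Numeric `k x rows x cols` array, nonnegative.
#' @param subject_id Subject identifier string.
#' @param frame_duration_ms Frame duration in milliseconds (`NA` if unknown).
#' @param meta Optional named list of acquisition metadata (group, seed,
#'   counts_per_frame, ...).
#' @return Object of class `gated_series`.
#' @export
gated_series <- function(counts, subject_id = "", frame_duration_ms = NA_real_,
                         meta = list()) {
  if (length(dim(counts)) != 3) stopf("counts must be a k x rows x cols array")
  if (any(!is.finite(counts))) stopf("counts contain non-finite values")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  structure(list(counts = counts, frames = dim(counts)[1],
                 grid = dim(counts)[2:3],
                 frame_duration_ms = frame_duration_ms,
                 subject_id = subject_id, meta = meta),
            class = "gated_series")
}

#' @export
print.gated_series <- function(x, ...) {
  cat(sprintf("gated_series '%s': %d frames of %d x %d, total counts %.4g\n",
              x$subject_id, x$frames, x$grid[1], x$grid[2], sum(x$counts)))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(series, path) {
  meta <- list(subject_id = series$subject_id, frames = series$frames,
               grid = series$grid,
               frame_duration_ms = series$frame_duration_ms)
  meta <- c(meta, series$meta)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a gated series to disk
#'
#' Supported carriers: NIfTI (axes stored as `(x, y, t)`), multi-page TIFF
#' (16-bit, one page per frame) and a plain long-format CSV
#' (`frame,row,col,count`). Every carrier gets a JSON sidecar
#' (`<path>.json`) holding frame count, grid and acquisition metadata.
#'
#' @param series A [gated_series()].
#' @param path Output file path.
#' @param format `"nifti"`, `"tiff"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, format = c("nifti", "tiff", "csv")) {
  stopifnot(inherits(series, "gated_series"))
  format <- match.arg(format)
  x <- series$counts
  integerish <- all(x == round(x))
  switch(format,
    nifti = {
      arr <- aperm(x, c(3, 2, 1))  # (t,y,x) -> (x,y,t)
      RNifti::writeNifti(RNifti::asNifti(arr), path,
                         datatype = if (integerish) "int32" else "double")
    },
    tiff = {
      if (!integerish) stopf("TIFF carrier requires integer counts")
      if (max(x) > 65535) stopf("TIFF carrier limited to counts <= 65535")
      pages <- lapply(seq_len(series$frames), function(q) x[q, , ] / 65535)
      tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    },
    csv = {
      df <- data.frame(frame = rep(seq_len(series$frames),
                                   each = prod(series$grid)),
                       row = rep(rep(seq_len(series$grid[1]),
                                     each = series$grid[2]), series$frames),
                       col = rep(seq_len(series$grid[2]),
                                 series$frames * series$grid[1]),
                       count = as.vector(aperm(x, c(3, 2, 1))))
      utils::write.csv(df, path, row.names = FALSE)
    })
  write_sidecar(series, path)
  invisible(path)
}

#' Read a gated series from disk
#'
#' Inverse of [write_series()]; integer counts round-trip bit-exactly. The
#' JSON sidecar, when present, is validated against the pixel data (frame
#' count and grid must match).
#'
#' @param path File path written by [write_series()].
#' @param format `"nifti"`, `"tiff"` or `"csv"`.
#' @return A [gated_series()].
#' @export
read_series <- function(path, format = c("nifti", "tiff", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- switch(format,
    nifti = {
      arr <- as.array(RNifti::readNifti(path))
      if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1L))
      if (length(dim(arr)) != 3) stopf("expected a 3D (x, y, t) NIfTI volume")
      aperm(arr, c(3, 2, 1))
    },
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      k <- length(pages)
      arr <- array(0, c(k, nrow(pages[[1]]), ncol(pages[[1]])))
      for (q in seq_len(k)) arr[q, , ] <- round(pages[[q]] * 65535)
      arr
    },
    csv = {
      df <- utils::read.csv(path)
      need <- c("frame", "row", "col", "count")
      if (!all(need %in% names(df)))
        stopf("CSV series must have columns %s", paste(need, collapse = ","))
      k <- max(df$frame); nr <- max(df$row); nc <- max(df$col)
      arr <- array(NA_real_, c(k, nr, nc))
      arr[cbind(df$frame, df$row, df$col)] <- df$count
      if (any(is.na(arr))) stopf("CSV series has missing pixels")
      arr
    })
  if (any(x < 0)) stopf("negative counts in %s", path)
  meta <- read_sidecar(path)
  if (!is.null(meta)) {
    if (!is.null(meta$frames) && meta$frames != dim(x)[1])
      stopf("sidecar declares %d frames but stack has %d", meta$frames,
            dim(x)[1])
    if (!is.null(meta$grid) && !all(unlist(meta$grid) == dim(x)[2:3]))
      stopf("sidecar grid disagrees with pixel data")
  }
  gated_series(x,
               subject_id = meta$subject_id %||% "",
               frame_duration_ms = meta$frame_duration_ms %||% NA_real_,
               meta = meta[setdiff(names(meta),
                                   c("subject_id", "frames", "grid",
                                     "frame_duration_ms"))] %||% list())
}

#' Write / read ROI label masks
#'
#' Region masks are integer label images (0 = background, 1 = LV, 2 = RV,
#' 3 = atria) stored in the same carriers as image series, with the legend
#' in the JSON sidecar.
#'
#' @param masks A `roi_mask_set` (see [roi_masks()]).
#' @param path Output path.
#' @param format `"nifti"`, `"tiff"` or `"csv"`.
#' @return `path` invisibly (write) or a `roi_mask_set` (read).
#' @export
write_masks <- function(masks, path, format = c("nifti", "tiff", "csv")) {
  stopifnot(inherits(masks, "roi_mask_set"))
  format <- match.arg(format)
  lab <- masks$labels
  arr <- array(lab, c(1, nrow(lab), ncol(lab)))
  ser <- gated_series(arr, subject_id = "roi_masks",
                      meta = list(legend = as.list(masks$legend)))
  write_series(ser, path, format)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path, format = c("nifti", "tiff", "csv")) {
  ser <- read_series(path, format)
  legend <- unlist(ser$meta$legend %||%
                     c(`0` = "background", `1` = "LV", `2` = "RV",
                       `3` = "atria"))
  structure(list(labels = matrix(as.integer(ser$counts[1, , ]),
                                 ser$grid[1], ser$grid[2]),
                 legend = legend),
            class = "roi_mask_set")
}

COHORT_COLUMNS <- c("subject_id", "group", "lvef", "qrs_ms", "pr_ms",
                    "lvrv_true", "ilv_true", "seed")

#' Write / read a cohort table
#'
#' The documented CSV schema is `subject_id,group,lvef,qrs_ms,pr_ms,
#' lvrv_true,ilv_true,seed`; extra columns (injected delays, per-rater code
#' columns `lvrv_r1..`, consensus columns) are carried through unchanged.
#' Reading validates LVEF range and severity codes row by row.
#'
#' @param table Data frame with at least the schema columns.
#' @param path CSV file path.
#' @return `path` invisibly (write) or a data frame (read).
#' @export
write_cohort_table <- function(table, path) {
  miss <- setdiff(COHORT_COLUMNS, names(table))
  if (length(miss))
    stopf("cohort table missing column(s): %s", paste(miss, collapse = ", "))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(COHORT_COLUMNS, names(df))
  if (length(miss))
    stopf("cohort table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(df)
  if (any(df$lvef < 0 | df$lvef > 100)) {
    bad <- which(df$lvef < 0 | df$lvef > 100)[1]
    stopf("row %d: LVEF %.2f outside [0, 100]", bad, df$lvef[bad])
  }
  if (any(df$qrs_ms <= 0) || any(df$pr_ms <= 0))
    stopf("qrs_ms and pr_ms must be positive")
  code_cols <- grep("^(lvrv|ilv)_(true|r[0-9]+|consensus)$", names(df),
                    value = TRUE)
  for (cc in code_cols) {
    ok <- df[[cc]] %in% DYS_LEVELS | is.na(df[[cc]])
    if (!all(ok))
      stopf("row %d: invalid code '%s' in column %s", which(!ok)[1],
            df[[cc]][which(!ok)[1]], cc)
  }
  df
}
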