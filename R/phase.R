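#' First-harmonic Fourier phase image
#'
#' Fits each pixel's time-activity curve to the first harmonic of its
#' discrete Fourier transform. Phase convention: a pure cosine peaking at
#' frame 0 has phase 0 degrees and phase increases with contraction delay
#' (a TAC shifted later by `s` frames gains `360 * s / Q` degrees). The
#' amplitude image is the first-harmonic magnitude; pixels with amplitude
#' below `amplitude_threshold_frac` of the image maximum are flagged
#' invalid (a constant series yields an all-invalid image).
#'
#' @param series A [gated_series()] with at least 4 frames.
#' @param amplitude_threshold_frac Validity threshold as a fraction of the
#'   maximum first-harmonic amplitude (default 0.05).
#' @return Object of class `phase_image`: `phase_deg` in `[0, 360)`,
#'   `amplitude`, logical `valid`, all `rows x cols` matrices.
#' @export
phase_image <- function(series, amplitude_threshold_frac = 0.05) {
  stopifnot(inherits(series, "gated_series"))
  if (series$frames < 4) stopf("need at least 4 frames for phase analysis")
  tac <- build_tac_matrix(series)
  Q <- ncol(tac$X)
  basis <- exp(-2i * pi * (seq_len(Q) - 1) / Q)
  f1 <- as.vector(tac$X %*% basis)
  amp <- Mod(f1) * 2 / Q
  phase <- (-Arg(f1) * 180 / pi) %% 360
  # a numerically constant series has no first harmonic anywhere
  tol <- 1e-10 * max(abs(tac$X), 1)
  maxamp <- max(amp)
  valid <- if (maxamp > tol) amp >= amplitude_threshold_frac * maxamp
           else rep(FALSE, length(amp))
  shape <- function(v) matrix(v, series$grid[1], series$grid[2], byrow = TRUE)
  structure(list(phase_deg = shape(phase), amplitude = shape(amp),
                 valid = shape(valid), grid = series$grid),
            class = "phase_image")
}

circular_mean_deg <- function(deg) {
  (atan2(mean(sin(deg * pi / 180)), mean(cos(deg * pi / 180))) * 180 / pi) %% 360
}

circular_sd_deg <- function(deg) {
  r <- sqrt(mean(sin(deg * pi / 180))^2 + mean(cos(deg * pi / 180))^2)
  if (r >= 1) return(0)
  sqrt(-2 * log(r)) * 180 / pi
}

# Narrowest arc containing at least frac of the sample: scan arcs anchored
# at each sorted phase and spanning the required number of consecutive
# (circularly) samples.
narrowest_arc_deg <- function(deg, frac = 0.95) {
  n <- length(deg)
  m <- ceiling(frac * n)
  if (m <= 1) return(0)
  s <- sort(deg %% 360)
  ext <- c(s, s + 360)
  min(ext[seq_len(n) + m - 1] - s)
}

#' Circular statistics of a phase histogram
#'
#' Circular mean and standard deviation plus the narrowest arc containing
#' 95% of the valid in-mask phases (the phase-histogram dispersion indices
#' used to read dyssynchrony).
#'
#' @param img A [phase_image()].
#' @param mask Logical `rows x cols` matrix selecting the region.
#' @param width_frac Mass for the histogram width (default 0.95).
#' @return List with `mean_phase_deg`, `sd_deg`, `width95_deg`, `n_pixels`.
#' @export
phase_stats <- function(img, mask, width_frac = 0.95) {
  stopifnot(inherits(img, "phase_image"))
  if (!any(mask)) stopf("mask is empty")
  sel <- mask & img$valid
  if (!any(sel)) stopf("no valid pixels in mask")
  ph <- img$phase_deg[sel]
  list(mean_phase_deg = circular_mean_deg(ph),
       sd_deg = circular_sd_deg(ph),
       width95_deg = narrowest_arc_deg(ph, width_frac),
       n_pixels = sum(sel))
}

#' Fraction of the cardiac cycle covered by a series' frames
#'
#' Raw acquisitions cover the full R-R interval (1); [preprocess_frames()]
#' drops the degraded final frame, leaving 15/16 of the cycle. DFT phases
#' from [phase_image()] are angles of the retained-frame window; multiply
#' them (or their differences and dispersions) by this fraction to express
#' timing in cardiac-cycle degrees.
#'
#' @param series A [gated_series()].
#' @return The covered cycle fraction (1 when the series was never
#'   preprocessed).
#' @export
cycle_fraction <- function(series) {
  stopifnot(inherits(series, "gated_series"))
  series$meta$cycle_fraction %||% 1
}

#' Signed circular difference between two angles
#'
#' `(a - b)` wrapped to `(-180, 180]`; used to compare regional mean phases
#' (e.g. RV minus LV gives the interventricular delay).
#'
#' @param a,b Angles in degrees.
#' @return Signed difference in degrees.
#' @export
phase_difference_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Count-based left ventricular ejection fraction
#'
#' Sums the series over the LV mask into an ROI time-activity curve and
#' computes `100 * (ED - ES) / (ED - BG)` from its extrema, where `BG` is
#' an optional background term (mean per-pixel background count scaled by
#' the number of LV pixels; 0 when no background mask is given). Apply
#' [preprocess_frames()] first on acquisitions whose final frame is
#' degraded, otherwise that artifact is read as end-systole.
#'
#' @param series A [gated_series()].
#' @param lv_mask Logical `rows x cols` matrix for the LV region.
#' @param background_mask Optional logical matrix of background pixels.
#' @return LVEF as a percentage.
#' @export
compute_lvef <- function(series, lv_mask, background_mask = NULL) {
  stopifnot(inherits(series, "gated_series"))
  if (!any(lv_mask)) stopf("lv_mask is empty")
  roi_tac <- apply(series$counts, 1, function(fr) sum(fr[lv_mask]))
  bg <- 0
  if (!is.null(background_mask)) {
    if (!any(background_mask)) stopf("background_mask is empty")
    bg_per_pixel <- mean(apply(series$counts, 1,
                               function(fr) mean(fr[background_mask])))
    bg <- bg_per_pixel * sum(lv_mask)
  }
  ed <- max(roi_tac); es <- min(roi_tac)
  if (ed == bg) stopf("ED equals background; LVEF undefined")
  100 * (ed - es) / (ed - bg)
}
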