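#' Subject-level simulation parameters
#'
#' Bundles the physiological and acquisition parameters describing one
#' synthetic gated blood-pool study.
#'
#' @param group One of `"control"`, `"nonisch_wide"`, `"nonisch_narrow"`,
#'   `"isch_wide"`, `"isch_narrow"` (heart-failure groups split by ischemic
#'   etiology and QRS width).
#' @param ef_true True left ventricular ejection fraction, in (0, 1).
#' @param qrs_ms,pr_ms ECG intervals in milliseconds (positive).
#' @param lvrv_delay_deg Mean phase offset of right-ventricular contraction
#'   relative to the left ventricle, in degrees of the cardiac cycle.
#'   Positive values delay the RV (interventricular dyssynchrony).
#' @param ilv_spread_deg Standard deviation of the spatially smooth phase
#'   offset field across LV pixels, in degrees (intraventricular
#'   dyssynchrony); nonnegative.
#' @param heart_rate_bpm Heart rate, beats per minute (sets frame duration).
#' @param counts_per_frame Expected total counts per acquired frame.
#' @param seed Integer seed driving all randomness for this subject.
#' @return An object of class `subject_params` (a validated list).
#' @export
subject_params <- function(group = "control", ef_true = 0.6,
                           qrs_ms = 80, pr_ms = 140,
                           lvrv_delay_deg = 0, ilv_spread_deg = 0,
                           heart_rate_bpm = 70,
                           counts_per_frame = 300000L, seed = 1L) {
  group <- match.arg(group, c("control", "nonisch_wide", "nonisch_narrow",
                              "isch_wide", "isch_narrow"))
  if (!is.numeric(ef_true) || length(ef_true) != 1 ||
      ef_true <= 0 || ef_true >= 1)
    stopf("ef_true must be a single number in (0, 1), got %s", ef_true)
  if (qrs_ms <= 0 || pr_ms <= 0) stopf("qrs_ms and pr_ms must be positive")
  if (ilv_spread_deg < 0) stopf("ilv_spread_deg must be nonnegative")
  if (counts_per_frame <= 0) stopf("counts_per_frame must be positive")
  if (heart_rate_bpm <= 0) stopf("heart_rate_bpm must be positive")
  structure(list(group = group, ef_true = ef_true, qrs_ms = qrs_ms,
                 pr_ms = pr_ms, lvrv_delay_deg = lvrv_delay_deg,
                 ilv_spread_deg = ilv_spread_deg,
                 heart_rate_bpm = heart_rate_bpm,
                 counts_per_frame = as.integer(round(counts_per_frame)),
                 seed = as.integer(seed)),
            class = "subject_params")
}

# Raised-cosine systolic waveform on [0, 2*pi): zero at the R wave
# (end-diastole, frame 0), peaking at theta = pi * systolic_fraction,
# back to zero at 2*pi*systolic_fraction and flat through diastole.
# systolic_fraction = 1 reduces to the pure first harmonic (1 - cos)/2.
systolic_waveform <- function(theta, systolic_fraction = 0.625) {
  th <- theta %% (2 * pi)
  s <- numeric(length(th))
  inside <- th < 2 * pi * systolic_fraction
  s[inside] <- (1 - cos(th[inside] / systolic_fraction)) / 2
  s
}

#' Anatomical region masks for the synthetic phantom
#'
#' Lays out elliptical left- and right-ventricular regions (lower half of
#' the field of view, anterior left-oblique-like arrangement), two atrial
#' ellipses above them, and background elsewhere.
#'
#' @param grid Integer pair `(rows, cols)`; default `c(64, 64)`.
#' @return Object of class `roi_mask_set`: list with `labels` (rows x cols
#'   integer matrix) and `legend` mapping 0=background, 1=LV, 2=RV, 3=atria.
#' @export
roi_masks <- function(grid = c(64, 64)) {
  nr <- grid[1]; nc <- grid[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ellipse <- function(r0, c0, a, b) ((rows - r0) / a)^2 + ((cols - c0) / b)^2 <= 1
  lv  <- ellipse(0.60 * nr, 0.64 * nc, 0.16 * nr, 0.13 * nc)
  rv  <- ellipse(0.60 * nr, 0.34 * nc, 0.16 * nr, 0.11 * nc)
  atr <- ellipse(0.28 * nr, 0.40 * nc, 0.11 * nr, 0.095 * nc) |
         ellipse(0.28 * nr, 0.66 * nc, 0.11 * nr, 0.095 * nc)
  for (nm in c("LV", "RV", "atria")) {
    m <- switch(nm, LV = lv, RV = rv, atria = atr)
    if (!any(m)) stopf("grid %dx%d too small to contain region %s", nr, nc, nm)
  }
  labels <- matrix(0L, nr, nc)
  labels[atr] <- 3L; labels[rv] <- 2L; labels[lv] <- 1L
  structure(list(labels = labels,
                 legend = c(`0` = "background", `1` = "LV", `2` = "RV",
                            `3` = "atria")),
            class = "roi_mask_set")
}

# Spatially smooth intra-LV phase offset field (degrees): a random linear
# gradient across the LV footprint, centred and rescaled so its population
# SD over LV pixels equals spread_deg exactly. Uses the current RNG stream.
ilv_phase_field <- function(lv_mask, spread_deg) {
  n <- sum(lv_mask)
  if (spread_deg == 0 || n < 2) return(numeric(n))
  idx <- which(lv_mask, arr.ind = TRUE)
  u <- scale(idx[, 1], scale = FALSE)
  v <- scale(idx[, 2], scale = FALSE)
  alpha <- runif(1, 0, 2 * pi)
  g <- cos(alpha) * u + sin(alpha) * v
  g <- g - mean(g)
  s <- sqrt(mean(g^2))
  if (s == 0) return(numeric(n))
  as.numeric(g / s * spread_deg)
}

#' Simulate one gated blood-pool image series
#'
#' Builds a noise-free periodic count model on the phantom of [roi_masks()]
#' and (optionally) draws Poisson counts. Ventricular pixels follow
#' `ED * (1 - ef * s(theta - phi))` with `s` the raised-cosine systolic
#' waveform; atrial pixels fill in anti-phase (`1 - s`); the background pool
#' carries the complement of the chamber count displacement so that every
#' frame's expected total is exactly `counts_per_frame`. The last frame's
#' expectation is attenuated (beat-window degradation) before noise.
#'
#' @param params A [subject_params()] object.
#' @param frames Number of gated frames (default 16).
#' @param grid Integer pair `(rows, cols)`, default 64 x 64.
#' @param noise_model `"poisson"` (per-pixel, per-frame Poisson counts) or
#'   `"none"` (real-valued expectations).
#' @param systolic_fraction Fraction of the cycle occupied by the systolic
#'   raised cosine; the default 0.625 (= 10/16) places end-systole exactly
#'   on a sampled frame of a 16-frame acquisition.
#' @param background_frac Background brightness as a fraction of peak
#'   ventricular end-diastolic brightness (default 0.10).
#' @param atrial_base,atrial_ef Atrial brightness (fraction of ventricular
#'   peak) and atrial emptying fraction.
#' @param last_frame_factor Attenuation applied to the final frame's
#'   expected counts (default 0.7), emulating R-R variability fall-off.
#' @return A [gated_series()] object with integer (Poisson) or real (noise
#'   free) counts, plus acquisition metadata.
#' @export
generate_series <- function(params, frames = 16L, grid = c(64, 64),
                            noise_model = c("poisson", "none"),
                            systolic_fraction = 0.625,
                            background_frac = 0.10,
                            atrial_base = 0.65, atrial_ef = 0.35,
                            last_frame_factor = 0.7) {
  stopifnot(inherits(params, "subject_params"))
  noise_model <- match.arg(noise_model)
  if (frames < 4) stopf("at least 4 frames required, got %d", frames)
  masks <- roi_masks(grid)
  lab <- masks$labels
  nr <- grid[1]; nc <- grid[2]
  k <- as.integer(frames)
  theta <- 2 * pi * (seq_len(k) - 1) / k

  with_seed(params$seed, {
    phi_lv <- ilv_phase_field(lab == 1L, params$ilv_spread_deg) * pi / 180
    phi_rv <- params$lvrv_delay_deg * pi / 180

    n_lv <- sum(lab == 1L); n_rv <- sum(lab == 2L)
    n_at <- sum(lab == 3L); n_bg <- sum(lab == 0L)

    # expected TACs per pixel, arbitrary brightness units (peak ED = 1)
    mu <- matrix(0, nr * nc, k)  # row-major pixel order p = (i-1)*nc + j
    pix_of <- function(mask) (which(mask, arr.ind = TRUE) %*% c(nc, 1)) - nc
    s_of <- function(phi) systolic_waveform(outer(phi, theta, function(p, t) t - p),
                                            systolic_fraction)
    lv_rows <- as.vector(pix_of(lab == 1L))
    rv_rows <- as.vector(pix_of(lab == 2L))
    at_rows <- as.vector(pix_of(lab == 3L))
    bg_rows <- as.vector(pix_of(lab == 0L))

    mu[lv_rows, ] <- 1 - params$ef_true * s_of(phi_lv)
    mu[rv_rows, ] <- 1 - params$ef_true *
      matrix(systolic_waveform(theta - phi_rv, systolic_fraction),
             n_rv, k, byrow = TRUE)
    mu[at_rows, ] <- atrial_base *
      (1 - atrial_ef *
         matrix(1 - systolic_waveform(theta, systolic_fraction),
                n_at, k, byrow = TRUE))

    # background pool: flat level plus the complement of chamber displacement,
    # so expected frame totals are constant (tracer conservation in the FOV)
    chamber_total <- colSums(mu[c(lv_rows, rv_rows, at_rows), , drop = FALSE])
    disp <- chamber_total - mean(chamber_total)
    bg_tac <- background_frac - disp / n_bg
    if (any(bg_tac < 0))
      stopf("background fraction %.3f too small to absorb chamber displacement",
            background_frac)
    mu[bg_rows, ] <- matrix(bg_tac, n_bg, k, byrow = TRUE)

    # scale so each (non-degraded) frame expects counts_per_frame total
    mu <- mu * (params$counts_per_frame / mean(colSums(mu)))
    mu[, k] <- mu[, k] * last_frame_factor

    counts <- if (noise_model == "poisson") {
      matrix(rpois(length(mu), mu), nrow(mu), k)
    } else mu

    arr <- array(0, dim = c(k, nr, nc))
    for (q in seq_len(k))
      arr[q, , ] <- matrix(counts[, q], nr, nc, byrow = TRUE)

    gated_series(arr,
                 subject_id = sprintf("%s_seed%d", params$group, params$seed),
                 frame_duration_ms = 60000 / params$heart_rate_bpm / k,
                 meta = list(group = params$group, seed = params$seed,
                             counts_per_frame = params$counts_per_frame))
  })
}

#' Default severity rule: monotone thresholds on delay magnitudes
#'
#' Cut points (degrees) mapping `|lvrv_delay_deg|` and `ilv_spread_deg` to
#' the four ordinal codes: below the first cut is absent, then mild,
#' moderate, severe.
#'
#' @param lvrv,ilv Increasing numeric vectors of three cut points.
#' @return A `severity_rule` list.
#' @export
severity_rule <- function(lvrv = c(20, 40, 60), ilv = c(10, 25, 40)) {
  for (nm in c("lvrv", "ilv")) {
    cuts <- get(nm)
    if (length(cuts) != 3 || is.unsorted(cuts, strictly = TRUE) || cuts[1] <= 0)
      stopf("%s cut points must be three strictly increasing positive values", nm)
  }
  structure(list(lvrv = lvrv, ilv = ilv), class = "severity_rule")
}

#' Ground-truth severity labels from generator parameters
#'
#' Applies a monotone threshold rule to the injected interventricular delay
#' magnitude and intra-LV phase dispersion; the label is a nondecreasing
#' function of each.
#'
#' @param params A [subject_params()] object.
#' @param rule A [severity_rule()].
#' @return List with elements `lvrv` and `ilv`, each one of `A`, `M`, `Md`,
#'   `S`.
#' @export
assign_ground_truth <- function(params, rule = severity_rule()) {
  stopifnot(inherits(params, "subject_params"), inherits(rule, "severity_rule"))
  grade <- function(x, cuts) DYS_LEVELS[findInterval(x, cuts) + 1L]
  list(lvrv = grade(abs(params$lvrv_delay_deg), rule$lvrv),
       ilv = grade(params$ilv_spread_deg, rule$ilv))
}

#' Cohort specification for the synthetic generator
#'
#' @param n_per_group Named integer vector of subjects per group; defaults
#'   to the study-like 33 controls plus 11/10/10/11 heart-failure subjects.
#' @param frames,grid,noise_model,counts_per_frame Acquisition settings
#'   passed to [generate_series()].
#' @param rule Severity rule (see [severity_rule()]).
#' @param master_seed Integer; all cohort randomness derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(control = 33, nonisch_wide = 11,
                                        nonisch_narrow = 10, isch_wide = 10,
                                        isch_narrow = 11),
                        frames = 16L, grid = c(64, 64),
                        noise_model = "poisson",
                        counts_per_frame = 300000L,
                        rule = severity_rule(), master_seed = 1L) {
  if (frames < 4) stopf("frames must be >= 4")
  if (any(n_per_group < 0)) stopf("group counts must be >= 0")
  bad <- setdiff(names(n_per_group),
                 c("control", "nonisch_wide", "nonisch_narrow",
                   "isch_wide", "isch_narrow"))
  if (length(bad)) stopf("unknown group(s): %s", paste(bad, collapse = ", "))
  structure(list(n_per_group = n_per_group, frames = as.integer(frames),
                 grid = grid, noise_model = noise_model,
                 counts_per_frame = as.integer(counts_per_frame),
                 rule = rule, master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# Clinical covariate distributions per group: LVEF% mean/sd, QRS ms mean/sd,
# P-R ms mean/sd, and truncation ranges keeping draws physiological and
# QRS-width groups on their side of 120 ms. Control ECG SDs are nominal
# normal-population values (the study's controls carried literature values).
GROUP_CLINICAL <- list(
  control        = list(lvef = c(59.7, 5.8),  qrs = c(80, 10),
                        pr = c(140, 15),  lvef_rng = c(40, 78),
                        qrs_rng = c(60, 115), pr_rng = c(100, 200)),
  nonisch_wide   = list(lvef = c(22.1, 7.4),  qrs = c(150.9, 30.1),
                        pr = c(178.18, 34.9), lvef_rng = c(8, 34.9),
                        qrs_rng = c(121, 240), pr_rng = c(90, 320)),
  nonisch_narrow = list(lvef = c(23.3, 8.2),  qrs = c(88.6, 8.8),
                        pr = c(191, 23.8),    lvef_rng = c(8, 34.9),
                        qrs_rng = c(60, 119), pr_rng = c(90, 320)),
  isch_wide      = list(lvef = c(22.6, 10.6), qrs = c(139.0, 23.8),
                        pr = c(191, 23.8),    lvef_rng = c(8, 34.9),
                        qrs_rng = c(121, 240), pr_rng = c(90, 320)),
  isch_narrow    = list(lvef = c(32.9, 9.3),  qrs = c(95.0, 12.4),
                        pr = c(176.36, 43.9), lvef_rng = c(8, 34.9),
                        qrs_rng = c(60, 119), pr_rng = c(90, 320)))

# Per-group severity class probabilities. Wide-QRS groups draw more severe
# labels (QRS-severity coupling). With the default group sizes the
# largest-remainder quotas reproduce the study-like marginal label counts
# (LV-RV 33/11/31; iLV 34/6/35 with one iLV-absent narrow-QRS HF subject).
DEFAULT_SEVERITY_PROBS <- list(
  lvrv = list(nonisch_wide   = c(A = 0,    M = 0.09, Md = 0.455, S = 0.455),
              nonisch_narrow = c(A = 0,    M = 0.40, Md = 0.30,  S = 0.30),
              isch_wide      = c(A = 0,    M = 0.09, Md = 0.41,  S = 0.50),
              isch_narrow    = c(A = 0,    M = 0.45, Md = 0.275, S = 0.275)),
  ilv  = list(nonisch_wide   = c(A = 0,    M = 0.09, Md = 0.455, S = 0.455),
              nonisch_narrow = c(A = 0,    M = 0.20, Md = 0.40,  S = 0.40),
              isch_wide      = c(A = 0,    M = 0.09, Md = 0.41,  S = 0.50),
              isch_narrow    = c(A = 0.09, M = 0.18, Md = 0.365, S = 0.365)))

# Deterministic class quota for n subjects by largest-remainder rounding;
# remainder ties break toward the less severe class.
severity_quota <- function(n, probs) {
  raw <- probs * n
  base <- floor(raw)
  rem <- raw - base
  need <- n - sum(base)
  if (need > 0) {
    ord <- order(-rem, seq_along(rem))  # biggest remainder, then less severe
    base[ord[seq_len(need)]] <- base[ord[seq_len(need)]] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

# Delay / spread magnitude ranges (degrees) per severity class, kept clear
# of the default rule's cut points so labels are stable under small noise.
LVRV_DELAY_RANGE <- list(M = c(24, 36), Md = c(44, 56), S = c(64, 85))
ILV_SPREAD_RANGE <- list(A = c(2, 6), M = c(12, 22), Md = c(28, 38),
                         S = c(42, 60))

rtrunc_norm <- function(n, mean, sd, rng) {
  x <- rnorm(n, mean, sd)
  for (it in 1:200) {
    out <- x < rng[1] | x > rng[2]
    if (!any(out)) break
    x[out] <- rnorm(sum(out), mean, sd)
  }
  pmin(pmax(x, rng[1]), rng[2])
}

#' Generate a synthetic ERNA cohort
#'
#' Draws per-subject clinical covariates from group-specific normal
#' distributions, assigns severity classes by deterministic per-group quotas
#' (wide-QRS groups skew severe), draws delay magnitudes inside each
#' severity band, simulates every image series, and records ground truth.
#' All randomness derives from `spec$master_seed`: the same spec yields an
#' identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @param severity_probs Per-axis, per-group severity class probabilities
#'   (see the package default `DEFAULT_SEVERITY_PROBS` layout); the knob
#'   controlling how strongly QRS-width group membership couples to
#'   severity.
#' @param ... Further arguments passed to [generate_series()].
#' @return List with `table` (one data frame row per subject: id, group,
#'   clinical covariates, injected delays, ground-truth labels, seed),
#'   `params` (list of [subject_params()]) and `series` (list of
#'   [gated_series()]).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            severity_probs = DEFAULT_SEVERITY_PROBS, ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_per_group <- spec$n_per_group[spec$n_per_group > 0]
  if (length(n_per_group) == 0)
    return(list(table = data.frame(), params = list(), series = list()))
  n_total <- sum(n_per_group)
  seeds <- derive_seeds(spec$master_seed, n_total + 1L)
  rows <- list(); params <- list(); series <- list()
  idx <- 0L
  with_seed(seeds[n_total + 1L], {
    for (g in names(n_per_group)) {
      n <- as.integer(n_per_group[[g]])
      cl <- GROUP_CLINICAL[[g]]
      lvef <- rtrunc_norm(n, cl$lvef[1], cl$lvef[2], cl$lvef_rng)
      qrs <- rtrunc_norm(n, cl$qrs[1], cl$qrs[2], cl$qrs_rng)
      pr <- rtrunc_norm(n, cl$pr[1], cl$pr[2], cl$pr_rng)
      if (g == "control") {
        lvrv_sev <- rep("A", n); ilv_sev <- rep("A", n)
        lvrv_delay <- rnorm(n, 0, 2)
      } else {
        qa <- severity_quota(n, severity_probs$lvrv[[g]])
        lvrv_sev <- sample(rep(names(qa), qa))
        qb <- severity_quota(n, severity_probs$ilv[[g]])
        ilv_sev <- sample(rep(names(qb), qb))
        lvrv_delay <- vapply(lvrv_sev, function(s) {
          if (s == "A") rnorm(1, 0, 2)
          else runif(1, LVRV_DELAY_RANGE[[s]][1], LVRV_DELAY_RANGE[[s]][2])
        }, numeric(1))
      }
      ilv_spread <- vapply(ilv_sev, function(s)
        runif(1, ILV_SPREAD_RANGE[[s]][1], ILV_SPREAD_RANGE[[s]][2]),
        numeric(1))
      for (i in seq_len(n)) {
        idx <- idx + 1L
        p <- subject_params(group = g, ef_true = lvef[i] / 100,
                            qrs_ms = qrs[i], pr_ms = pr[i],
                            lvrv_delay_deg = lvrv_delay[i],
                            ilv_spread_deg = ilv_spread[i],
                            counts_per_frame = spec$counts_per_frame,
                            seed = seeds[idx])
        gt <- assign_ground_truth(p, spec$rule)
        params[[idx]] <- p
        rows[[idx]] <- data.frame(
          subject_id = sprintf("S%03d", idx), group = g,
          lvef = lvef[i], qrs_ms = qrs[i], pr_ms = pr[i],
          lvrv_delay_deg = lvrv_delay[i], ilv_spread_deg = ilv_spread[i],
          lvrv_true = gt$lvrv, ilv_true = gt$ilv,
          seed = seeds[idx], stringsAsFactors = FALSE)
      }
    }
  })
  for (i in seq_along(params)) {
    series[[i]] <- generate_series(params[[i]], frames = spec$frames,
                                   grid = spec$grid,
                                   noise_model = spec$noise_model, ...)
    series[[i]]$subject_id <- rows[[i]]$subject_id
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, params = params, series = series)
}
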