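#' Default end-to-end run configuration
#'
#' A plain named list understood by [run_pipeline()]. All seeds are
#' explicit: a single `master_seed` fans out deterministically to the
#' cohort generator, the per-axis splits and the cross-validation folds, so
#' stages can be rerun in isolation and two runs of one config are
#' bit-identical.
#'
#' @param out_dir Output directory (created if absent).
#' @param master_seed Integer master seed.
#' @param n_per_group Cohort composition (see [cohort_spec()]).
#' @param counts_per_frame,frames,grid,noise_model Acquisition settings.
#' @param fads_mode `"uncentered"` or `"centered"`.
#' @param axes Axes to model, subset of `c("iLV", "LVRV")`.
#' @param split_fraction,folds Split and cross-validation settings.
#' @param write_images Write every subject's series (NIfTI) next to the
#'   tables (default `FALSE`; tables, features, models and reports are
#'   always written).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(out_dir, master_seed = 1L,
                       n_per_group = c(control = 33, nonisch_wide = 11,
                                       nonisch_narrow = 10, isch_wide = 10,
                                       isch_narrow = 11),
                       counts_per_frame = 300000L, frames = 16L,
                       grid = c(64, 64), noise_model = "poisson",
                       fads_mode = "uncentered",
                       axes = c("iLV", "LVRV"),
                       split_fraction = 0.7, folds = 10L,
                       write_images = FALSE) {
  cfg <- list(out_dir = out_dir, master_seed = as.integer(master_seed),
              n_per_group = n_per_group,
              counts_per_frame = as.integer(counts_per_frame),
              frames = as.integer(frames), grid = grid,
              noise_model = noise_model, fads_mode = fads_mode,
              axes = axes, split_fraction = split_fraction,
              folds = as.integer(folds), write_images = write_images)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$out_dir)) stopf("config requires out_dir")
  if (sum(cfg$n_per_group) <= 0) stopf("config declares an empty cohort")
  if (!all(cfg$axes %in% c("iLV", "LVRV"))) stopf("unknown axis in config")
  if (cfg$split_fraction <= 0 || cfg$split_fraction >= 1)
    stopf("split_fraction must be in (0, 1)")
  if (is.null(cfg$master_seed)) stopf("config requires an explicit master_seed")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$n_per_group)) y$n_per_group <- unlist(y$n_per_group)
  if (!is.null(y$grid)) y$grid <- unlist(y$grid)
  if (!is.null(y$axes)) y$axes <- unlist(y$axes)
  do.call(run_config, y)
}

#' Run the full dyssynchrony analysis pipeline
#'
#' Simulate a cohort, preprocess every series, decompose with FADS, compute
#' per-region phase statistics and the ERNA ejection fraction, build
#' per-axis feature matrices, split, cross-validate and train the cascade,
#' predict the held-out subjects, and evaluate. All artifacts (cohort
#' table, features, phase summary, models, predictions, per-axis reports)
#' are written under `config$out_dir`, together with a manifest recording
#' seeds, package version and MD5 digests of every artifact.
#'
#' @param config A `run_config` list or the path to a YAML file.
#' @return Invisible list with the cohort table, per-axis results
#'   (confusion matrices, hit rates, cross-validation summaries) and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  seeds <- derive_seeds(config$master_seed, 4L)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  cohort <- step("simulate", generate_cohort(cohort_spec(
    n_per_group = config$n_per_group, frames = config$frames,
    grid = config$grid, noise_model = config$noise_model,
    counts_per_frame = config$counts_per_frame, master_seed = seeds[1])))
  tab <- cohort$table
  write_cohort_table(tab, out("cohort.csv"))
  masks <- roi_masks(config$grid)
  write_masks(masks, out("roi_masks.nii"))
  if (isTRUE(config$write_images)) {
    dir.create(out("series"), showWarnings = FALSE)
    for (i in seq_len(nrow(tab)))
      write_series(cohort$series[[i]],
                   out("series", paste0(tab$subject_id[i], ".nii")))
  }

  lab <- masks$labels
  pre <- step("preprocess", lapply(cohort$series, preprocess_frames))
  fads <- step("fads", lapply(pre, function(s)
    fads_decompose(build_tac_matrix(s), mode = config$fads_mode)))

  phase_rows <- step("phase", lapply(seq_along(pre), function(i) {
    img <- phase_image(pre[[i]])
    cf <- cycle_fraction(pre[[i]])
    lv <- phase_stats(img, lab == 1L)
    rv <- phase_stats(img, lab == 2L)
    data.frame(subject_id = tab$subject_id[i],
               lvef_erna = compute_lvef(pre[[i]], lab == 1L),
               lv_mean_phase = lv$mean_phase_deg,
               lv_sd_cycle_deg = lv$sd_deg * cf,
               lv_width95_cycle_deg = lv$width95_deg * cf,
               lvrv_delay_cycle_deg = cf *
                 phase_difference_deg(rv$mean_phase_deg, lv$mean_phase_deg))
  }))
  phase_df <- do.call(rbind, phase_rows)
  utils::write.csv(phase_df, out("phase_summary.csv"), row.names = FALSE)

  results <- list()
  for (axis in config$axes) {
    truth <- class3(if (axis == "iLV") tab$ilv_true else tab$lvrv_true)
    X <- step(paste0("features_", axis),
              build_feature_matrix(tab, fads, axis))
    write_feature_matrix(X, out(sprintf("features_%s.csv", tolower(axis))))
    hp <- cascade_hyperparams(axis, folds = config$folds,
                              split_fraction = config$split_fraction,
                              seed = seeds[2])
    sp <- split_train_test(truth, config$split_fraction, seed = seeds[3])
    cv <- step(paste0("cv_", axis),
               cross_validate(X[sp$train, , drop = FALSE], truth[sp$train],
                              axis, hp))
    model <- step(paste0("train_", axis),
                  train_cascade(X[sp$train, , drop = FALSE], truth[sp$train],
                                axis, hp))
    write_model(model, out(sprintf("model_%s.json", tolower(axis))))
    pred <- predict(model, X[sp$test, , drop = FALSE])
    utils::write.csv(
      data.frame(subject_id = tab$subject_id[sp$test],
                 true = as.character(truth[sp$test]),
                 predicted = as.character(pred)),
      out(sprintf("predictions_%s.csv", tolower(axis))), row.names = FALSE)
    ev <- confusion_and_hit_rates(truth[sp$test], pred)
    results[[axis]] <- list(
      split = sp, cv = cv, evaluation = ev,
      proportions = list(stage1 = class_proportions(truth, "stage1"),
                         stage2 = class_proportions(truth, "stage2")))
    report <- list(axis = axis,
                   confusion = ev$confusion, per_class = ev$per_class,
                   overall = ev$overall,
                   cv_stage1 = cv$stage1[c("mean", "sd", "folds")],
                   cv_stage2 = cv$stage2[c("mean", "sd", "folds")],
                   n_train = length(sp$train), n_test = length(sp$test))
    jsonlite::write_json(report, out(sprintf("report_%s.json", tolower(axis))),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }

  artifacts <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                            "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dyssync")),
    master_seed = config$master_seed,
    stage_seeds = list(cohort = seeds[1], hyper = seeds[2], split = seeds[3],
                       reserved = seeds[4]),
    config = config[setdiff(names(config), "out_dir")],
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, artifacts))),
      artifacts)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(table = tab, results = results, manifest = manifest))
}
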