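#' Hyperparameters for the two-stage severity cascade
#'
#' Defaults reproduce the per-axis settings of the reference model: for the
#' intra-LV axis `gamma = 0.15`, `cost = 65`; for the interventricular axis
#' `gamma = 0.05`, `cost = 10`. `gamma` is recorded for fidelity but inert:
#' the linear kernel `u . v` has no gamma.
#'
#' @param axis `"iLV"` or `"LVRV"` (sets the per-axis defaults), or `NULL`
#'   to pass both `cost_C` and `gamma` explicitly.
#' @param cost_C Positive misclassification cost for both stages.
#' @param gamma Recorded kernel parameter (inactive for the linear kernel).
#' @param class_weights Named positive weights for stage 2
#'   (`c(mild = ..., nonmild = ...)`); `NULL` means inverse class
#'   frequency on the stage-2 training subset.
#' @param folds Cross-validation folds (default 10).
#' @param split_fraction Training fraction of the cohort split (default 0.7).
#' @param seed Integer seed for splits and fold assignment.
#' @return Object of class `cascade_hyperparams`.
#' @export
cascade_hyperparams <- function(axis = NULL, cost_C = NULL, gamma = NULL,
                                class_weights = NULL, folds = 10L,
                                split_fraction = 0.7, seed = 1L) {
  if (!is.null(axis)) {
    axis <- match.arg(axis, c("iLV", "LVRV"))
    defaults <- if (axis == "iLV") c(gamma = 0.15, cost = 65)
                else c(gamma = 0.05, cost = 10)
    cost_C <- cost_C %||% unname(defaults["cost"])
    gamma <- gamma %||% unname(defaults["gamma"])
  }
  if (is.null(cost_C) || cost_C <= 0) stopf("cost_C must be positive")
  if (is.null(gamma) || gamma <= 0) stopf("gamma must be positive")
  if (split_fraction <= 0 || split_fraction >= 1)
    stopf("split_fraction must be in (0, 1)")
  if (folds < 2) stopf("folds must be >= 2")
  structure(list(axis = axis, cost_C = cost_C, gamma = gamma,
                 class_weights = class_weights, folds = as.integer(folds),
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "cascade_hyperparams")
}

#' Split a cohort into training and testing sets
#'
#' With `stratify = TRUE` (default) the split is per class: each class
#' contributes `floor(fraction * n_class)` subjects to training and the
#' remainder to testing, which reproduces the reference test-set
#' compositions on study-sized cohorts. Unstratified, the training size is
#' `round(fraction * n)`. Deterministic under `seed`.
#'
#' @param labels Vector of class labels (one per subject).
#' @param fraction Training fraction, in (0, 1).
#' @param seed Integer seed.
#' @param stratify Stratify by class (default `TRUE`).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, fraction = 0.7, seed = 1L,
                             stratify = TRUE) {
  n <- length(labels)
  if (n == 0) stopf("empty cohort")
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  with_seed(seed, {
    if (stratify) {
      idx_by_class <- split(seq_len(n), as.character(labels))
      small <- names(idx_by_class)[lengths(idx_by_class) < 2]
      if (length(small))
        stopf("class %s has fewer than 2 members; try stratify = FALSE",
              paste(small, collapse = ", "))
      train <- unlist(lapply(idx_by_class, function(ix) {
        k <- floor(fraction * length(ix))
        sample(ix, k)
      }), use.names = FALSE)
    } else {
      train <- sample(seq_len(n), round(fraction * n))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

# Fit one linear C-SVM stage and extract an oriented linear decision rule:
# dv(x) = x . w + b with dv >= 0 mapped to the FIRST level of `y` (the less
# severe class), regardless of libsvm's internal label order. Boundary ties
# (dv exactly 0) therefore resolve to the less severe class.
fit_linear_stage <- function(X, y, cost, class_weights = NULL) {
  lev <- levels(y)
  if (length(unique(y)) < 2)
    stopf("stage training data contains a single class (%s)", unique(y)[1])
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = class_weights)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm's positive decision value belongs to its first internal label
  pos_level <- fit$levels[fit$labels[1]]
  if (pos_level != lev[1]) {
    w <- -w; b <- -b
  }
  list(weights = w, bias = b, levels = lev)
}

stage_decide <- function(stage, X) {
  dv <- drop(X %*% stage$weights) + stage$bias
  ifelse(dv >= 0, stage$levels[1], stage$levels[2])
}

#' Train the two-stage severity cascade
#'
#' Stage 1 (linear SVM) is fitted on all training subjects, absent versus
#' present dyssynchrony. Stage 2 (class-weighted linear SVM) is fitted only
#' on the present-dyssynchrony subjects, mild versus moderate-severe, with
#' weights defaulting to inverse class frequency to counter the mild-class
#' imbalance. The feature normalizer is fitted on the training set only and
#' travels with the model.
#'
#' @param X Feature matrix (rows = training subjects), raw scale.
#' @param labels3 Labels on the 3-class scale (`A`, `M`, `MdS`); see
#'   [class3()].
#' @param axis `"iLV"` or `"LVRV"`.
#' @param hyperparams A [cascade_hyperparams()]; defaults to the axis
#'   defaults.
#' @return Object of class `cascade_model`.
#' @export
train_cascade <- function(X, labels3, axis = c("iLV", "LVRV"),
                          hyperparams = NULL) {
  axis <- match.arg(axis)
  hp <- hyperparams %||% cascade_hyperparams(axis)
  labels3 <- factor(as.character(labels3), levels = CLASS3_LEVELS)
  if (length(unique(labels3)) < 3)
    stopf("training set must contain all three classes (A, M, MdS)")
  X <- as.matrix(X)
  norm <- fit_normalizer(X)
  Z <- apply_normalizer(norm, X)

  y1 <- factor(ifelse(labels3 == "A", "absent", "present"),
               levels = c("absent", "present"))
  stage1 <- fit_linear_stage(Z, y1, hp$cost_C)

  present <- labels3 != "A"
  y2 <- factor(ifelse(labels3[present] == "M", "mild", "nonmild"),
               levels = c("mild", "nonmild"))
  cw <- hp$class_weights
  if (is.null(cw)) {
    tab <- table(y2)
    cw <- as.numeric(sum(tab) / (2 * tab))
    names(cw) <- names(tab)
  }
  stage2 <- fit_linear_stage(Z[present, , drop = FALSE], y2, hp$cost_C,
                             class_weights = cw)

  structure(list(stage1 = stage1, stage2 = stage2, normalizer = norm,
                 axis = axis, hyperparams = hp, class_weights = cw,
                 n_train = nrow(X)),
            class = "cascade_model")
}

#' Predict severity classes with a fitted cascade
#'
#' Subjects routed "absent" by stage 1 are labelled `A` and never reach
#' stage 2; the rest are labelled `M` or `MdS` by stage 2. Deterministic;
#' decision-boundary ties resolve to the less severe class.
#'
#' @param object A `cascade_model`.
#' @param newdata Feature vector or matrix on the raw scale.
#' @param ... Unused.
#' @return Factor of predictions with levels `A`, `M`, `MdS`.
#' @export
predict.cascade_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(X) != length(object$normalizer$center))
    stopf("feature dimension %d does not match model dimension %d",
          ncol(X), length(object$normalizer$center))
  Z <- apply_normalizer(object$normalizer, X)
  s1 <- stage_decide(object$stage1, Z)
  out <- rep("A", nrow(Z))
  pres <- s1 == "present"
  if (any(pres)) {
    s2 <- stage_decide(object$stage2, Z[pres, , drop = FALSE])
    out[pres] <- ifelse(s2 == "mild", "M", "MdS")
  }
  factor(out, levels = CLASS3_LEVELS)
}

#' Per-stage k-fold cross-validation of the cascade
#'
#' Folds are assigned per stage: stage 1 over all training subjects, stage
#' 2 over the present-dyssynchrony subset only. Assignment is seeded and
#' stratified by class (members of each class are dealt round-robin to
#' folds after a seeded shuffle). If a stage's smallest class has fewer
#' members than `folds`, the fold count is reduced to it with a warning.
#'
#' @param X Feature matrix (raw scale).
#' @param labels3 3-class labels, parallel to rows of `X`.
#' @param axis `"iLV"` or `"LVRV"`.
#' @param hyperparams A [cascade_hyperparams()].
#' @return List with per-stage `mean` and `sd` accuracy (percent) and the
#'   per-fold accuracies.
#' @export
cross_validate <- function(X, labels3, axis = c("iLV", "LVRV"),
                           hyperparams = NULL) {
  axis <- match.arg(axis)
  hp <- hyperparams %||% cascade_hyperparams(axis)
  labels3 <- factor(as.character(labels3), levels = CLASS3_LEVELS)
  X <- as.matrix(X)

  run_stage <- function(Z, y, cost, weights_fun = NULL, seed) {
    n <- length(y)
    if (n < hp$folds) stopf("fewer subjects (%d) than folds (%d)", n, hp$folds)
    k <- min(hp$folds, min(table(y)))
    if (k < hp$folds)
      warning(sprintf("reducing folds from %d to %d (smallest class size)",
                      hp$folds, k), call. = FALSE)
    if (k < 2) stopf("smallest class too small for cross-validation")
    fold <- integer(n)
    with_seed(seed, {
      for (cl in levels(droplevels(y))) {
        ix <- sample(which(y == cl))
        fold[ix] <- rep(seq_len(k), length.out = length(ix))
      }
    })
    acc <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      cw <- if (is.null(weights_fun)) NULL else weights_fun(y[tr])
      norm <- fit_normalizer(Z[tr, , drop = FALSE])
      st <- fit_linear_stage(apply_normalizer(norm, Z[tr, , drop = FALSE]),
                             droplevels(y[tr]), cost, cw)
      pred <- stage_decide(st, apply_normalizer(norm, Z[!tr, , drop = FALSE]))
      100 * mean(pred == as.character(y[!tr]))
    }, numeric(1))
    list(mean = mean(acc), sd = stats::sd(acc), folds = k, per_fold = acc)
  }

  seeds <- derive_seeds(hp$seed, 2)
  y1 <- factor(ifelse(labels3 == "A", "absent", "present"),
               levels = c("absent", "present"))
  s1 <- run_stage(X, y1, hp$cost_C, seed = seeds[1])
  pres <- labels3 != "A"
  y2 <- factor(ifelse(labels3[pres] == "M", "mild", "nonmild"),
               levels = c("mild", "nonmild"))
  wf <- function(ytr) {
    tab <- table(droplevels(ytr))
    w <- as.numeric(sum(tab) / (2 * tab)); names(w) <- names(tab); w
  }
  s2 <- run_stage(X[pres, , drop = FALSE], y2, hp$cost_C, weights_fun = wf,
                  seed = seeds[2])
  list(stage1 = s1, stage2 = s2)
}

#' Serialize / load a cascade model as JSON
#'
#' Stores stage weights and biases, the normalizer, hyperparameters, axis
#' and seed; [read_model()] restores a functioning `cascade_model`.
#'
#' @param model A `cascade_model`.
#' @param path JSON file path.
#' @return `path` invisibly (write) or a `cascade_model` (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  payload <- list(
    axis = model$axis,
    stage1 = model$stage1, stage2 = model$stage2,
    normalizer = list(center = model$normalizer$center,
                      scale = model$normalizer$scale),
    class_weights = as.list(model$class_weights),
    hyperparams = unclass(model$hyperparams),
    n_train = model$n_train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_stage <- function(s) list(weights = as.numeric(s$weights),
                                bias = s$bias, levels = s$levels)
  hp <- p$hyperparams
  structure(list(
    stage1 = fix_stage(p$stage1), stage2 = fix_stage(p$stage2),
    normalizer = structure(list(center = as.numeric(p$normalizer$center),
                                scale = as.numeric(p$normalizer$scale)),
                           class = "normalizer"),
    axis = p$axis,
    hyperparams = structure(list(axis = hp$axis, cost_C = hp$cost_C,
                                 gamma = hp$gamma,
                                 class_weights = hp$class_weights,
                                 folds = hp$folds,
                                 split_fraction = hp$split_fraction,
                                 seed = hp$seed),
                            class = "cascade_hyperparams"),
    class_weights = unlist(p$class_weights),
    n_train = p$n_train),
    class = "cascade_model")
}
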