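# Shared fixtures, generated in code at test time.

default_masks <- roi_masks(c(64, 64))

# A small, fast control-like subject (fewer counts than the acquisition
# default; unit tests that need the full 300k density draw their own).
quick_params <- function(seed = 1, ...) {
  subject_params(ef_true = 0.597, counts_per_frame = 60000L, seed = seed, ...)
}

# Tiny separable feature set for cascade unit tests: three Gaussian blobs
# (absent / mild / moderate-severe), widely separated.
toy_cohort <- function(n_per_class = c(A = 20, M = 8, MdS = 20), sep = 10,
                       d = 5, seed = 42) {
  centers <- list(A = rep(0, d), M = rep(sep, d), MdS = rep(2 * sep, d))
  X <- NULL; y <- NULL
  set.seed(seed)
  for (cl in names(n_per_class)) {
    X <- rbind(X, matrix(rnorm(n_per_class[[cl]] * d, 0, 1), ncol = d,
                         byrow = TRUE) +
                 matrix(centers[[cl]], n_per_class[[cl]], d, byrow = TRUE))
    y <- c(y, rep(cl, n_per_class[[cl]]))
  }
  list(X = X, y = factor(y, levels = c("A", "M", "MdS")))
}

# Build (truth, prediction) vectors realizing given per-class hit counts;
# misses are attributed to an arbitrary other class.
labels_from_counts <- function(correct, total) {
  lv <- c("A", "M", "MdS")
  truth <- rep(lv, total)
  pred <- unlist(lapply(1:3, function(i) {
    wrong <- lv[if (i == 1) 3 else 1]
    c(rep(lv[i], correct[i]), rep(wrong, total[i] - correct[i]))
  }))
  list(truth = truth, pred = pred)
}

# Independent brute-force consensus oracle: explicit frequency count, then
# explicit sorted-median walk (no shared code with consensus_label).
oracle_consensus <- function(codes) {
  lv <- c("A", "M", "Md", "S")
  counts <- vapply(lv, function(l) sum(codes == l), integer(1))
  winners <- lv[counts == max(counts) & counts > 0]
  if (length(winners) == 1) return(winners)
  vals <- sort(match(codes, lv))
  n <- length(vals)
  med <- if (n %% 2 == 1) vals[(n + 1) / 2] else vals[n / 2]  # lower median
  lv[med]
}
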