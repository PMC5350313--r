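#' Confusion matrix and hit rates on the 3-class scale
#'
#' Rows are true labels (`A`, `M`, `MdS`), columns are predictions.
#' Per-class hit rate is the diagonal over the row sum, the overall hit
#' rate the trace over the total, both as percentages rounded to 2
#' decimals.
#'
#' @param true_labels,predicted Equal-length label vectors on the 3-class
#'   scale (codes `Md`/`S` are collapsed to `MdS` automatically).
#' @return List with `confusion` (3 x 3 integer matrix), `per_class`
#'   (named percentages), `overall` (percentage).
#' @export
confusion_and_hit_rates <- function(true_labels, predicted) {
  if (length(true_labels) == 0) stopf("empty label vectors")
  if (length(true_labels) != length(predicted))
    stopf("label vectors differ in length")
  to3 <- function(x) {
    x <- as.character(x)
    x[x %in% c("Md", "S")] <- "MdS"
    factor(x, levels = CLASS3_LEVELS)
  }
  tr <- to3(true_labels); pr <- to3(predicted)
  cm <- table(true = tr, predicted = pr)
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(true = CLASS3_LEVELS,
                               predicted = CLASS3_LEVELS))
  rs <- rowSums(cm)
  per_class <- ifelse(rs > 0, round(100 * diag(cm) / rs, 2), NA_real_)
  names(per_class) <- CLASS3_LEVELS
  list(confusion = cm,
       per_class = per_class,
       overall = round(100 * sum(diag(cm)) / sum(cm), 2))
}

#' Class balance at a cascade stage
#'
#' Stage 1: percentage of absent versus present subjects over the whole
#' cohort. Stage 2: percentage of mild versus moderate-severe among the
#' present-dyssynchrony subjects only. Integers by round-half-up (a note is
#' attached when rounding makes the pair sum to 99 or 101).
#'
#' @param labels Severity codes (`A`, `M`, `Md`, `S`) or 3-class labels.
#' @param stage `"stage1"` or `"stage2"`.
#' @return Named integer vector of two percentages.
#' @export
class_proportions <- function(labels, stage = c("stage1", "stage2")) {
  stage <- match.arg(stage)
  if (length(labels) == 0) stopf("empty labels")
  x <- as.character(labels)
  x[x %in% c("Md", "S")] <- "MdS"
  if (stage == "stage1") {
    p <- c(absent = sum(x == "A"), present = sum(x != "A")) / length(x)
  } else {
    pres <- x[x != "A"]
    if (length(pres) == 0) stopf("no present-dyssynchrony subjects")
    p <- c(mild = sum(pres == "M"), nonmild = sum(pres == "MdS")) /
      length(pres)
  }
  out <- round_half_up(100 * p)
  storage.mode(out) <- "integer"
  if (sum(out) != 100L)
    attr(out, "note") <- sprintf("rounded percentages sum to %d", sum(out))
  out
}

# Tie-corrected Kendall's W over an n_subjects x n_raters ordinal matrix,
# using midranks within each rater. Returns NA when every rater is
# constant (denominator zero).
kendall_w_stat <- function(R) {
  n <- nrow(R); m <- ncol(R)
  ranks <- apply(R, 2, rank)
  Ttie <- apply(ranks, 2, function(r) {
    t <- table(r); sum(t^3 - t)
  })
  S <- sum((rowSums(ranks) - m * (n + 1) / 2)^2)
  denom <- m^2 * (n^3 - n) - m * sum(Ttie)
  if (denom <= 0) return(c(W = NA_real_, W_uncorrected = NA_real_))
  c(W = 12 * S / denom,
    W_uncorrected = 12 * S / (m^2 * (n^3 - n)))
}

#' Kendall's coefficient of concordance among raters
#'
#' Tie-corrected W with midranks: `W = 12 S / (m^2 (n^3 - n) - m sum(T))`,
#' where `S` is the sum of squared deviations of the rank sums and `T` the
#' standard per-rater tie correction. The p-value is obtained by seeded
#' permutation of each rater's codes (primary) and by the chi-square
#' approximation `chi^2 = m (n - 1) W` on `n - 1` degrees of freedom
#' (secondary). The uncorrected W is reported alongside.
#'
#' @param ratings `n_subjects x n_raters` matrix of ordinal codes (numeric,
#'   or characters in `A`, `M`, `Md`, `S`).
#' @param n_perm Number of permutations (default 10000; 0 skips the
#'   permutation test).
#' @param seed Integer seed for the permutation test.
#' @return Object of class `agreement_report`: `W`, `W_uncorrected`,
#'   `p_permutation`, `p_chisq`, `n_subjects`, `n_raters`, `n_perm`.
#' @export
kendall_w <- function(ratings, n_perm = 10000L, seed = 1L) {
  R <- as.matrix(ratings)
  if (is.character(R)) R <- matrix(dys_ordinal(R), nrow(R), ncol(R))
  if (nrow(R) < 2 || ncol(R) < 2)
    stopf("need at least 2 subjects and 2 raters")
  w <- kendall_w_stat(R)
  if (is.na(w["W"]))
    stopf("W undefined: every rater gave identical codes to all subjects")
  p_perm <- NA_real_
  if (n_perm > 0) {
    p_perm <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        Rp <- apply(R, 2, sample)
        wb <- kendall_w_stat(Rp)["W"]
        if (!is.na(wb) && wb >= w["W"]) hits <- hits + 1L
      }
      (1 + hits) / (n_perm + 1)
    })
  }
  n <- nrow(R); m <- ncol(R)
  structure(list(W = unname(w["W"]),
                 W_uncorrected = unname(w["W_uncorrected"]),
                 p_permutation = p_perm,
                 p_chisq = stats::pchisq(m * (n - 1) * w[["W"]], n - 1,
                                         lower.tail = FALSE),
                 n_subjects = n, n_raters = m, n_perm = n_perm),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Kendall's W = %.3f (uncorrected %.3f), %d subjects x %d raters\n",
    x$W, x$W_uncorrected, x$n_subjects, x$n_raters))
  cat(sprintf("  p (permutation, %d reps) = %.4g; p (chi-square) = %.4g\n",
              x$n_perm, x$p_permutation, x$p_chisq))
  invisible(x)
}
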