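#' Consensus severity label from a rater panel
#'
#' Returns the strictly most frequent code when one exists; otherwise the
#' median of the ordinal values (A=0 < M=1 < Md=2 < S=3). An even panel
#' with a half-integer median rounds toward the less severe code
#' (clinically conservative; a three-rater panel never hits this case).
#'
#' @param codes Character vector of codes in `A`, `M`, `Md`, `S` (one per
#'   rater; order irrelevant).
#' @return A single code.
#' @export
consensus_label <- function(codes) {
  if (length(codes) == 0) stopf("at least one rater code required")
  ords <- dys_ordinal(codes)
  tab <- table(ords)
  top <- tab[tab == max(tab)]
  if (length(top) == 1)
    return(DYS_LEVELS[as.integer(names(top)) + 1L])
  s <- sort(ords)
  lower_median <- s[floor((length(s) + 1) / 2)]
  DYS_LEVELS[lower_median + 1L]
}

#' Coarse cascade classes from a severity label
#'
#' Stage 1 separates absent from present dyssynchrony; stage 2 (defined
#' only for present cases) separates mild from moderate-severe, the two of
#' which the cascade never distinguishes.
#'
#' @param label A code in `A`, `M`, `Md`, `S`.
#' @return List with `stage1` (`"absent"`/`"present"`) and `stage2`
#'   (`"mild"`, `"nonmild"`, or `NA` for absent cases).
#' @export
coarse_classes <- function(label) {
  ord <- dys_ordinal(label)
  if (length(ord) != 1) stopf("coarse_classes takes a single label")
  if (ord == 0) return(list(stage1 = "absent", stage2 = NA_character_))
  list(stage1 = "present", stage2 = if (ord == 1) "mild" else "nonmild")
}

#' Collapse severity labels to the cascade's 3-class scale
#'
#' @param labels Character vector of codes in `A`, `M`, `Md`, `S`.
#' @return Factor with levels `A`, `M`, `MdS`.
#' @export
class3 <- function(labels) {
  ord <- dys_ordinal(labels)
  factor(CLASS3_LEVELS[pmin(ord, 2L) + 1L], levels = CLASS3_LEVELS)
}

#' Add consensus columns to a cohort table
#'
#' Applies [consensus_label()] across the per-rater code columns
#' (`lvrv_r1..`, `ilv_r1..`) of a cohort table, writing `lvrv_consensus`
#' and `ilv_consensus`.
#'
#' @param table Cohort data frame with rater code columns.
#' @return The table with consensus columns appended.
#' @export
add_consensus <- function(table) {
  for (axis in c("lvrv", "ilv")) {
    cols <- grep(sprintf("^%s_r[0-9]+$", axis), names(table), value = TRUE)
    if (length(cols) == 0) next
    table[[paste0(axis, "_consensus")]] <-
      apply(table[cols], 1, function(r) consensus_label(unname(r)))
  }
  table
}
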