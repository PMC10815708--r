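# Severe / non-severe partition of the cohort from THI scores.

#' Build a cohort phenotype table
#'
#' @param sample_id character sample identifiers (must be unique).
#' @param thi Tinnitus Handicap Inventory scores, integers in `[0, 100]`.
#' @return tibble with columns sample_id, thi (and, after
#'   [partition_by_thi()], subgroup).
#' @export
cohort_table <- function(sample_id, thi) {
  if (anyDuplicated(sample_id))
    stop("cohort_table: duplicate sample_id")
  thi <- as.double(thi)
  if (any(is.na(thi) | thi < 0 | thi > 100))
    stop("cohort_table: THI scores must lie in [0, 100]")
  tibble(sample_id = as.character(sample_id), thi = thi)
}

#' Partition a cohort into severe and non-severe tinnitus subgroups
#'
#' A sample is severe when its THI score strictly exceeds the third quartile
#' of the cohort's THI distribution ("higher than" — a score exactly equal
#' to Q3 is non-severe). Q3 is estimated by linear interpolation between
#' order statistics (`stats::quantile(type = 7)`, the common default in
#' statistical software); `threshold_override` substitutes any published
#' threshold (e.g. 68) for the data-driven Q3, making an external split
#' exactly reproducible.
#'
#' @param cohort a [cohort_table()].
#' @param threshold_override optional numeric threshold; when given, severe
#'   iff `thi > threshold_override`.
#' @return the cohort tibble with added columns `subgroup`
#'   ("severe"/"non_severe") and an attribute `thi_threshold` holding the
#'   threshold used.
#' @export
partition_by_thi <- function(cohort, threshold_override = NULL) {
  stopifnot(all(c("sample_id", "thi") %in% names(cohort)))
  if (is.null(threshold_override)) {
    if (nrow(cohort) < 4)
      stop("partition_by_thi: fewer than 4 samples; supply threshold_override")
    thr <- unname(quantile(cohort$thi, probs = 0.75, type = 7))
  } else {
    thr <- as.double(threshold_override)
  }
  out <- cohort
  out$subgroup <- ifelse(cohort$thi > thr, "severe", "non_severe")
  attr(out, "thi_threshold") <- thr
  out
}

#' Sample ids in one subgroup of a partitioned cohort
#' @param cohort output of [partition_by_thi()].
#' @param subgroup "severe" or "non_severe".
#' @return character vector of sample ids.
#' @export
subgroup_samples <- function(cohort, subgroup = c("severe", "non_severe")) {
  subgroup <- match.arg(subgroup)
  cohort$sample_id[cohort$subgroup == subgroup]
}
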