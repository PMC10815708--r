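# Interval arithmetic under the (start, end] convention.

#' Reciprocal overlap between two intervals
#'
#' The standard SV-matching criterion: with intersection
#' `I = max(0, min(end_a, end_b) - max(start_a, start_b))`, the reciprocal
#' overlap is `min(I / len(a), I / len(b))`. Symmetric in its arguments,
#' lies in `[0, 1]`, equals 1 only for identical intervals, and is invariant
#' under coordinate translation. Intervals on different chromosomes have
#' reciprocal overlap 0 by definition.
#'
#' Vectorized over its arguments (recycled pairwise).
#'
#' @param start_a,end_a,start_b,end_b interval coordinates
#'   (`(start, end]`, so length = end - start; must be positive).
#' @param chrom_a,chrom_b optional chromosome names; when supplied, pairs on
#'   different chromosomes return 0.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
reciprocal_overlap <- function(start_a, end_a, start_b, end_b,
                               chrom_a = NULL, chrom_b = NULL) {
  len_a <- end_a - start_a
  len_b <- end_b - start_b
  if (any(len_a <= 0) || any(len_b <= 0))
    stop("reciprocal_overlap: zero- or negative-length interval")
  i <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  ro <- pmin(i / len_a, i / len_b)
  if (!is.null(chrom_a) && !is.null(chrom_b)) {
    ro[normalize_chrom(chrom_a) != normalize_chrom(chrom_b)] <- 0
  }
  ro
}

#' Directional overlap of interval a by interval b
#'
#' Fraction of `a` covered by `b` (`I / len(a)`), the alternative to
#' reciprocal overlap selectable in [cluster_shared()].
#' @inheritParams reciprocal_overlap
#' @return numeric vector in `[0, 1]`.
#' @export
directional_overlap <- function(start_a, end_a, start_b, end_b,
                                chrom_a = NULL, chrom_b = NULL) {
  len_a <- end_a - start_a
  if (any(len_a <= 0)) stop("directional_overlap: zero-length interval")
  i <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  ov <- i / len_a
  if (!is.null(chrom_a) && !is.null(chrom_b)) {
    ov[normalize_chrom(chrom_a) != normalize_chrom(chrom_b)] <- 0
  }
  ov
}

#' Overlap in base pairs between interval rows of two tables
#'
#' Index-join helper over `(start, end]` intervals using IRanges; returns
#' one row per overlapping (query, subject) pair.
#'
#' @param query,subject data frames with chrom/start/end columns.
#' @param min_overlap_bp minimum intersection, in bp, to report a pair.
#' @return tibble with columns query_idx, subject_idx, overlap_bp.
#' @keywords internal
overlap_pairs <- function(query, subject, min_overlap_bp = 1) {
  if (!nrow(query) || !nrow(subject)) {
    return(tibble(query_idx = integer(), subject_idx = integer(),
                  overlap_bp = double()))
  }
  # affected bases are start+1 .. end
  q <- IRanges::IRanges(start = query$start + 1, end = query$end)
  s <- IRanges::IRanges(start = subject$start + 1, end = subject$end)
  hits <- IRanges::findOverlaps(q, s, minoverlap = min_overlap_bp)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same <- normalize_chrom(query$chrom[qi]) == normalize_chrom(subject$chrom[si])
  qi <- qi[same]; si <- si[same]
  ov <- pmin(query$end[qi], subject$end[si]) -
    pmax(query$start[qi], subject$start[si])
  keep <- ov >= min_overlap_bp
  tibble(query_idx = qi[keep], subject_idx = si[keep], overlap_bp = ov[keep])
}
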