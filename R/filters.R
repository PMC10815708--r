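# Per-caller call-level filters applied before the sharing analysis.

#' Remove oversize calls
#'
#' Drops calls whose length exceeds `max_length` ("greater than" is strict:
#' a call of exactly `max_length` bp is retained). The 100 kb default
#' reflects the resolution limit of exome-based CNV calling, where very
#' large calls are dominated by segmentation artifacts.
#'
#' @param calls an [sv_calls()] tibble.
#' @param max_length maximum retained length in bp.
#' @return the filtered tibble, input order preserved.
#' @export
filter_by_length <- function(calls, max_length = 100000) {
  calls[sv_length(calls) <= max_length, , drop = FALSE]
}

#' Retain calls by ACMG pathogenicity class
#'
#' Keeps pathogenic, likely pathogenic and uncertain-significance calls by
#' default; benign, likely benign and unclassified calls are dropped.
#'
#' @param calls an [sv_calls()] tibble.
#' @param keep_classes character vector of classes to retain.
#' @return the filtered tibble, input order preserved.
#' @export
filter_by_acmg <- function(calls,
                           keep_classes = c("pathogenic", "likely_pathogenic",
                                            "uncertain")) {
  bad <- setdiff(keep_classes, ACMG_CLASSES)
  if (length(bad)) stop("filter_by_acmg: unknown class(es): ",
                        paste(bad, collapse = ", "))
  calls[calls$acmg_class %in% keep_classes, , drop = FALSE]
}

#' Drop records with no well-defined interval (breakends, empty intervals)
#' @param calls an [sv_calls()] tibble.
#' @return tibble without BND and zero-length records.
#' @export
drop_non_interval <- function(calls) {
  calls[calls$svtype != "BND" & calls$end > calls$start, , drop = FALSE]
}
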