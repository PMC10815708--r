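#' @importFrom dplyr %>% arrange bind_rows distinct filter group_by left_join
#'   mutate n pull rename select summarise ungroup anti_join semi_join
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_dbl map_int map_lgl pmap
#' @importFrom stats median quantile rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# Interval convention used throughout the package: (start, end] on a 1-based
# genome. `start` is the base preceding the affected segment (VCF POS for a
# symbolic DEL/DUP record), `end` is the last affected base (VCF INFO/END),
# so the affected bases are start+1 .. end and length = end - start. This is
# the only convention under which the length of a call equals end - start
# for both VCF symbolic alleles and BED intervals read verbatim.

#' Recognized structural variant types
#' @keywords internal
SV_TYPES <- c("DEL", "DUP", "INV", "BND", "OTHER")

#' ACMG pathogenicity classes, ordered from most to least severe
#'
#' The ordering is used when a consensus record inherits the "worst" class
#' among its member calls: pathogenic > likely_pathogenic > uncertain >
#' likely_benign > benign > unclassified.
#' @export
ACMG_CLASSES <- c("pathogenic", "likely_pathogenic", "uncertain",
                  "likely_benign", "benign", "unclassified")

#' Build a validated table of SV calls
#'
#' An SV call set is a tibble with one row per call emitted by one caller for
#' one sample. Coordinates follow the package interval convention: `start` is
#' the base before the affected segment (VCF POS), `end` the last affected
#' base (VCF END), so `sv_length()` equals `end - start`.
#'
#' @param sample_id character, sample identifiers.
#' @param caller_id character, caller labels (e.g. "cnvkit", "manta",
#'   "tiddit"; arbitrary names are accepted).
#' @param chrom character chromosome names; a leading "chr" prefix is
#'   stripped so both dialects compare equal.
#' @param start,end integer-like coordinates, `end >= start`.
#' @param svtype one of DEL, DUP, INV, BND, OTHER.
#' @param acmg_class one of [ACMG_CLASSES]; defaults to "unclassified".
#' @param genotype one of "het", "hom", "unknown".
#' @return a tibble of class `sv_calls`.
#' @export
sv_calls <- function(sample_id = character(), caller_id = character(),
                     chrom = character(), start = integer(), end = integer(),
                     svtype = character(), acmg_class = "unclassified",
                     genotype = "unknown") {
  x <- tibble(
    sample_id = as.character(sample_id),
    caller_id = as.character(caller_id),
    chrom = normalize_chrom(as.character(chrom)),
    start = as.double(start),
    end = as.double(end),
    svtype = as.character(svtype),
    acmg_class = as.character(acmg_class),
    genotype = as.character(genotype)
  )
  validate_sv_calls(x)
}

validate_sv_calls <- function(x) {
  if (nrow(x)) {
    if (any(is.na(x$chrom) | !nzchar(x$chrom)))
      stop("sv_calls: chrom must be nonempty")
    if (any(x$end < x$start))
      stop("sv_calls: end must be >= start (negative length)")
    bad <- setdiff(unique(x$svtype), SV_TYPES)
    if (length(bad))
      stop("sv_calls: unknown svtype(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(x$acmg_class), ACMG_CLASSES)
    if (length(bad))
      stop("sv_calls: unknown acmg_class(es): ", paste(bad, collapse = ", "))
  }
  class(x) <- unique(c("sv_calls", class(x)))
  x
}

#' Length of a structural variant
#'
#' Under the `(start, end]` convention the number of affected bases is
#' `end - start`; this reproduces the printed length of every deletion and
#' duplication record the package ships as fixtures.
#'
#' @param calls an `sv_calls` tibble, or any data frame with `start`/`end`.
#' @return nonnegative numeric vector of lengths in bp.
#' @export
sv_length <- function(calls) {
  len <- calls$end - calls$start
  if (any(len < 0)) stop("sv_length: negative length (end < start)")
  len
}

#' Strip the "chr" prefix so both chromosome dialects match
#' @keywords internal
normalize_chrom <- function(chrom) sub("^chr", "", chrom)

#' Gene interval table
#'
#' @param gene_symbol,chrom,start,end,coding columns; coordinates use the
#'   package `(start, end]` convention (a BED row maps verbatim:
#'   internal start = BED start, internal end = BED end).
#' @return tibble with columns gene_symbol, chrom, start, end, coding.
#' @export
gene_intervals <- function(gene_symbol = character(), chrom = character(),
                           start = integer(), end = integer(), coding = TRUE) {
  x <- tibble(
    gene_symbol = as.character(gene_symbol),
    chrom = normalize_chrom(as.character(chrom)),
    start = as.double(start),
    end = as.double(end),
    coding = as.logical(coding)
  )
  if (nrow(x) && any(x$end < x$start))
    stop("gene_intervals: end must be >= start")
  x
}

#' Population SV database table (gnomAD-SV style)
#'
#' @param chrom,start,end,svtype interval columns as in [sv_calls()].
#' @param frequency_global,carriers_global global allele frequency in
#'   `[0, 1]` and carrier count.
#' @param frequency_subpop,carriers_subpop optional subpopulation columns
#'   (`NA` when absent).
#' @return tibble of population SV records.
#' @export
population_sv <- function(chrom = character(), start = integer(),
                          end = integer(), svtype = character(),
                          frequency_global = double(),
                          carriers_global = integer(),
                          frequency_subpop = NA_real_,
                          carriers_subpop = NA_integer_) {
  x <- tibble(
    chrom = normalize_chrom(as.character(chrom)),
    start = as.double(start),
    end = as.double(end),
    svtype = as.character(svtype),
    frequency_global = as.double(frequency_global),
    carriers_global = as.double(carriers_global),
    frequency_subpop = as.double(frequency_subpop),
    carriers_subpop = as.double(carriers_subpop)
  )
  if (nrow(x)) {
    if (any(x$end < x$start)) stop("population_sv: end must be >= start")
    fr <- c(x$frequency_global, x$frequency_subpop)
    if (any(fr < 0 | fr > 1, na.rm = TRUE))
      stop("population_sv: frequencies must lie in [0, 1]")
  }
  x
}

#' Gene constraint table (LOEUF / pLI)
#'
#' @param gene_symbol gene symbols.
#' @param loeuf loss-of-function observed/expected upper bound fraction;
#'   lower means more constrained.
#' @param pli probability of being loss-of-function intolerant, in `[0, 1]`.
#' @return tibble of constraint records.
#' @export
constraint_table <- function(gene_symbol = character(), loeuf = double(),
                             pli = double()) {
  x <- tibble(
    gene_symbol = as.character(gene_symbol),
    loeuf = as.double(loeuf),
    pli = as.double(pli)
  )
  if (nrow(x)) {
    if (any(x$loeuf < 0, na.rm = TRUE)) stop("constraint_table: loeuf must be >= 0")
    if (any(x$pli < 0 | x$pli > 1, na.rm = TRUE))
      stop("constraint_table: pli must lie in [0, 1]")
  }
  x
}

#' Rank ACMG classes, 1 = most severe
#' @keywords internal
acmg_rank <- function(class) match(class, ACMG_CLASSES)

#' Worst (most severe) ACMG class among a set of calls
#' @param classes character vector of ACMG classes.
#' @return single class label; "unclassified" for empty input.
#' @export
acmg_worst <- function(classes) {
  if (!length(classes)) return("unclassified")
  ACMG_CLASSES[min(acmg_rank(classes))]
}
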