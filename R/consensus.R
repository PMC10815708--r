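# Cross-caller consensus: candidates independently prioritized per caller
# are intersected, keeping regions supported by >= min_callers tools.

#' Intersect per-caller candidate regions into consensus candidates
#'
#' Candidates from different callers are matched when their reciprocal
#' overlap is at least `match_ro`, OR when both breakpoints differ by at
#' most `breakpoint_tol` bp — the second clause rescues near-identical
#' calls whose RO is skewed by a single stretched breakpoint. Matching
#' deliberately ignores `svtype`: callers are known to disagree on the
#' DEL/DUP label of the same event, and such conflicts must be surfaced,
#' not silently resolved. Groups (single-linkage components of the match
#' graph) supported by fewer than `min_callers` distinct callers are
#' dropped.
#'
#' Each consensus candidate carries the member-wise lower-median interval,
#' the majority svtype plus a `type_discordant` flag with the per-caller
#' types recorded, the union of carrier samples and gene symbols, the worst
#' ACMG class, and the set of supporting callers.
#'
#' @param per_caller_candidates tibble of per-caller candidate regions (one
#'   subgroup), as produced by [collapse_gene_rows()]: columns chrom, start,
#'   end, svtype, acmg_class, carrier_samples, caller_id, gene_symbols.
#' @param min_callers minimum distinct supporting callers (default 2).
#' @param match_ro reciprocal overlap for a cross-caller match (default 0.6).
#' @param breakpoint_tol breakpoint tolerance in bp for the rescue clause
#'   (default 200, chosen to comfortably cover the 1 bp / 70 bp start/end
#'   offsets observed between short-read SV callers on the same event).
#' @return tibble of consensus candidates with columns chrom, start, end,
#'   svtype, type_discordant, caller_types (list), acmg_class,
#'   carrier_samples (list), gene_symbols (list), supporting_callers (list).
#' @export
cross_caller_consensus <- function(per_caller_candidates, min_callers = 2,
                                   match_ro = 0.6, breakpoint_tol = 200) {
  x <- per_caller_candidates
  empty <- tibble(
    chrom = character(), start = double(), end = double(),
    svtype = character(), type_discordant = logical(), caller_types = list(),
    acmg_class = character(), carrier_samples = list(),
    gene_symbols = list(), supporting_callers = list()
  )
  if (!nrow(x)) return(empty)

  # breakpoint-proximity rescue can match intervals with zero overlap, so
  # consider all same-chromosome pairs
  all_pairs <- expand_same_chrom_pairs(x)
  a <- all_pairs$a; b <- all_pairs$b
  if (length(a)) {
    ro <- reciprocal_overlap(x$start[a], x$end[a], x$start[b], x$end[b])
    near <- abs(x$start[a] - x$start[b]) <= breakpoint_tol &
      abs(x$end[a] - x$end[b]) <= breakpoint_tol
    diff_caller <- x$caller_id[a] != x$caller_id[b]
    keep <- diff_caller & (ro >= match_ro | near)
    a <- a[keep]; b <- b[keep]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b), directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(x)))
  )
  comp <- igraph::components(g)$membership

  out <- lapply(split(seq_len(nrow(x)), comp), function(idx) {
    members <- x[idx, , drop = FALSE]
    callers <- sort(unique(members$caller_id))
    if (length(callers) < min_callers) return(NULL)
    types <- unique(members$svtype)
    tab <- sort(table(members$svtype), decreasing = TRUE)
    maj <- if (length(tab) > 1 && tab[1] == tab[2]) "OTHER" else names(tab)[1]
    tibble(
      chrom = members$chrom[1],
      start = lower_median(members$start),
      end = lower_median(members$end),
      svtype = maj,
      type_discordant = length(types) > 1,
      caller_types = list(setNames(members$svtype, members$caller_id)),
      acmg_class = acmg_worst(members$acmg_class),
      carrier_samples = list(sort(unique(unlist(members$carrier_samples)))),
      gene_symbols = list(sort(unique(unlist(members$gene_symbols)))),
      supporting_callers = list(callers)
    )
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) return(empty)
  arrange(out, chrom, start, end)
}

#' All unordered same-chromosome index pairs of a region table
#' @keywords internal
expand_same_chrom_pairs <- function(x) {
  idx <- split(seq_len(nrow(x)), x$chrom)
  a <- integer(); b <- integer()
  for (ii in idx) {
    if (length(ii) < 2) next
    cmb <- utils::combn(ii, 2)
    a <- c(a, cmb[1, ]); b <- c(b, cmb[2, ])
  }
  list(a = a, b = b)
}
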