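# Within-subgroup sharing analysis: single-linkage clustering of one
# caller's calls under a reciprocal-overlap criterion, the operation SV
# merging toolkits (SVDB and kin) perform when they collapse per-sample
# call sets into shared regions.

#' Cluster same-caller calls shared across samples of a subgroup
#'
#' Builds a graph over the calls with an edge wherever two calls lie on the
#' same chromosome, have the same `svtype`, and overlap reciprocally by at
#' least `min_ro`; connected components of this graph are the single-linkage
#' clusters. Clusters carried by fewer than `min_samples` distinct samples
#' are discarded — this is the "shared by two or more individuals of the
#' same subgroup" rule. Each retained cluster gets a representative
#' interval: the member-wise median of starts and ends (lower median on
#' ties) and the majority `svtype` (ties fall back to `OTHER` with
#' `type_ambiguous = TRUE`).
#'
#' @param calls an [sv_calls()] tibble, one caller, one subgroup, already
#'   length- and ACMG-filtered; BND records are excluded internally.
#' @param min_ro minimum reciprocal overlap linking two calls (default 0.6).
#' @param min_samples minimum number of distinct carrier samples (default 2).
#' @param overlap_mode `"reciprocal"` (default) or `"directional"`; in
#'   directional mode two calls are linked when either call covers the
#'   other by at least `min_ro`.
#' @return tibble of clusters with columns chrom, start, end, svtype,
#'   type_ambiguous, acmg_class (worst among members), carrier_samples
#'   (list), caller_id, n_members, member_idx (list of row indices into
#'   `calls`).
#' @export
cluster_shared <- function(calls, min_ro = 0.6, min_samples = 2,
                           overlap_mode = c("reciprocal", "directional")) {
  overlap_mode <- match.arg(overlap_mode)
  empty <- tibble(
    chrom = character(), start = double(), end = double(),
    svtype = character(), type_ambiguous = logical(),
    acmg_class = character(), carrier_samples = list(),
    caller_id = character(), n_members = integer(), member_idx = list()
  )
  calls <- drop_non_interval(calls)
  if (!nrow(calls)) return(empty)
  if (length(unique(calls$caller_id)) > 1)
    stop("cluster_shared: calls must come from a single caller")

  # candidate pairs restricted to >=1 bp overlap, then scored
  pairs <- overlap_pairs(calls, calls, min_overlap_bp = 1)
  pairs <- pairs[pairs$query_idx < pairs$subject_idx, , drop = FALSE]
  if (nrow(pairs)) {
    a <- pairs$query_idx; b <- pairs$subject_idx
    same_type <- calls$svtype[a] == calls$svtype[b]
    if (overlap_mode == "reciprocal") {
      sc <- reciprocal_overlap(calls$start[a], calls$end[a],
                               calls$start[b], calls$end[b])
    } else {
      sc <- pmax(
        directional_overlap(calls$start[a], calls$end[a],
                            calls$start[b], calls$end[b]),
        directional_overlap(calls$start[b], calls$end[b],
                            calls$start[a], calls$end[a])
      )
    }
    keep <- same_type & sc >= min_ro
    a <- a[keep]; b <- b[keep]
  } else {
    a <- integer(); b <- integer()
  }

  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(calls)))
  )
  comp <- igraph::components(g)$membership

  out <- lapply(split(seq_len(nrow(calls)), comp), function(idx) {
    members <- calls[idx, , drop = FALSE]
    carriers <- unique(members$sample_id)
    if (length(carriers) < min_samples) return(NULL)
    rep_iv <- cluster_representative(members)
    tibble(
      chrom = members$chrom[1],
      start = rep_iv$start, end = rep_iv$end,
      svtype = rep_iv$svtype, type_ambiguous = rep_iv$type_ambiguous,
      acmg_class = acmg_worst(members$acmg_class),
      carrier_samples = list(sort(carriers)),
      caller_id = members$caller_id[1],
      n_members = nrow(members),
      member_idx = list(idx)
    )
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) return(empty)
  arrange(out, chrom, start, end)
}

#' Representative interval of a cluster: lower-median breakpoints,
#' majority svtype
#' @keywords internal
cluster_representative <- function(members) {
  tab <- sort(table(members$svtype), decreasing = TRUE)
  tie <- length(tab) > 1 && tab[1] == tab[2]
  list(
    start = lower_median(members$start),
    end = lower_median(members$end),
    svtype = if (tie) "OTHER" else names(tab)[1],
    type_ambiguous = tie
  )
}

#' Lower median: the floor(n+1)/2-th order statistic
#' @keywords internal
lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]
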