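# Shared helpers: a brute-force single-linkage clustering oracle (kept
# deliberately independent of the package's igraph-based implementation)
# and a random-instance generator for property tests.

# Transitive closure over an explicit all-pairs adjacency matrix.
oracle_cluster_shared <- function(calls, min_ro = 0.6, min_samples = 2) {
  calls <- calls[calls$svtype != "BND" & calls$end > calls$start, , drop = FALSE]
  n <- nrow(calls)
  if (!n) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (calls$chrom[i] != calls$chrom[j]) next
      if (calls$svtype[i] != calls$svtype[j]) next
      inter <- max(0, min(calls$end[i], calls$end[j]) -
                     max(calls$start[i], calls$start[j]))
      ro <- min(inter / (calls$end[i] - calls$start[i]),
                inter / (calls$end[j] - calls$start[j]))
      if (ro >= min_ro) adj[i, j] <- TRUE
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- cid
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ]))))
      frontier <- setdiff(nxt, which(!is.na(comp)))
    }
  }
  keep <- Filter(
    function(idx) length(unique(calls$sample_id[idx])) >= min_samples,
    split(seq_len(n), comp)
  )
  unname(lapply(keep, sort))
}

random_call_instance <- function(n_max = 12, seed = 1) {
  set.seed(seed)
  n <- sample.int(n_max, 1)
  start <- sample.int(2000, n, replace = TRUE)
  len <- sample.int(300, n, replace = TRUE)
  sv_calls(
    sample_id = sample(paste0("P", 1:4), n, replace = TRUE),
    caller_id = "callerA",
    chrom = sample(c("1", "2"), n, replace = TRUE),
    start = start, end = start + len,
    svtype = sample(c("DEL", "DUP"), n, replace = TRUE),
    acmg_class = "uncertain"
  )
}

# canonical form of a clustering: sorted list of sorted member index sets
clustering_sets <- function(member_idx_list) {
  s <- lapply(member_idx_list, sort)
  s[order(vapply(s, function(x) paste(x, collapse = ","), character(1)))]
}
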