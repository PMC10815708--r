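# Population SV database annotation and gene-constraint ranking.

#' Find population-database SVs overlapping a candidate set
#'
#' Returns all database records overlapping each candidate by at least
#' `min_overlap_bp` (default 1 bp) and, by default, of the same SV type.
#' The permissive 1 bp default is deliberate: population references report
#' events that only partially tile a candidate region (a few-hundred-bp
#' duplication inside a multi-kb candidate is still informative), so any
#' reciprocal-overlap threshold is opt-in via `min_ro`. An empty match list
#' marks the candidate as absent from the reference population.
#'
#' @param candidates candidate tibble (chrom/start/end/svtype columns), e.g.
#'   from [cross_caller_consensus()].
#' @param db a [population_sv()] tibble.
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @param require_same_type match only records of the candidate's svtype
#'   (default TRUE).
#' @param min_ro optional reciprocal-overlap threshold (default 0 = off).
#' @return tibble with one row per (candidate, db record) match: candidate
#'   index and coordinates, the db record's columns, overlap_bp, ro and
#'   same_type; sorted by candidate then descending ro.
#' @export
find_popdb_overlaps <- function(candidates, db, min_overlap_bp = 1,
                                require_same_type = TRUE, min_ro = 0) {
  empty <- tibble(
    candidate_idx = integer(), chrom = character(),
    cand_start = double(), cand_end = double(), cand_svtype = character(),
    db_start = double(), db_end = double(), db_svtype = character(),
    frequency_global = double(), carriers_global = double(),
    frequency_subpop = double(), carriers_subpop = double(),
    overlap_bp = double(), ro = double(), same_type = logical()
  )
  if (!nrow(candidates) || !nrow(db)) return(empty)
  hits <- overlap_pairs(candidates, db, min_overlap_bp = min_overlap_bp)
  if (!nrow(hits)) return(empty)
  qi <- hits$query_idx; si <- hits$subject_idx
  ro <- reciprocal_overlap(candidates$start[qi], candidates$end[qi],
                           db$start[si], db$end[si])
  same <- candidates$svtype[qi] == db$svtype[si]
  keep <- ro >= min_ro & (!require_same_type | same)
  qi <- qi[keep]; si <- si[keep]
  out <- tibble(
    candidate_idx = qi,
    chrom = candidates$chrom[qi],
    cand_start = candidates$start[qi], cand_end = candidates$end[qi],
    cand_svtype = candidates$svtype[qi],
    db_start = db$start[si], db_end = db$end[si], db_svtype = db$svtype[si],
    frequency_global = db$frequency_global[si],
    carriers_global = db$carriers_global[si],
    frequency_subpop = db$frequency_subpop[si],
    carriers_subpop = db$carriers_subpop[si],
    overlap_bp = hits$overlap_bp[keep],
    ro = ro[keep],
    same_type = same[keep]
  )
  arrange(out, candidate_idx, dplyr::desc(ro))
}

#' Join LOEUF/pLI constraint scores onto candidate genes
#'
#' Every gene of every candidate is looked up in the constraint table;
#' genes absent from the table carry NA scores. The most-constrained gene
#' per candidate is the one with the lowest LOEUF, ties broken by the
#' highest pLI; genes without a LOEUF score never win.
#'
#' @param candidates candidate tibble with a gene_symbols list column.
#' @param constraints a [constraint_table()] tibble. Non-coding genes
#'   (e.g. microRNAs) typically have no LOEUF entry and surface as NA.
#' @return list with `gene_scores` (one row per candidate gene with loeuf,
#'   pli) and `most_constrained` (one row per candidate: candidate_idx,
#'   gene_symbol, loeuf, pli).
#' @export
join_constraints <- function(candidates, constraints) {
  gs <- tibble(
    candidate_idx = rep(seq_len(nrow(candidates)),
                        lengths(candidates$gene_symbols)),
    gene_symbol = unlist(candidates$gene_symbols, use.names = FALSE) %||% character()
  )
  gs <- left_join(gs, constraints, by = "gene_symbol")
  mc <- gs %>%
    filter(!is.na(loeuf)) %>%
    arrange(candidate_idx, loeuf, dplyr::desc(pli), gene_symbol) %>%
    group_by(candidate_idx) %>%
    dplyr::slice(1) %>%
    ungroup()
  list(gene_scores = gs, most_constrained = mc)
}

#' Most-constrained gene among a set of symbols
#'
#' Convenience wrapper over the [join_constraints()] ranking rule: lowest
#' LOEUF wins, ties broken by highest pLI.
#'
#' @param gene_symbols character vector.
#' @param constraints a [constraint_table()] tibble.
#' @return single gene symbol (NA if none has a score).
#' @export
most_constrained_gene <- function(gene_symbols, constraints) {
  x <- constraints[constraints$gene_symbol %in% gene_symbols, , drop = FALSE]
  x <- x[!is.na(x$loeuf), , drop = FALSE]
  if (!nrow(x)) return(NA_character_)
  x <- x[order(x$loeuf, -x$pli, x$gene_symbol), , drop = FALSE]
  x$gene_symbol[1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
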