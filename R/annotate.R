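# Split-style gene annotation of shared regions, blacklist filtering, and
# the subgroup-unique gene selection.

#' Annotate regions with overlapping genes (split rows)
#'
#' Emits one (region, gene) row per gene whose interval overlaps the region
#' by at least 1 bp, the "split" annotation style of AnnotSV-like tools
#' where a multi-gene SV becomes one row per covered gene.
#'
#' @param regions data frame with chrom/start/end columns (e.g. the output
#'   of [cluster_shared()]).
#' @param genes a [gene_intervals()] tibble.
#' @return `regions` expanded with columns gene_symbol and gene_coding; a
#'   region overlapping no gene contributes no rows.
#' @export
annotate_genes <- function(regions, genes) {
  empty <- dplyr::mutate(regions[0, , drop = FALSE],
                         gene_symbol = character(), gene_coding = logical())
  if (!nrow(regions) || !nrow(genes)) return(empty)
  hits <- overlap_pairs(regions, genes, min_overlap_bp = 1)
  if (!nrow(hits)) return(empty)
  out <- regions[hits$query_idx, , drop = FALSE]
  out$gene_symbol <- genes$gene_symbol[hits$subject_idx]
  out$gene_coding <- genes$coding[hits$subject_idx]
  arrange(out, chrom, start, end, gene_symbol)
}

#' Remove blacklisted gene rows (FLAGS and olfactory receptors)
#'
#' FLAGS (FrequentLy mutAted GeneS) and olfactory-receptor genes recur in
#' any exome cohort and are treated as likely artifacts. A (region, gene)
#' row is removed when its gene is on either list; a region disappears
#' entirely only when all of its gene rows are removed.
#'
#' @param rows output of [annotate_genes()].
#' @param flags_list,olfactory_list character vectors of gene symbols.
#' @return the filtered rows.
#' @export
filter_gene_blacklist <- function(rows, flags_list = character(),
                                  olfactory_list = character()) {
  black <- unique(c(flags_list, olfactory_list))
  rows[!(rows$gene_symbol %in% black), , drop = FALSE]
}

#' Retain severe-subgroup rows whose gene is unique to the severe subgroup
#'
#' A gene observed in any retained non-severe cluster is considered part of
#' the shared CNV background and its severe rows are excluded; a region
#' survives as long as at least one of its genes survives.
#'
#' @param severe_rows,nonsevere_rows annotated (region, gene) rows for the
#'   two subgroups, processed through identical preceding stages.
#' @return the retained severe rows.
#' @export
severe_unique_genes <- function(severe_rows, nonsevere_rows) {
  seen <- unique(nonsevere_rows$gene_symbol)
  severe_rows[!(severe_rows$gene_symbol %in% seen), , drop = FALSE]
}

#' Collapse annotated gene rows back to one row per region
#'
#' Inverse of the split annotation: regions identified by
#' (chrom, start, end, caller_id) with their surviving genes as a list
#' column.
#'
#' @param rows annotated (region, gene) rows.
#' @return tibble with one row per region and a gene_symbols list column.
#' @export
collapse_gene_rows <- function(rows) {
  if (!nrow(rows)) {
    out <- rows[, setdiff(names(rows), c("gene_symbol", "gene_coding")),
                drop = FALSE]
    out$gene_symbols <- list()
    return(out)
  }
  key <- paste(rows$caller_id, rows$chrom, rows$start, rows$end, rows$svtype)
  idx <- split(seq_len(nrow(rows)), key)
  out <- lapply(idx, function(i) {
    r <- rows[i[1], setdiff(names(rows), c("gene_symbol", "gene_coding")),
              drop = FALSE]
    r$gene_symbols <- list(sort(unique(rows$gene_symbol[i])))
    r
  })
  arrange(dplyr::bind_rows(out), chrom, start, end)
}
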