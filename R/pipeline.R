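# End-to-end prioritization cascade, mirroring the flowchart order:
# per caller and per subgroup, length filter -> ACMG filter -> shared-region
# clustering -> gene annotation -> blacklist filter -> severe-unique gene
# selection; the per-caller paths stay independent until the final
# >= 2-callers consensus, after which candidates are annotated against the
# population database and the constraint table.

#' Run the full SV prioritization pipeline
#'
#' @param calls combined [sv_calls()] for the whole cohort (all samples,
#'   all callers), e.g. from [read_vcf_manifest()].
#' @param cohort partitioned cohort from [partition_by_thi()].
#' @param genes gene model from [read_gene_bed()].
#' @param flags_list,olfactory_list blacklisted gene symbols.
#' @param popdb optional [population_sv()] table for frequency annotation.
#' @param constraints optional [constraint_table()] for LOEUF/pLI ranking.
#' @param max_sv_length length-filter cutoff in bp (default 100000).
#' @param keep_acmg ACMG classes retained (default pathogenic /
#'   likely_pathogenic / uncertain).
#' @param min_ro reciprocal overlap for within-subgroup sharing (default 0.6).
#' @param min_samples minimum carriers per shared region (default 2).
#' @param min_callers minimum supporting callers per candidate (default 2).
#' @param breakpoint_tol cross-caller breakpoint tolerance in bp
#'   (default 200).
#' @param overlap_mode "reciprocal" (default) or "directional" sharing
#'   criterion, passed to [cluster_shared()].
#' @param uniqueness_basis compare severe genes against non-severe
#'   "clusters" (default) or against raw post-filter non-severe "calls".
#' @return list with elements:
#'   * `candidates`: consensus candidate tibble (severe subgroup), with
#'     popdb_matches / constraint columns attached when the tables are
#'     given;
#'   * `report`: nested list of per-stage survivor counts (variants, genes,
#'     carrier individuals), JSON-serializable;
#'   * `stages`: per-caller intermediate tables for inspection.
#' @export
run_pipeline <- function(calls, cohort, genes,
                         flags_list = character(),
                         olfactory_list = character(),
                         popdb = NULL, constraints = NULL,
                         max_sv_length = 100000,
                         keep_acmg = c("pathogenic", "likely_pathogenic",
                                       "uncertain"),
                         min_ro = 0.6, min_samples = 2, min_callers = 2,
                         breakpoint_tol = 200,
                         overlap_mode = "reciprocal",
                         uniqueness_basis = c("clusters", "calls")) {
  uniqueness_basis <- match.arg(uniqueness_basis)
  if (!"subgroup" %in% names(cohort))
    stop("run_pipeline: cohort must be partitioned (see partition_by_thi)")
  unknown <- setdiff(unique(calls$sample_id), cohort$sample_id)
  if (length(unknown))
    stop("run_pipeline: calls reference samples absent from the cohort: ",
         paste(head(unknown, 5), collapse = ", "))

  callers <- sort(unique(calls$caller_id))
  sub_of <- setNames(cohort$subgroup, cohort$sample_id)
  stages <- list()
  report <- list(parameters = list(
    max_sv_length = max_sv_length, keep_acmg = keep_acmg, min_ro = min_ro,
    min_samples = min_samples, min_callers = min_callers,
    breakpoint_tol = breakpoint_tol, overlap_mode = overlap_mode,
    uniqueness_basis = uniqueness_basis,
    thi_threshold = attr(cohort, "thi_threshold")
  ))

  for (grp in c("severe", "non_severe")) {
    grp_samples <- subgroup_samples(cohort, grp)
    for (cl in callers) {
      raw <- calls[calls$caller_id == cl & calls$sample_id %in% grp_samples, ]
      len_f <- filter_by_length(raw, max_length = max_sv_length)
      acmg_f <- filter_by_acmg(len_f, keep_classes = keep_acmg)
      clusters <- cluster_shared(acmg_f, min_ro = min_ro,
                                 min_samples = min_samples,
                                 overlap_mode = overlap_mode)
      gene_rows <- annotate_genes(clusters, genes)
      kept_rows <- filter_gene_blacklist(gene_rows, flags_list, olfactory_list)
      stages[[grp]][[cl]] <- list(
        raw = raw, length_filtered = len_f, acmg_filtered = acmg_f,
        clusters = clusters, gene_rows = gene_rows, blacklist_kept = kept_rows
      )
      report[[grp]][[cl]] <- list(
        n_raw = nrow(raw),
        n_after_length = nrow(len_f),
        n_after_acmg = nrow(acmg_f),
        n_shared_clusters = nrow(clusters),
        n_gene_rows = nrow(gene_rows),
        n_after_blacklist = length(unique(region_key(kept_rows))),
        n_genes = length(unique(kept_rows$gene_symbol)),
        n_carriers = length(unique(unlist(kept_rows$carrier_samples)))
      )
    }
  }

  # severe-unique gene selection, per caller path
  per_caller <- list()
  for (cl in callers) {
    sev <- stages[["severe"]][[cl]]$blacklist_kept
    if (uniqueness_basis == "clusters") {
      ns_genes_tbl <- stages[["non_severe"]][[cl]]$blacklist_kept
    } else {
      ns_calls <- stages[["non_severe"]][[cl]]$acmg_filtered
      ns_genes_tbl <- annotate_genes(drop_non_interval(ns_calls), genes)
    }
    uniq <- severe_unique_genes(sev, ns_genes_tbl)
    stages[["severe"]][[cl]]$unique_rows <- uniq
    report[["severe"]][[cl]]$n_after_unique <-
      length(unique(region_key(uniq)))
    report[["severe"]][[cl]]$n_genes_unique <-
      length(unique(uniq$gene_symbol))
    per_caller[[cl]] <- collapse_gene_rows(uniq)
  }
  per_caller_tbl <- dplyr::bind_rows(per_caller)

  candidates <- cross_caller_consensus(per_caller_tbl,
                                       min_callers = min_callers,
                                       match_ro = min_ro,
                                       breakpoint_tol = breakpoint_tol)
  report$consensus <- list(
    n_candidates = nrow(candidates),
    n_genes = length(unique(unlist(candidates$gene_symbols))),
    n_carriers = length(unique(unlist(candidates$carrier_samples))),
    n_type_discordant = sum(candidates$type_discordant)
  )

  if (!is.null(popdb) && nrow(candidates)) {
    matches <- find_popdb_overlaps(candidates, popdb)
    candidates$popdb_matches <- lapply(seq_len(nrow(candidates)), function(i)
      matches[matches$candidate_idx == i, , drop = FALSE])
    candidates$popdb_n_matches <- vapply(candidates$popdb_matches, nrow,
                                         integer(1))
  }
  if (!is.null(constraints) && nrow(candidates)) {
    jc <- join_constraints(candidates, constraints)
    mc <- jc$most_constrained
    idx <- match(seq_len(nrow(candidates)), mc$candidate_idx)
    candidates$most_constrained_gene <- mc$gene_symbol[idx]
    candidates$most_constrained_loeuf <- mc$loeuf[idx]
    candidates$most_constrained_pli <- mc$pli[idx]
  }

  list(candidates = candidates, report = report, stages = stages)
}

#' Stable identity of a region row (caller x interval)
#' @keywords internal
region_key <- function(rows) {
  if (!nrow(rows)) return(character())
  paste(rows$caller_id, rows$chrom, rows$start, rows$end, rows$svtype)
}

#' Write a pipeline stage report as JSON
#' @param report the `report` element of [run_pipeline()]'s result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_stage_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
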