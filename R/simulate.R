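# Seeded generator of a full synthetic input bundle: per-sample per-caller
# VCFs, phenotype table, gene model, blacklists, population database,
# constraint and expression tables, plus a machine-readable truth set.
# Coordinates live on a sequence-free mini-genome (two 25 Mb chromosomes):
# the pipeline never touches bases, only intervals.
#
# Design notes:
#  * Category-scoped RNG substreams (seed + category name) make the draws
#    of one category independent of whether another category is enabled.
#  * Planted events are separated from the random background: background
#    calls are rejection-sampled away from planted loci (50 kb margin) so
#    that each truth entry's expected fate is decidable by construction.
#  * Caller dropout never leaves a planted event with fewer than two
#    callers covering all of its carriers, so a planted candidate remains
#    recoverable by the >=2-callers consensus; the jitter/dropout model
#    stresses the matcher, not the study design.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the shape of the study cohort the pipeline was built
#' around: 310 samples whose THI distribution has its third quartile at 68
#' (so 75 samples fall in the severe subgroup), three callers per sample,
#' four planted severe-specific shared SVs (three ERBB3-like deletions and
#' one 22.5 kb multi-gene duplication), inter-caller breakpoint jitter of
#' up to 5 bp at the start and 70 bp at the end, and occasional DEL/DUP
#' type disagreement between callers.
#'
#' @param n_samples cohort size.
#' @param thi_q3_target third quartile of the generated THI distribution.
#' @param n_severe_carrier_sets planted severe-specific shared SVs
#'   (expected candidates).
#' @param n_nonsevere_shared shared SVs planted only in non-severe samples.
#' @param n_cross_group_shared SVs shared by both subgroups (must be
#'   rejected at the severe-unique-gene step).
#' @param n_blacklist_decoys shared severe SVs covering only blacklisted
#'   genes (rejected at gene filtering).
#' @param n_oversize_decoys shared severe SVs longer than 100 kb (rejected
#'   at the length filter).
#' @param n_benign_decoys shared severe SVs with benign ACMG class
#'   (rejected at the ACMG filter).
#' @param n_single_caller_decoys shared severe SVs emitted by one caller
#'   only (rejected at the cross-caller consensus).
#' @param background_mean Poisson mean of private background SVs per
#'   sample.
#' @param jitter_start,jitter_end per-caller breakpoint jitter: offsets
#'   drawn uniformly in `[-jitter_start, jitter_start]` /
#'   `[-jitter_end, jitter_end]`.
#' @param caller_dropout probability that one caller misses a planted call
#'   in one carrier (capped so the event keeps >= 2 fully-supporting
#'   callers).
#' @param type_mislabel probability that one caller reports the opposite
#'   DEL/DUP type for a planted severe event (the cross-caller
#'   type-discordance scenario).
#' @param callers caller labels.
#' @param rng_seed integer seed; all randomness derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 310, thi_q3_target = 68,
                       n_severe_carrier_sets = 4, n_nonsevere_shared = 5,
                       n_cross_group_shared = 3, n_blacklist_decoys = 3,
                       n_oversize_decoys = 2, n_benign_decoys = 3,
                       n_single_caller_decoys = 2,
                       background_mean = 20,
                       jitter_start = 5, jitter_end = 70,
                       caller_dropout = 0.1, type_mislabel = 0.1,
                       callers = c("cnvkit", "manta", "tiddit"),
                       rng_seed = 1) {
  stopifnot(n_samples >= 8, length(callers) >= 2,
            caller_dropout >= 0, caller_dropout < 1,
            type_mislabel >= 0, type_mislabel <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# fixed mini-genome
SIM_CONTIGS <- c(`1` = 25e6, `2` = 25e6)

#' Substream seed derived from the master seed and a category name
#' @keywords internal
substream_seed <- function(seed, name) {
  (abs(as.integer(seed)) %% 1000000L) * 1009L + sum(utf8ToInt(name))
}

#' Deterministic gene model and planted loci for a configuration
#' @keywords internal
sim_layout <- function(config) {
  gene <- function(symbol, chrom, start, end, coding = TRUE)
    tibble(gene_symbol = symbol, chrom = as.character(chrom),
           start = start, end = end, coding = coding)
  n_sev <- config$n_severe_carrier_sets

  fixture_genes <- dplyr::bind_rows(
    gene("ERBB3", 1, 5600000, 5604000),
    gene("COPS6", 2, 4000200, 4003000),
    gene("MCM7", 2, 4003200, 4010000),
    gene("MIR25", 2, 4004100, 4004200, coding = FALSE),
    gene("MIR93", 2, 4005000, 4005100, coding = FALSE),
    gene("MIR106B", 2, 4006000, 4006100, coding = FALSE),
    gene("TAF6", 2, 4010500, 4016000),
    gene("AP4M1", 2, 4016500, 4022500)
  )
  # planted severe events: three ERBB3-like deletions + one multi-gene dup,
  # then additional single-gene deletions if more are requested
  sev <- tibble(
    chrom = c("1", "1", "1", "2"),
    start = c(5600100, 5601200, 5602400, 4000500),
    end = c(5600900, 5602050, 5603300, 4023000),
    svtype = c("DEL", "DEL", "DEL", "DUP")
  )[seq_len(min(n_sev, 4)), ]
  extra_genes <- NULL
  if (n_sev > 4) {
    i <- seq_len(n_sev - 4)
    extra_genes <- gene(sprintf("SEVG%02d", i + 4), 1,
                        6200000 + (i - 1) * 100000,
                        6200000 + (i - 1) * 100000 + 4000)
    sev <- dplyr::bind_rows(sev, tibble(
      chrom = "1",
      start = extra_genes$start + 500,
      end = extra_genes$start + 2000,
      svtype = "DEL"
    ))
  }

  mk_block <- function(n, prefix, chrom, base, spacing = 100000,
                       gene_w = 4000, sv_off = 500, sv_len = 1500,
                       svtype = "DEL") {
    if (!n) return(list(genes = NULL, svs = NULL))
    i <- seq_len(n)
    g <- gene(sprintf("%s%02d", prefix, i), chrom,
              base + (i - 1) * spacing, base + (i - 1) * spacing + gene_w)
    s <- tibble(chrom = as.character(chrom), start = g$start + sv_off,
                end = g$start + sv_off + sv_len, svtype = svtype)
    list(genes = g, svs = s)
  }

  ns <- mk_block(config$n_nonsevere_shared, "NSG", 2, 6000000)
  xg <- mk_block(config$n_cross_group_shared, "XG", 1, 9000000)
  bn <- mk_block(config$n_benign_decoys, "BNG", 1, 15000000)
  sc <- mk_block(config$n_single_caller_decoys, "SCG", 2, 18000000,
                 sv_len = 1800)
  # oversize: 150 kb events spanning a small gene
  os <- NULL; os_sv <- NULL
  if (config$n_oversize_decoys) {
    i <- seq_len(config$n_oversize_decoys)
    os <- gene(sprintf("OSG%02d", i), 2, 15000000 + (i - 1) * 300000,
               15000000 + (i - 1) * 300000 + 5000)
    os_sv <- tibble(chrom = "2", start = os$start - 10000,
                    end = os$start - 10000 + 150000, svtype = "DUP")
  }
  # blacklist decoys sit inside genes that are on the FLAGS/olfactory lists
  bl_symbols <- c(read_gene_list(svprior_extdata("flags_genes.txt")),
                  read_gene_list(svprior_extdata("olfactory_genes.txt")))
  bl <- NULL; bl_sv <- NULL
  if (config$n_blacklist_decoys) {
    i <- seq_len(config$n_blacklist_decoys)
    bl <- gene(bl_symbols[(i - 1) %% length(bl_symbols) + 1], 1,
               12000000 + (i - 1) * 200000,
               12000000 + (i - 1) * 200000 + 50000)
    bl_sv <- tibble(chrom = "1", start = bl$start + 1000,
                    end = bl$start + 3000, svtype = "DEL")
  }
  # background decoy genes, kept away from every planted locus
  i <- 0:23
  bg_genes <- dplyr::bind_rows(
    gene(sprintf("DECOY%03d", i + 1), 1, 200000 + i * 140000,
         200000 + i * 140000 + 3000),
    gene(sprintf("DECOY%03d", i + 25), 2, 200000 + i * 140000,
         200000 + i * 140000 + 3000),
    gene(sprintf("DECOY%03d", 48 + 1:15), 1, 20000000 + (1:15 - 1) * 300000,
         20000000 + (1:15 - 1) * 300000 + 3000),
    gene(sprintf("DECOY%03d", 63 + 1:15), 2, 20000000 + (1:15 - 1) * 300000,
         20000000 + (1:15 - 1) * 300000 + 3000)
  )

  genes <- dplyr::bind_rows(fixture_genes, extra_genes, ns$genes, xg$genes,
                            bn$genes, sc$genes, os, bl, bg_genes)
  planted <- dplyr::bind_rows(
    dplyr::mutate(sev, category = "severe"),
    if (!is.null(ns$svs)) dplyr::mutate(ns$svs, category = "nonsevere_shared"),
    if (!is.null(xg$svs)) dplyr::mutate(xg$svs, category = "cross_group"),
    if (!is.null(bl_sv)) dplyr::mutate(bl_sv, category = "blacklist"),
    if (!is.null(os_sv)) dplyr::mutate(os_sv, category = "oversize"),
    if (!is.null(bn$svs)) dplyr::mutate(bn$svs, category = "benign"),
    if (!is.null(sc$svs)) dplyr::mutate(sc$svs, category = "single_caller")
  )
  planted$truth_id <- sprintf("%s_%02d", planted$category,
                              stats::ave(seq_len(nrow(planted)),
                                         planted$category, FUN = seq_along))
  list(genes = genes, planted = planted)
}

#' Generate THI scores whose third quartile sits exactly at the target
#'
#' The sorted scores place four copies of the target value across the Q3
#' interpolation window, scores strictly below it underneath and scores of
#' target+1 .. 100 above, so `quantile(type = 7)` returns the target
#' exactly and the number of strictly-greater scores is fixed by n.
#' @keywords internal
sim_thi_scores <- function(n, q3) {
  h <- 0.75 * (n - 1) + 1
  k <- floor(h)
  n_above <- n - (k + 3)
  stopifnot(k >= 1, n_above >= 1)
  low <- pmin(q3 - 1, round((q3 - 1) * stats::rbeta(k - 1, 2, 1.5)))
  high <- sample((q3 + 1):100, n_above, replace = TRUE)
  sorted <- c(sort(low), rep(q3, 4), sort(high))
  sorted[sample.int(n)]
}

#' Generate a synthetic cohort bundle with a known truth set
#'
#' Produces the full set of pipeline inputs — per-sample per-caller SV
#' calls, phenotype table, gene model, blacklists, population SV database,
#' constraint table and expression matrices — together with a truth table
#' recording every planted event, its carriers and the pipeline stage at
#' which it must be retained or rejected. Deterministic for a fixed
#' `rng_seed`; when `out_dir` is given the bundle is also written to disk
#' as VCF/BED/TSV/JSON files plus a VCF manifest.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory to write the bundle into.
#' @return list of class `sv_cohort_bundle` with elements calls, phenotype,
#'   genes, flags, olfactory, popdb, constraints, expression, truth,
#'   config, contigs (and `dir` when written).
#' @export
generate_cohort <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  layout <- sim_layout(config)
  callers <- config$callers
  seed <- config$rng_seed

  # --- phenotype ---
  set.seed(substream_seed(seed, "thi"))
  sample_ids <- sprintf("S%03d", seq_len(config$n_samples))
  thi <- sim_thi_scores(config$n_samples, config$thi_q3_target)
  phenotype <- cohort_table(sample_ids, thi)
  severe_ids <- sample_ids[thi > config$thi_q3_target]
  nonsevere_ids <- setdiff(sample_ids, severe_ids)

  # --- planted events ---
  planted <- layout$planted
  truth_rows <- list()
  planted_calls <- list()
  for (i in seq_len(nrow(planted))) {
    p <- planted[i, ]
    set.seed(substream_seed(seed, paste0("plant_", p$truth_id)))
    carriers <- switch(
      p$category,
      nonsevere_shared = sample(nonsevere_ids, 2),
      cross_group = c(sample(severe_ids, 2), sample(nonsevere_ids, 2)),
      sample(severe_ids, 2)
    )
    use_callers <- if (p$category == "single_caller") sample(callers, 1) else callers
    acmg <- if (p$category == "benign") {
      sample(c("benign", "likely_benign"), 1)
    } else "uncertain"

    # per-carrier caller dropout, keeping >= 2 callers that cover every
    # carrier (the event must stay recoverable by the consensus rule)
    present <- matrix(TRUE, nrow = length(carriers), ncol = length(use_callers),
                      dimnames = list(carriers, use_callers))
    # cross-group events emulate CNVs common to the whole cohort: every
    # caller sees them in every carrier, so their rejection at the
    # severe-unique step is decidable in each per-caller path
    if (length(use_callers) >= 3 && config$caller_dropout > 0 &&
        p$category != "cross_group") {
      for (ci in seq_along(carriers)) {
        drop <- which(runif(length(use_callers)) < config$caller_dropout)
        if (length(drop) > 1) drop <- drop[1]
        present[ci, drop] <- FALSE
      }
      full <- which(colSums(present) == length(carriers))
      if (length(full) < 2) {
        restore <- setdiff(seq_along(use_callers), full)[seq_len(2 - length(full))]
        present[, restore] <- TRUE
        full <- which(colSums(present) == length(carriers))
      }
    } else {
      full <- seq_along(use_callers)
    }

    mislabeled <- NA_character_
    if (p$category == "severe" && p$svtype %in% c("DEL", "DUP") &&
        runif(1) < config$type_mislabel) {
      mislabeled <- use_callers[sample(full, 1)]
    }

    for (ci in seq_along(carriers)) {
      for (ki in seq_along(use_callers)) {
        if (!present[ci, ki]) next
        cl <- use_callers[ki]
        type <- p$svtype
        if (!is.na(mislabeled) && cl == mislabeled)
          type <- if (type == "DEL") "DUP" else "DEL"
        planted_calls[[length(planted_calls) + 1]] <- tibble(
          sample_id = carriers[ci], caller_id = cl, chrom = p$chrom,
          start = p$start + sample(-config$jitter_start:config$jitter_start, 1),
          end = p$end + sample(-config$jitter_end:config$jitter_end, 1),
          svtype = type, acmg_class = acmg, genotype = "het"
        )
      }
    }

    genes_hit <- annotate_genes(p, layout$genes)$gene_symbol
    truth_rows[[i]] <- tibble(
      truth_id = p$truth_id, category = p$category,
      chrom = p$chrom, start = p$start, end = p$end, svtype = p$svtype,
      genes = list(sort(unique(genes_hit))),
      carriers = list(sort(carriers)),
      callers = list(sort(use_callers)),
      mislabeled_caller = mislabeled,
      expected = switch(p$category,
                        severe = "candidate",
                        nonsevere_shared = "not_reported",
                        cross_group = "rejected_uniqueness",
                        blacklist = "rejected_blacklist",
                        oversize = "rejected_length",
                        benign = "rejected_acmg",
                        single_caller = "rejected_consensus")
    )
  }
  truth <- dplyr::bind_rows(truth_rows)

  # --- background private calls, rejection-sampled off the planted loci ---
  set.seed(substream_seed(seed, "background"))
  keepout <- dplyr::transmute(planted, chrom,
                              start = start - 50000, end = end + 50000)
  n_bg <- rpois(config$n_samples, config$background_mean)
  bg <- draw_background_calls(sum(n_bg), keepout)
  bg$sample_id <- rep(sample_ids, n_bg)
  bg$caller_id <- sample(callers, nrow(bg), replace = TRUE)
  bg$genotype <- "het"

  calls <- validate_sv_calls(dplyr::bind_rows(
    dplyr::bind_rows(planted_calls), bg
  ))

  # --- population database: near-copies of candidate truths + background ---
  set.seed(substream_seed(seed, "popdb"))
  cand <- truth[truth$expected == "candidate", ]
  near <- tibble(
    chrom = cand$chrom,
    start = cand$start + sample(0:3, nrow(cand), replace = TRUE),
    end = cand$end - sample(0:5, nrow(cand), replace = TRUE),
    svtype = cand$svtype,
    frequency_global = round(10^runif(nrow(cand), -5, -3.7), 8),
    carriers_global = sample(1:15, nrow(cand), replace = TRUE),
    frequency_subpop = 0, carriers_subpop = 0
  )
  bgdb <- draw_background_calls(20, keepout)
  popdb <- population_sv(
    chrom = c(near$chrom, bgdb$chrom),
    start = c(near$start, bgdb$start), end = c(near$end, bgdb$end),
    svtype = c(near$svtype, bgdb$svtype),
    frequency_global = c(near$frequency_global,
                         round(10^runif(20, -5, -2), 8)),
    carriers_global = c(near$carriers_global, sample(1:200, 20, replace = TRUE)),
    frequency_subpop = c(near$frequency_subpop, rep(0, 20)),
    carriers_subpop = c(near$carriers_subpop, rep(0, 20))
  )

  # --- constraints: published scores for the fixture genes, synthetic
  #     scores for the remaining coding genes ---
  set.seed(substream_seed(seed, "constraints"))
  fixed <- constraint_fixture()
  other <- layout$genes$gene_symbol[layout$genes$coding &
                                      !(layout$genes$gene_symbol %in%
                                          fixed$gene_symbol)]
  other <- unique(other)
  constraints <- dplyr::bind_rows(
    fixed,
    constraint_table(other, loeuf = round(runif(length(other), 0.3, 1.9), 3),
                     pli = round(stats::rbeta(length(other), 0.4, 1.2), 3))
  )

  bundle <- structure(list(
    calls = calls, phenotype = phenotype, genes = layout$genes,
    flags = read_gene_list(svprior_extdata("flags_genes.txt")),
    olfactory = read_gene_list(svprior_extdata("olfactory_genes.txt")),
    popdb = popdb, constraints = constraints,
    expression = expression_fixtures(),
    truth = truth, config = config, contigs = SIM_CONTIGS
  ), class = "sv_cohort_bundle")

  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir)
    bundle$dir <- out_dir
  }
  bundle
}

#' Draw background calls uniformly, avoiding keep-out intervals
#' @keywords internal
draw_background_calls <- function(n, keepout) {
  out <- tibble(chrom = character(), start = double(), end = double(),
                svtype = character(), acmg_class = character())
  while (nrow(out) < n) {
    m <- n - nrow(out)
    chrom <- as.character(sample(1:2, m, replace = TRUE))
    len <- sample(100:5000, m, replace = TRUE)
    start <- floor(runif(m, 1, SIM_CONTIGS[1] - 6000))
    cand <- tibble(
      chrom = chrom, start = start, end = start + len,
      svtype = sample(c("DEL", "DUP"), m, replace = TRUE),
      acmg_class = sample(c("benign", "likely_benign", "uncertain"), m,
                          replace = TRUE, prob = c(0.4, 0.3, 0.3))
    )
    bad <- overlap_pairs(cand, keepout, min_overlap_bp = 1)$query_idx
    if (length(bad)) cand <- cand[-unique(bad), , drop = FALSE]
    out <- dplyr::bind_rows(out, cand)
  }
  out
}

#' Write a synthetic bundle to disk as standard formats
#'
#' Writes per-sample per-caller VCFs plus a manifest, phenotype TSV, gene
#' BED (with a coding flag column), blacklist lists, population DB TSV,
#' constraint TSV, expression TSVs with the ortholog map, and the truth set
#' as JSON. File contents are byte-deterministic given the bundle.
#'
#' @param bundle an `sv_cohort_bundle` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "expression"), showWarnings = FALSE)

  samples <- bundle$phenotype$sample_id
  callers <- bundle$config$callers
  man <- tidyr::crossing(sample = samples, caller = callers)
  man$path <- file.path("vcf", paste0(man$sample, ".", man$caller, ".vcf"))
  for (i in seq_len(nrow(man))) {
    sub <- bundle$calls[bundle$calls$sample_id == man$sample[i] &
                          bundle$calls$caller_id == man$caller[i], ]
    write_sv_vcf(sub, file.path(dir, man$path[i]), contigs = bundle$contigs)
  }
  readr::write_tsv(man, file.path(dir, "manifest.tsv"))
  readr::write_tsv(bundle$phenotype, file.path(dir, "phenotype.tsv"))

  g <- bundle$genes
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d", g$chrom, as.integer(g$start),
                     as.integer(g$end), g$gene_symbol, as.integer(g$coding)),
             file.path(dir, "genes.bed"))
  writeLines(bundle$flags, file.path(dir, "flags.txt"))
  writeLines(bundle$olfactory, file.path(dir, "olfactory.txt"))

  db <- bundle$popdb
  readr::write_tsv(
    tibble(chrom = db$chrom, start = db$start, end = db$end,
           svtype = db$svtype, freq_global = db$frequency_global,
           n_global = db$carriers_global, freq_subpop = db$frequency_subpop,
           n_subpop = db$carriers_subpop),
    file.path(dir, "population_sv.tsv"))
  readr::write_tsv(
    tibble(gene = bundle$constraints$gene_symbol,
           loeuf = bundle$constraints$loeuf, pli = bundle$constraints$pli),
    file.path(dir, "constraints.tsv"))

  for (nm in c("brain", "cochlea", "sgn")) {
    ds <- bundle$expression[[nm]]
    df <- tibble::as_tibble(data.frame(gene = rownames(ds$values), ds$values,
                                       check.names = FALSE))
    readr::write_tsv(df, file.path(dir, "expression", paste0(nm, ".tsv")))
  }
  readr::write_tsv(bundle$expression$orthologs,
                   file.path(dir, "expression", "orthologs.tsv"))

  truth_json <- bundle$truth
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Score planted-truth recovery of a pipeline run
#'
#' A reported candidate matches a truth entry when both lie on the same
#' chromosome and overlap reciprocally by at least `min_ro` (SV type is
#' ignored, because a type-discordant consensus may carry an OTHER label).
#' Precision is the fraction of reported candidates matching an expected
#' truth, recall the fraction of expected truths recovered, and
#' flag accuracy the fraction of mislabel-planted truths whose recovered
#' candidate carries `type_discordant = TRUE` (vacuously 1 when no
#' mislabel was planted).
#'
#' @param candidates candidate tibble from [run_pipeline()].
#' @param truth truth tibble from [generate_cohort()].
#' @param min_ro match threshold (default 0.6).
#' @return list with precision, recall, flag_accuracy, n_candidates,
#'   n_expected, n_mislabeled and a per-truth `matches` tibble.
#' @export
score_recovery <- function(candidates, truth, min_ro = 0.6) {
  expected <- truth[truth$expected == "candidate", , drop = FALSE]
  match_tbl <- tibble(truth_id = expected$truth_id,
                      matched = FALSE, type_discordant = NA)
  cand_matched <- rep(FALSE, nrow(candidates))
  for (i in seq_len(nrow(expected))) {
    if (!nrow(candidates)) break
    ro <- reciprocal_overlap(expected$start[i], expected$end[i],
                             candidates$start, candidates$end,
                             chrom_a = expected$chrom[i],
                             chrom_b = candidates$chrom)
    hit <- which(ro >= min_ro)
    if (length(hit)) {
      match_tbl$matched[i] <- TRUE
      match_tbl$type_discordant[i] <- any(candidates$type_discordant[hit])
      cand_matched[hit] <- TRUE
    }
  }
  mis <- expected$truth_id[!is.na(expected$mislabeled_caller)]
  mis_rows <- match_tbl[match_tbl$truth_id %in% mis, , drop = FALSE]
  flag_acc <- if (nrow(mis_rows)) {
    mean(mis_rows$matched & mis_rows$type_discordant %in% TRUE)
  } else 1
  list(
    precision = if (nrow(candidates)) mean(cand_matched) else 1,
    recall = if (nrow(expected)) mean(match_tbl$matched) else 1,
    flag_accuracy = flag_acc,
    n_candidates = nrow(candidates),
    n_expected = nrow(expected),
    n_mislabeled = length(mis),
    matches = match_tbl
  )
}

#' Check that every planted decoy is rejected at its designed stage
#'
#' Inspects the per-stage tables of a [run_pipeline()] result and verifies,
#' for each truth entry, that its region is still present immediately
#' before its designated rejection stage and absent immediately after it
#' (oversize events at the length filter, benign events at the ACMG
#' filter, blacklist-only events at gene filtering, cross-group events at
#' the severe-unique step, single-caller events at the consensus; severe
#' events must reach the final candidate list and non-severe events must
#' not be reported).
#'
#' @param result a [run_pipeline()] result (with `stages`).
#' @param truth truth tibble from [generate_cohort()].
#' @param min_ro interval-match threshold (default 0.6).
#' @return tibble with truth_id, category, ok.
#' @export
score_decoy_rejection <- function(result, truth, min_ro = 0.6) {
  stages <- result$stages
  present <- function(tbls, t) {
    any(vapply(tbls, function(tb) {
      if (is.null(tb) || !nrow(tb)) return(FALSE)
      ro <- reciprocal_overlap(t$start, t$end, tb$start, tb$end,
                               chrom_a = t$chrom, chrom_b = tb$chrom)
      any(ro >= min_ro)
    }, logical(1)))
  }
  pick <- function(grp, what) lapply(stages[[grp]], `[[`, what)
  out <- lapply(seq_len(nrow(truth)), function(i) {
    t <- truth[i, ]
    ok <- switch(
      t$category,
      oversize = present(pick("severe", "raw"), t) &&
        !present(pick("severe", "length_filtered"), t),
      benign = present(pick("severe", "length_filtered"), t) &&
        !present(pick("severe", "acmg_filtered"), t),
      blacklist = present(pick("severe", "gene_rows"), t) &&
        !present(pick("severe", "blacklist_kept"), t),
      cross_group = present(pick("severe", "blacklist_kept"), t) &&
        !present(pick("severe", "unique_rows"), t),
      single_caller = present(pick("severe", "unique_rows"), t) &&
        !present(list(result$candidates), t),
      nonsevere_shared = present(pick("non_severe", "blacklist_kept"), t) &&
        !present(list(result$candidates), t),
      severe = present(list(result$candidates), t)
    )
    tibble(truth_id = t$truth_id, category = t$category, ok = isTRUE(ok))
  })
  dplyr::bind_rows(out)
}

#' Run the prioritization pipeline on a generated bundle
#'
#' Convenience wrapper: partitions the bundle's phenotype table at the
#' configured THI threshold and runs [run_pipeline()] with the bundle's
#' gene model, blacklists, population DB and constraints.
#'
#' @param bundle an `sv_cohort_bundle`.
#' @param calls optional call table overriding `bundle$calls` (e.g. calls
#'   re-read from the written VCFs).
#' @param ... passed to [run_pipeline()].
#' @return a [run_pipeline()] result.
#' @export
run_bundle <- function(bundle, calls = NULL, ...) {
  cohort <- partition_by_thi(bundle$phenotype)
  run_pipeline(
    calls = calls %||% bundle$calls, cohort = cohort, genes = bundle$genes,
    flags_list = bundle$flags, olfactory_list = bundle$olfactory,
    popdb = bundle$popdb, constraints = bundle$constraints, ...
  )
}
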