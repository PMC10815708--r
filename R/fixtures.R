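# Accessors for the small plain-text fixtures shipped with the package:
# the published candidate-SV coordinates, the population-database records
# overlapping them, the constraint table, and synthetic stand-ins (labelled
# ".synthetic" in their filenames) for the gene model and the three
# expression databases, whose real counterparts are either access-restricted
# or too large to ship.

svprior_extdata <- function(file) {
  p <- system.file("extdata", file, package = "svprior")
  if (!nzchar(p)) stop("fixture not found: ", file)
  p
}

#' Published candidate SV coordinates (worked example input)
#'
#' The four deletion/duplication candidates reported in individuals with
#' severe tinnitus: three rare deletions in ERBB3 (chr12) carried by two
#' individuals, and a 23.2 kb duplication (chr7) covering AP4M1, COPS6,
#' MCM7, TAF6 and three microRNA genes, carried by two other individuals.
#'
#' @return tibble with chrom, start, end, svtype, acmg and an individuals
#'   list column.
#' @export
candidate_sv_fixture <- function() {
  x <- readr::read_tsv(svprior_extdata("candidate_svs.tsv"),
                       show_col_types = FALSE)
  x$individuals <- strsplit(x$individuals, ",")
  x
}

#' Expand the candidate fixture into a multi-caller toy call set
#'
#' Each fixture SV is emitted once per listed carrier and per caller, with
#' uncertain-significance ACMG class — the minimal input on which the full
#' cascade reproduces the published four-candidate, eight-gene outcome.
#'
#' @param callers caller labels to emulate (default the two short-read SV
#'   callers that supported the published candidates).
#' @return an [sv_calls()] tibble.
#' @export
toy_two_caller_calls <- function(callers = c("manta", "tiddit")) {
  fx <- candidate_sv_fixture()
  rows <- tidyr::crossing(i = seq_len(nrow(fx)), caller_id = callers)
  out <- lapply(seq_len(nrow(rows)), function(r) {
    i <- rows$i[r]
    samples <- fx$individuals[[i]]
    sv_calls(
      sample_id = samples,
      caller_id = rows$caller_id[r],
      chrom = fx$chrom[i], start = fx$start[i], end = fx$end[i],
      svtype = fx$svtype[i], acmg_class = fx$acmg[i], genotype = "het"
    )
  })
  validate_sv_calls(dplyr::bind_rows(out))
}

#' Phenotype table for the worked-example carriers
#'
#' THI scores of the four carrier individuals (80 for the deletion
#' carriers, 76 for the duplication carriers), all above the severe-tinnitus
#' threshold of 68.
#' @return a [cohort_table()].
#' @export
toy_cohort <- function() {
  cohort_table(
    sample_id = c("I4-40", "I4-41", "I4-28", "I4-37"),
    thi = c(80, 80, 76, 76)
  )
}

#' Gene model covering the candidate regions (synthetic stand-in)
#'
#' Eight gene intervals on chr12/chr7 enclosing the fixture SVs. The
#' coordinates approximate the true gene extents but are synthetic — they
#' are a stand-in for a full transcript model, sufficient for split-style
#' annotation of the fixture regions.
#' @return a [gene_intervals()] tibble.
#' @export
candidate_gene_model <- function() {
  read_gene_bed(svprior_extdata("candidate_genes.synthetic.bed"))
}

#' Population SV records overlapping the candidate regions
#'
#' Seven gnomAD-style records (four deletions, three duplications) with
#' global and Non-Finnish-European frequency/carrier columns.
#' @return a [population_sv()] tibble.
#' @export
population_db_fixture <- function() {
  read_population_db(svprior_extdata("population_svs.tsv"))
}

#' LOEUF / pLI constraint scores for the five coding candidate genes
#' @return a [constraint_table()] tibble.
#' @export
constraint_fixture <- function() {
  read_constraints(svprior_extdata("gene_constraints.tsv"))
}

#' FLAGS and olfactory-receptor blacklists (subset fixtures)
#' @return list with elements `flags` and `olfactory`.
#' @export
blacklist_fixture <- function() {
  list(
    flags = read_gene_list(svprior_extdata("flags_genes.txt")),
    olfactory = read_gene_list(svprior_extdata("olfactory_genes.txt"))
  )
}

#' Synthetic expression datasets for the candidate genes
#'
#' Three datasets emulating the structure of the public sources used for
#' candidate-gene expression profiling: human brain RNA-Seq (TPM, 13
#' tissues), mouse cochlear hair/non-hair cells (RPKM) and mouse spiral
#' ganglion neuron microarray intensities. Values are synthetic but
#' reproduce the qualitative pattern of interest (ERBB3 and COPS6 expressed
#' everywhere, AP4M1 absent from SGN, microRNA genes not expressed).
#'
#' @return list with three [expression_dataset()] objects (`brain`,
#'   `cochlea`, `sgn`) and the `orthologs` map.
#' @export
expression_fixtures <- function() {
  list(
    brain = read_expression_tsv(
      svprior_extdata("expression_brain_tpm.synthetic.tsv"),
      name = "brain", unit = "TPM", species = "human"),
    cochlea = read_expression_tsv(
      svprior_extdata("expression_cochlea_rpkm.synthetic.tsv"),
      name = "cochlea", unit = "RPKM", species = "mouse"),
    sgn = read_expression_tsv(
      svprior_extdata("expression_sgn_microarray.synthetic.tsv"),
      name = "sgn", unit = "intensity", species = "mouse"),
    orthologs = read_ortholog_map(svprior_extdata("ortholog_map.tsv"))
  )
}
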