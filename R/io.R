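# Readers and writers for the standard formats the pipeline touches.
# VCF parsing is delegated to vcfR; coordinates are taken verbatim from
# POS/END (no re-basing), per the package (start, end] convention.

#' Read one caller's SV call set from a VCF file
#'
#' Parses a VCF with symbolic SV alleles (INFO keys `SVTYPE`, `END`,
#' `SVLEN`). `END` missing but `SVLEN` present is recovered as
#' `END = POS + |SVLEN|`; records lacking both are skipped with a warning.
#' The ACMG class is read from a configurable INFO key and defaults to
#' `"unclassified"` when absent; classification itself happens upstream of
#' this package. BND records carry no well-defined interval: they are
#' retained at parse time (with `end = start`) but are excluded from all
#' downstream interval operations.
#'
#' @param path path to a VCF (plain text or bgzipped).
#' @param caller_id label recorded as the call provenance.
#' @param sample_id sample the file belongs to.
#' @param acmg_key INFO key holding the ACMG class annotation.
#' @return an [sv_calls()] tibble, one row per usable VCF record.
#' @export
read_caller_vcf <- function(path, caller_id, sample_id, acmg_key = "ACMG") {
  if (!file.exists(path)) stop("read_caller_vcf: no such file: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("read_caller_vcf: cannot parse VCF '", path,
                             "': ", conditionMessage(e))
  )
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  keep <- !is.na(fix[, "POS"])
  fix <- fix[keep, , drop = FALSE]
  if (!nrow(fix)) {
    return(sv_calls())
  }
  info <- fix[, "INFO"]
  pos <- as.double(fix[, "POS"])
  svtype <- info_field(info, "SVTYPE")
  svtype <- ifelse(is.na(svtype), "OTHER",
                   ifelse(svtype %in% SV_TYPES, svtype, "OTHER"))
  end <- suppressWarnings(as.double(info_field(info, "END")))
  svlen <- suppressWarnings(as.double(info_field(info, "SVLEN")))
  derive <- is.na(end) & !is.na(svlen)
  end[derive] <- pos[derive] + abs(svlen[derive])
  # BND junctions have no END; keep them as zero-length placeholders
  is_bnd <- svtype == "BND"
  end[is_bnd & is.na(end)] <- pos[is_bnd & is.na(end)]
  drop <- is.na(end)
  if (any(drop)) {
    warning("read_caller_vcf: skipping ", sum(drop), " record(s) in '",
            basename(path), "' lacking both END and SVLEN")
  }
  bad_len <- !drop & end < pos
  if (any(bad_len)) {
    stop("read_caller_vcf: negative computed length at ", path, " line(s) ",
         paste(which(bad_len), collapse = ","))
  }
  acmg <- info_field(info, acmg_key)
  acmg <- ifelse(is.na(acmg) | !(acmg %in% ACMG_CLASSES), "unclassified", acmg)
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"), error = function(e) NULL)
  geno <- rep("unknown", nrow(fix))
  if (!is.null(gt) && ncol(gt) >= 1) {
    g <- gt[keep, 1]
    geno <- dplyr::case_when(
      g %in% c("0/1", "0|1", "1/0", "1|0") ~ "het",
      g %in% c("1/1", "1|1") ~ "hom",
      TRUE ~ "unknown"
    )
  }
  keep2 <- !drop
  sv_calls(
    sample_id = rep(sample_id, sum(keep2)),
    caller_id = rep(caller_id, sum(keep2)),
    chrom = fix[keep2, "CHROM"],
    start = pos[keep2],
    end = end[keep2],
    svtype = svtype[keep2],
    acmg_class = acmg[keep2],
    genotype = geno[keep2]
  )
}

#' Extract a single key from semicolon-delimited INFO strings
#' @keywords internal
info_field <- function(info, key) {
  vapply(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]*"), info)),
         function(x) if (length(x)) sub(paste0(".*", key, "="), "", x[[1]]) else NA_character_,
         character(1))
}

#' Read a manifest of per-sample per-caller VCFs into one call table
#'
#' @param manifest_path TSV with columns `sample`, `caller`, `path`
#'   (relative paths resolved against the manifest's directory).
#' @param acmg_key passed to [read_caller_vcf()].
#' @return combined [sv_calls()] tibble.
#' @export
read_vcf_manifest <- function(manifest_path, acmg_key = "ACMG") {
  man <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  stopifnot(all(c("sample", "caller", "path") %in% names(man)))
  base <- dirname(manifest_path)
  paths <- ifelse(file.exists(man$path), man$path, file.path(base, man$path))
  out <- purrr::pmap(list(paths, man$caller, man$sample), function(p, cl, s) {
    read_caller_vcf(p, caller_id = cl, sample_id = s, acmg_key = acmg_key)
  })
  validate_sv_calls(dplyr::bind_rows(out))
}

#' Write SV calls for one sample/caller as a minimal symbolic-allele VCF
#'
#' Emits VCF 4.2 with INFO keys SVTYPE/END/SVLEN/ACMG and a GT column, the
#' dialect [read_caller_vcf()] consumes; used by the synthetic-cohort
#' generator and for round-trip testing.
#'
#' @param calls an [sv_calls()] tibble for a single sample and caller.
#' @param path output file path.
#' @param contigs optional named numeric vector of contig lengths.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, contigs = NULL) {
  stopifnot(length(unique(calls$sample_id)) <= 1,
            length(unique(calls$caller_id)) <= 1)
  sample <- if (nrow(calls)) calls$sample_id[1] else "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT\">",
    "##INFO=<ID=ACMG,Number=1,Type=String,Description=\"ACMG pathogenicity class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  body <- character(0)
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$start, calls$end)
    calls <- calls[o, ]
    svlen <- ifelse(calls$svtype == "DEL", -(calls$end - calls$start),
                    calls$end - calls$start)
    gt <- c(het = "0/1", hom = "1/1", unknown = "./.")[calls$genotype]
    body <- sprintf(
      "%s\t%d\tsv%d\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d;ACMG=%s\tGT\t%s",
      calls$chrom, as.integer(calls$start), seq_len(nrow(calls)),
      calls$svtype, calls$svtype, as.integer(calls$end), as.integer(svlen),
      calls$acmg_class, gt
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a gene model from a BED file
#'
#' BED is 0-based half-open; under the package `(start, end]` convention the
#' coordinates map verbatim (internal start = BED start, internal end = BED
#' end), so overlap arithmetic against VCF-derived calls is consistent.
#' An optional 5th column with values in {0, 1} marks protein-coding genes
#' (default: coding).
#'
#' @param path BED file with at least 4 columns (chrom, start, end, name).
#' @return a [gene_intervals()] tibble.
#' @export
read_gene_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) return(gene_intervals())
  parts <- strsplit(lines, "\t")
  ncol <- vapply(parts, length, integer(1))
  if (any(ncol < 4))
    stop("read_gene_bed: line ", which(ncol < 4)[1], " has fewer than 4 columns")
  start <- suppressWarnings(as.double(vapply(parts, `[`, character(1), 2)))
  end <- suppressWarnings(as.double(vapply(parts, `[`, character(1), 3)))
  if (any(is.na(start) | is.na(end)))
    stop("read_gene_bed: malformed coordinates at line ",
         which(is.na(start) | is.na(end))[1])
  coding <- rep(TRUE, length(parts))
  has5 <- ncol >= 5
  coding[has5] <- vapply(parts[has5], `[`, character(1), 5) != "0"
  gene_intervals(
    gene_symbol = vapply(parts, `[`, character(1), 4),
    chrom = vapply(parts, `[`, character(1), 1),
    start = start, end = end, coding = coding
  )
}

#' Read a population SV database TSV
#'
#' Expected columns: chrom, start, end, svtype, freq_global, n_global and
#' optionally freq_subpop, n_subpop. Frequencies are consumed as given and
#' never recomputed from carrier counts.
#'
#' @param path headered TSV.
#' @return a [population_sv()] tibble.
#' @export
read_population_db <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("chrom", "start", "end", "svtype", "freq_global", "n_global")
  if (!all(need %in% names(x)))
    stop("read_population_db: missing column(s): ",
         paste(setdiff(need, names(x)), collapse = ", "))
  population_sv(
    chrom = x$chrom, start = x$start, end = x$end, svtype = x$svtype,
    frequency_global = x$freq_global, carriers_global = x$n_global,
    frequency_subpop = if ("freq_subpop" %in% names(x)) x$freq_subpop else NA_real_,
    carriers_subpop = if ("n_subpop" %in% names(x)) x$n_subpop else NA_real_
  )
}

#' Read a gene constraint TSV (columns gene, loeuf, pli)
#' @param path headered TSV.
#' @return a [constraint_table()] tibble.
#' @export
read_constraints <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene", "loeuf", "pli")
  if (!all(need %in% names(x)))
    stop("read_constraints: missing column(s): ",
         paste(setdiff(need, names(x)), collapse = ", "))
  constraint_table(gene_symbol = x$gene, loeuf = x$loeuf, pli = x$pli)
}

#' Read a phenotype table (columns sample_id, thi)
#' @param path headered TSV.
#' @return tibble with sample_id and thi columns; see [partition_by_thi()].
#' @export
read_phenotype <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample_id", "thi") %in% names(x)))
    stop("read_phenotype: need columns sample_id, thi")
  cohort_table(x$sample_id, x$thi)
}

#' Read a plain-text gene symbol list (one symbol per line)
#' @param path text file; blank lines and `#` comments ignored.
#' @return character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write the final candidate table as TSV
#'
#' One row per consensus candidate with columns Chr, Start, End, Length,
#' SVType, Individuals (comma-joined, sorted), GeneSymbols (comma-joined,
#' sorted), ACMG, CallerSupport and TypeDiscordant, sorted by
#' (chrom, start, end) for deterministic output.
#'
#' @param candidates a candidate tibble as produced by
#'   [cross_caller_consensus()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  cols <- c("Chr", "Start", "End", "Length", "SVType", "Individuals",
            "GeneSymbols", "ACMG", "CallerSupport", "TypeDiscordant")
  if (!nrow(candidates)) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- tibble(
    Chr = candidates$chrom,
    Start = as.integer(candidates$start),
    End = as.integer(candidates$end),
    Length = as.integer(candidates$end - candidates$start),
    SVType = candidates$svtype,
    Individuals = map_chr(candidates$carrier_samples,
                          ~ paste(sort(unique(.x)), collapse = ",")),
    GeneSymbols = map_chr(candidates$gene_symbols,
                          ~ paste(sort(unique(.x)), collapse = ",")),
    ACMG = candidates$acmg_class,
    CallerSupport = map_chr(candidates$supporting_callers,
                            ~ paste(sort(unique(.x)), collapse = ",")),
    TypeDiscordant = candidates$type_discordant
  )
  out <- out[order(chrom_rank(out$Chr), out$Start, out$End), ]
  readr::write_tsv(out, path)
  invisible(path)
}

#' Natural chromosome ordering (1..22 numerically, then X, Y, others)
#' @keywords internal
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(normalize_chrom(as.character(chrom))))
  rank <- ifelse(is.na(num), 1000 + match(chrom, sort(unique(chrom))), num)
  rank
}
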