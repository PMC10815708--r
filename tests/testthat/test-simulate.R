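small_cfg <- function(seed = 1, ...) {
  sim_config(n_samples = 40, rng_seed = seed, ...)
}

test_that("generation is byte-deterministic under a fixed seed", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_cohort(small_cfg(seed = 7), out_dir = d1)
  generate_cohort(small_cfg(seed = 7), out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the content
  d3 <- file.path(tempdir(), "bundle_c")
  unlink(d3, recursive = TRUE)
  generate_cohort(small_cfg(seed = 8), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "phenotype.tsv")),
                         readLines(file.path(d3, "phenotype.tsv"))))
})

test_that("the truth set lists the configured number of expected candidates", {
  b <- generate_cohort(small_cfg(seed = 2))
  expect_equal(sum(b$truth$expected == "candidate"), 4)
  b6 <- generate_cohort(sim_config(n_samples = 40, n_severe_carrier_sets = 6,
                                   rng_seed = 2))
  expect_equal(sum(b6$truth$expected == "candidate"), 6)
  # decoy categories are mutually exclusive by id
  expect_false(anyDuplicated(b$truth$truth_id) > 0)
})

test_that("planted events keep >= 2 carriers and >= 2 callers in the calls", {
  b <- generate_cohort(small_cfg(seed = 3))
  for (i in seq_len(nrow(b$truth))) {
    t <- b$truth[i, ]
    if (t$category == "single_caller") next
    ro <- reciprocal_overlap(t$start, t$end, b$calls$start, b$calls$end,
                             chrom_a = t$chrom, chrom_b = b$calls$chrom)
    hits <- b$calls[ro >= 0.6, ]
    expect_true(length(unique(hits$sample_id)) >= 2, info = t$truth_id)
    expect_true(length(unique(hits$caller_id)) >= 2, info = t$truth_id)
  }
})

test_that("planted carriers sit in their intended subgroup", {
  b <- generate_cohort(small_cfg(seed = 4))
  coh <- partition_by_thi(b$phenotype)
  severe <- subgroup_samples(coh, "severe")
  for (i in seq_len(nrow(b$truth))) {
    t <- b$truth[i, ]
    if (t$category %in% c("severe", "blacklist", "oversize", "benign",
                          "single_caller")) {
      expect_true(all(t$carriers[[1]] %in% severe), info = t$truth_id)
    }
    if (t$category == "nonsevere_shared") {
      expect_true(all(!t$carriers[[1]] %in% severe), info = t$truth_id)
    }
  }
})

test_that("a planted type mislabel shows up as the opposite type in the calls", {
  # scan seeds until a mislabel is planted, then verify the calls
  found <- FALSE
  for (seed in 1:20) {
    b <- generate_cohort(small_cfg(seed = seed))
    mis <- b$truth[!is.na(b$truth$mislabeled_caller), ]
    if (!nrow(mis)) next
    found <- TRUE
    t <- mis[1, ]
    hits <- b$calls[b$calls$chrom == t$chrom &
                      b$calls$start >= t$start - 100 &
                      b$calls$end <= t$end + 100, ]
    flipped <- hits[hits$caller_id == t$mislabeled_caller, ]
    straight <- hits[hits$caller_id != t$mislabeled_caller, ]
    expect_true(nrow(flipped) >= 2)
    expect_true(all(flipped$svtype != t$svtype))
    expect_true(all(straight$svtype == t$svtype))
    break
  }
  expect_true(found)
})

test_that("background calls avoid planted loci and are mostly private", {
  b <- generate_cohort(small_cfg(seed = 5))
  planted_regions <- b$truth
  bg <- b$calls
  # calls overlapping a planted region trace to the carriers of some
  # planted event there (background is rejection-sampled off these loci)
  for (i in seq_len(nrow(planted_regions))) {
    t <- planted_regions[i, ]
    near <- bg[bg$chrom == t$chrom & bg$end > t$start - 10000 &
                 bg$start < t$end + 10000, ]
    window_truths <- planted_regions[
      planted_regions$chrom == t$chrom &
        planted_regions$end > t$start - 11000 &
        planted_regions$start < t$end + 11000, ]
    allowed <- unique(unlist(window_truths$carriers))
    expect_true(all(near$sample_id %in% allowed), info = t$truth_id)
  }
})

test_that("configuration invariants are enforced at construction", {
  expect_error(sim_config(n_samples = 4), "n_samples")
  expect_error(sim_config(caller_dropout = 1), "caller_dropout")
  expect_error(sim_config(callers = "only_one"), "callers")
})

test_that("written bundles reload into the same pipeline outcome", {
  d <- file.path(tempdir(), "bundle_rt")
  unlink(d, recursive = TRUE)
  b <- generate_cohort(small_cfg(seed = 6), out_dir = d)
  calls2 <- read_vcf_manifest(file.path(d, "manifest.tsv"))
  key <- function(x) sort(paste(x$sample_id, x$caller_id, x$chrom, x$start,
                                x$end, x$svtype, x$acmg_class))
  expect_identical(key(calls2), key(b$calls))
  pheno <- read_phenotype(file.path(d, "phenotype.tsv"))
  expect_equal(pheno$thi, b$phenotype$thi)
  genes <- read_gene_bed(file.path(d, "genes.bed"))
  expect_equal(nrow(genes), nrow(b$genes))
  res_mem <- run_bundle(b)
  res_dsk <- run_bundle(b, calls = calls2)
  expect_equal(res_mem$candidates$start, res_dsk$candidates$start)
  expect_equal(score_recovery(res_dsk$candidates, b$truth)$recall, 1)
})
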