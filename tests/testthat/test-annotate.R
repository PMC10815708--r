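test_that("split annotation emits one row per overlapped gene", {
  genes <- candidate_gene_model()
  dup <- tibble::tibble(chrom = "7", start = 100089053, end = 100112257,
                        svtype = "DUP", caller_id = "manta")
  rows <- annotate_genes(dup, genes)
  expect_setequal(rows$gene_symbol,
                  c("AP4M1", "COPS6", "MCM7", "MIR106B", "MIR25", "MIR93",
                    "TAF6"))
  expect_equal(nrow(rows), 7)
  expect_equal(sum(rows$gene_coding), 4)  # the three microRNAs are non-coding

  none <- tibble::tibble(chrom = "7", start = 1, end = 1000,
                         svtype = "DEL", caller_id = "manta")
  expect_equal(nrow(annotate_genes(none, genes)), 0)
})

test_that("a region spanning two adjacent genes yields two rows", {
  genes <- gene_intervals(c("G1", "G2"), "1", c(100, 200), c(200, 300))
  region <- tibble::tibble(chrom = "1", start = 150, end = 250,
                           caller_id = "c", svtype = "DEL")
  rows <- annotate_genes(region, genes)
  expect_setequal(rows$gene_symbol, c("G1", "G2"))
  # abutting but non-overlapping interval: (start, end] share no base
  region2 <- tibble::tibble(chrom = "1", start = 200, end = 300,
                            caller_id = "c", svtype = "DEL")
  expect_equal(annotate_genes(region2, genes)$gene_symbol, "G2")
})

test_that("blacklisting removes genes, and regions only when fully covered", {
  rows <- tibble::tibble(
    chrom = "1", start = c(10, 10, 500), end = c(200, 200, 900),
    caller_id = "c", svtype = "DEL",
    gene_symbol = c("TTN", "ERBB3", "OR2T1"), gene_coding = TRUE
  )
  kept <- filter_gene_blacklist(rows, flags_list = "TTN",
                                olfactory_list = "OR2T1")
  expect_equal(kept$gene_symbol, "ERBB3")   # region 1 survives via ERBB3
  expect_false(any(kept$start == 500))      # region 2 fully blacklisted
  expect_identical(filter_gene_blacklist(rows), rows)  # empty lists: identity
})

test_that("severe-unique selection removes genes seen in non-severe clusters", {
  sev <- tibble::tibble(
    chrom = "1", start = c(1, 1, 100), end = c(50, 50, 200),
    caller_id = "c", svtype = "DEL",
    gene_symbol = c("SHARED", "ONLYSEV", "SHARED"), gene_coding = TRUE
  )
  ns <- tibble::tibble(gene_symbol = "SHARED")
  out <- severe_unique_genes(sev, ns)
  expect_equal(out$gene_symbol, "ONLYSEV")  # region at 100 fully excluded
  expect_identical(severe_unique_genes(sev, ns[0, ]), sev)
})

test_that("gene rows collapse back to one region with sorted gene sets", {
  rows <- tibble::tibble(
    chrom = "7", start = 100, end = 200, caller_id = "manta", svtype = "DUP",
    acmg_class = "uncertain", carrier_samples = list(c("a", "b")),
    gene_symbol = c("B", "A"), gene_coding = TRUE
  )
  out <- collapse_gene_rows(rows)
  expect_equal(nrow(out), 1)
  expect_equal(out$gene_symbols[[1]], c("A", "B"))
})
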