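make_caller_candidate <- function(caller, start, end, svtype = "DEL",
                                  chrom = "12", samples = c("I4-40", "I4-41"),
                                  genes = "ERBB3") {
  tibble::tibble(
    chrom = chrom, start = start, end = end, svtype = svtype,
    acmg_class = "uncertain", carrier_samples = list(samples),
    caller_id = caller, gene_symbols = list(genes)
  )
}

test_that("jittered breakpoints (1 bp start, 70 bp end) still reach consensus", {
  x <- dplyr::bind_rows(
    make_caller_candidate("manta", 100089053, 100112257, "DUP", chrom = "7"),
    make_caller_candidate("tiddit", 100089054, 100112327, "DUP", chrom = "7")
  )
  out <- cross_caller_consensus(x)
  expect_equal(nrow(out), 1)
  expect_setequal(out$supporting_callers[[1]], c("manta", "tiddit"))
  expect_false(out$type_discordant)
})

test_that("DEL/DUP disagreement is surfaced as a flag, never resolved away", {
  x <- dplyr::bind_rows(
    make_caller_candidate("manta", 56100028, 56100172, "DEL"),
    make_caller_candidate("tiddit", 56100028, 56100172, "DUP")
  )
  out <- cross_caller_consensus(x)
  expect_equal(nrow(out), 1)
  expect_true(out$type_discordant)
  expect_equal(out$svtype, "OTHER")  # two-way tie has no majority
  expect_setequal(names(out$caller_types[[1]]), c("manta", "tiddit"))
  # with a third concordant caller the majority label wins, flag stays
  x3 <- dplyr::bind_rows(x, make_caller_candidate("cnvkit", 56100030,
                                                  56100170, "DEL"))
  out3 <- cross_caller_consensus(x3)
  expect_equal(out3$svtype, "DEL")
  expect_true(out3$type_discordant)
})

test_that("single-caller regions are dropped by the >=2-callers rule", {
  x <- make_caller_candidate("manta", 56100028, 56100172)
  expect_equal(nrow(cross_caller_consensus(x)), 0)
  # same caller twice is still one supporting caller
  x2 <- dplyr::bind_rows(x, make_caller_candidate("manta", 56100029,
                                                  56100170))
  expect_equal(nrow(cross_caller_consensus(x2)), 0)
})

test_that("breakpoint tolerance rescues skewed-RO pairs but respects its bound", {
  # a 100 bp call inside a 400 bp call: RO = 0.25, breakpoints within 200
  x <- dplyr::bind_rows(
    make_caller_candidate("manta", 1000, 1400),
    make_caller_candidate("tiddit", 1180, 1280)
  )
  expect_equal(nrow(cross_caller_consensus(x)), 1)
  # both conditions failing: no match
  y <- dplyr::bind_rows(
    make_caller_candidate("manta", 1000, 1400),
    make_caller_candidate("tiddit", 1300, 2400)
  )
  expect_equal(nrow(cross_caller_consensus(y)), 0)
})

test_that("consensus unions carriers and genes and takes the worst ACMG class", {
  a <- make_caller_candidate("manta", 100, 600, samples = c("S1", "S2"),
                             genes = c("G1", "G2"))
  b <- make_caller_candidate("tiddit", 105, 610, samples = c("S2", "S3"),
                             genes = "G2")
  b$acmg_class <- "pathogenic"
  out <- cross_caller_consensus(dplyr::bind_rows(a, b))
  expect_setequal(out$carrier_samples[[1]], c("S1", "S2", "S3"))
  expect_setequal(out$gene_symbols[[1]], c("G1", "G2"))
  expect_equal(out$acmg_class, "pathogenic")
})

test_that("acmg_worst follows the severity ordering", {
  expect_equal(acmg_worst(c("benign", "uncertain")), "uncertain")
  expect_equal(acmg_worst(c("likely_benign", "likely_pathogenic")),
               "likely_pathogenic")
  expect_equal(acmg_worst(character(0)), "unclassified")
})
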