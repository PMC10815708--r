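test_that("reciprocal overlap matches hand arithmetic", {
  expect_equal(reciprocal_overlap(100, 200, 100, 200), 1)
  expect_equal(reciprocal_overlap(100, 200, 300, 400), 0)
  # published candidate deletion vs its population near-copy:
  # intersection 138, lengths 144 and 138
  expect_equal(reciprocal_overlap(56100028, 56100172, 56100029, 56100167),
               138 / 144)
  expect_equal(reciprocal_overlap(10, 20, 10, 20, chrom_a = "1", chrom_b = "2"),
               0)
  expect_error(reciprocal_overlap(10, 10, 10, 20), "zero")
})

test_that("reciprocal overlap is symmetric, bounded and translation-invariant", {
  set.seed(7)
  for (i in 1:200) {
    a0 <- sample.int(1000, 1); a1 <- a0 + sample.int(400, 1)
    b0 <- sample.int(1000, 1); b1 <- b0 + sample.int(400, 1)
    ro <- reciprocal_overlap(a0, a1, b0, b1)
    expect_equal(ro, reciprocal_overlap(b0, b1, a0, a1))
    expect_true(ro >= 0 && ro <= 1)
    if (ro == 1) expect_true(a0 == b0 && a1 == b1)
    d <- sample.int(500, 1)
    expect_equal(reciprocal_overlap(a0 + d, a1 + d, b0 + d, b1 + d), ro)
  }
})

test_that("identical calls in two samples form one retained cluster", {
  calls <- sv_calls(
    sample_id = c("I4-40", "I4-41"), caller_id = "manta", chrom = "12",
    start = 56100028, end = 56100172, svtype = "DEL",
    acmg_class = "uncertain"
  )
  cl <- cluster_shared(calls)
  expect_equal(nrow(cl), 1)
  expect_setequal(cl$carrier_samples[[1]], c("I4-40", "I4-41"))
  expect_equal(cl$start, 56100028)
  expect_equal(cl$svtype, "DEL")
})

test_that("private calls never survive the sharing rule", {
  calls <- sv_calls(sample_id = "I4-40", caller_id = "manta", chrom = "12",
                    start = 56100028, end = 56100172, svtype = "DEL",
                    acmg_class = "uncertain")
  expect_equal(nrow(cluster_shared(calls)), 0)
  # two overlapping calls in the SAME sample are still one carrier
  calls2 <- dplyr::bind_rows(calls, calls)
  expect_equal(nrow(cluster_shared(calls2)), 0)
})

test_that("single linkage chains sub-threshold pairs through a shared neighbor", {
  # A-B and B-C overlap 0.7, A-C only 0.4: one cluster of all three
  calls <- sv_calls(
    sample_id = c("P1", "P2", "P3"), caller_id = "manta", chrom = "1",
    start = c(0, 30, 60), end = c(100, 130, 160), svtype = "DEL",
    acmg_class = "uncertain"
  )
  cl <- cluster_shared(calls, min_ro = 0.6)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 3)
  expect_equal(cl$start, 30)    # lower median of starts
  expect_equal(cl$end, 130)
})

test_that("clustering agrees with the brute-force single-linkage oracle", {
  for (seed in 1:500) {
    calls <- random_call_instance(n_max = 12, seed = seed)
    got <- cluster_shared(calls, min_ro = 0.6, min_samples = 2)
    want <- oracle_cluster_shared(calls, min_ro = 0.6, min_samples = 2)
    expect_identical(clustering_sets(got$member_idx), clustering_sets(want),
                     info = paste("seed", seed))
  }
})

test_that("raising min_ro only refines clusters, never merges them", {
  for (seed in 1:50) {
    calls <- random_call_instance(n_max = 12, seed = seed)
    lo <- cluster_shared(calls, min_ro = 0.4, min_samples = 1)
    hi <- cluster_shared(calls, min_ro = 0.8, min_samples = 1)
    # each high-threshold cluster is contained in one low-threshold cluster
    for (h in hi$member_idx) {
      containing <- vapply(lo$member_idx, function(l) all(h %in% l),
                           logical(1))
      expect_equal(sum(containing), 1)
    }
  }
})

test_that("type-discordant calls never link within a caller", {
  calls <- sv_calls(
    sample_id = c("P1", "P2"), caller_id = "manta", chrom = "1",
    start = 100, end = 600, svtype = c("DEL", "DUP"),
    acmg_class = "uncertain"
  )
  expect_equal(nrow(cluster_shared(calls)), 0)
})

test_that("length and ACMG filters behave at their boundaries", {
  calls <- sv_calls(
    sample_id = "S1", caller_id = "c", chrom = "7",
    start = c(100056545, 0, 10), end = c(100214180, 100000, 20),
    svtype = "DUP",
    acmg_class = c("uncertain", "benign", "pathogenic")
  )
  kept <- filter_by_length(calls)
  expect_equal(sv_length(kept), c(100000, 10))   # 157635 removed, == kept
  expect_equal(nrow(filter_by_length(calls[0, ])), 0)

  expect_equal(filter_by_acmg(calls)$acmg_class,
               c("uncertain", "pathogenic"))
  expect_equal(nrow(filter_by_acmg(calls[calls$acmg_class == "benign", ])), 0)
  expect_error(filter_by_acmg(calls, keep_classes = "nope"), "unknown")
})
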