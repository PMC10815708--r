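test_that("candidates find their near-exact population counterparts", {
  cands <- candidate_sv_fixture()
  db <- population_db_fixture()
  m <- find_popdb_overlaps(cands, db)
  # every candidate has at least one same-type overlap
  expect_setequal(unique(m$candidate_idx), 1:4)
  # the three deletions receive near-exact counterparts
  del_best <- vapply(1:3, function(i) max(m$ro[m$candidate_idx == i]),
                     double(1))
  expect_true(all(del_best > 0.95))
  # matches are sorted by descending ro within candidate
  for (i in unique(m$candidate_idx)) {
    expect_false(is.unsorted(rev(m$ro[m$candidate_idx == i])))
  }
})

test_that("type and chromosome constraints exclude non-matches", {
  cand <- tibble::tibble(chrom = "1", start = 100, end = 600, svtype = "DEL")
  db <- population_sv(chrom = c("1", "2"), start = c(100, 100),
                      end = c(600, 600), svtype = c("DUP", "DEL"),
                      frequency_global = 0.001, carriers_global = 1)
  expect_equal(nrow(find_popdb_overlaps(cand, db)), 0)
  # dropping the type requirement recovers the same-chromosome record
  m <- find_popdb_overlaps(cand, db, require_same_type = FALSE)
  expect_equal(nrow(m), 1)
  expect_false(m$same_type)
})

test_that("overlap matching is symmetric and loosening never removes matches", {
  set.seed(31)
  cands <- tibble::tibble(
    chrom = sample(c("1", "2"), 15, TRUE),
    start = sample.int(5000, 15), svtype = sample(c("DEL", "DUP"), 15, TRUE)
  )
  cands$end <- cands$start + sample.int(800, 15)
  db_start <- sample.int(5000, 15)
  db <- population_sv(
    chrom = sample(c("1", "2"), 15, TRUE), start = db_start,
    end = db_start + sample.int(800, 15),
    svtype = sample(c("DEL", "DUP"), 15, TRUE),
    frequency_global = 0.001, carriers_global = 1
  )

  fwd <- find_popdb_overlaps(cands, db)
  db_as_cand <- tibble::tibble(chrom = db$chrom, start = db$start,
                               end = db$end, svtype = db$svtype)
  cand_as_db <- population_sv(chrom = cands$chrom, start = cands$start,
                              end = cands$end, svtype = cands$svtype,
                              frequency_global = 0, carriers_global = 0)
  rev <- find_popdb_overlaps(db_as_cand, cand_as_db)
  pair_key <- function(s1, e1, s2, e2) sort(paste(s1, e1, s2, e2))
  expect_identical(
    pair_key(fwd$cand_start, fwd$cand_end, fwd$db_start, fwd$db_end),
    pair_key(rev$db_start, rev$db_end, rev$cand_start, rev$cand_end)
  )

  strict <- find_popdb_overlaps(cands, db, min_overlap_bp = 50)
  expect_true(nrow(strict) <= nrow(fwd))
  loose_type <- find_popdb_overlaps(cands, db, require_same_type = FALSE)
  expect_true(nrow(loose_type) >= nrow(fwd))
})

test_that("constraint ranking prefers low LOEUF, then high pLI", {
  cons <- constraint_fixture()
  expect_equal(
    most_constrained_gene(c("ERBB3", "AP4M1", "COPS6", "MCM7", "TAF6"), cons),
    "COPS6"
  )
  expect_equal(most_constrained_gene("ERBB3", cons), "ERBB3")
  expect_true(is.na(most_constrained_gene("NOT_A_GENE", cons)))
  # pLI breaks a LOEUF tie
  tie <- constraint_table(c("G1", "G2"), loeuf = c(0.5, 0.5),
                          pli = c(0.2, 0.9))
  expect_equal(most_constrained_gene(c("G1", "G2"), tie), "G2")
})

test_that("join_constraints marks absent genes and ranks per candidate", {
  cands <- tibble::tibble(
    chrom = "7", start = 1, end = 2,
    gene_symbols = list(c("ERBB3", "MIR25"), "COPS6")
  )
  jc <- join_constraints(cands, constraint_fixture())
  expect_equal(nrow(jc$gene_scores), 3)
  expect_true(is.na(jc$gene_scores$loeuf[jc$gene_scores$gene_symbol == "MIR25"]))
  expect_equal(jc$most_constrained$gene_symbol, c("ERBB3", "COPS6"))
})
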