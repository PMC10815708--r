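mk_ds <- function(values, name = "ds", species = "human") {
  expression_dataset(name, values, species = species)
}

test_that("rescaling maps the dataset-wide maximum to exactly 100", {
  v <- matrix(c(5, 10), 1, dimnames = list("G1", c("t1", "t2")))
  out <- normalize_dataset(mk_ds(v))
  expect_equal(unname(out$values[1, ]), c(50, 100))
  single <- normalize_dataset(mk_ds(matrix(42, 1, dimnames = list("G", "t"))))
  expect_equal(unname(single$values[1, 1]), 100)
  # dataset-wide, not per gene: the second gene's max is not rescaled to 100
  v2 <- matrix(c(10, 200, 5, 100), 2,
               dimnames = list(c("G1", "G2"), c("t1", "t2")))
  out2 <- normalize_dataset(mk_ds(v2))
  expect_equal(max(out2$values), 100)
  expect_equal(out2$values["G1", "t1"], 5)
})

test_that("rescaling is idempotent and scale-invariant", {
  set.seed(9)
  v <- matrix(runif(20, 0, 37), 4,
              dimnames = list(paste0("G", 1:4), paste0("t", 1:5)))
  a <- normalize_dataset(mk_ds(v))
  expect_equal(normalize_dataset(a)$values, a$values)
  for (c in c(0.01, 3, 1e6)) {
    b <- normalize_dataset(mk_ds(v * c))
    expect_equal(b$values, a$values)
  }
})

test_that("an all-zero dataset is returned unchanged with a warning", {
  v <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("x", "y")))
  expect_warning(out <- normalize_dataset(mk_ds(v)), "all-zero")
  expect_equal(out$values, v)
})

test_that("merge takes the union of genes with explicit missing markers", {
  d1 <- mk_ds(matrix(c(1, 2), 2, dimnames = list(c("A", "B"), "t1")), "d1")
  d2 <- mk_ds(matrix(3, 1, dimnames = list("B", "t1")), "d2")
  d3 <- mk_ds(matrix(4, 1, dimnames = list("C", "t1")), "d3")
  m <- merge_by_gene(list(d1, d2, d3))
  expect_equal(rownames(m), c("A", "B", "C"))
  expect_equal(colnames(m), c("d1.t1", "d2.t1", "d3.t1"))
  expect_true(is.na(m["A", "d2.t1"]))       # absent gene: NA, not 0
  expect_equal(m["B", "d2.t1"], 3)
  # disjoint gene sets give block-missing structure, values kept exactly once
  expect_equal(sum(!is.na(m)), 4)
})

test_that("duplicate gene rows within a dataset are an error naming the gene", {
  v <- matrix(1:2, 2, dimnames = list(c("A", "A"), "t"))
  expect_error(merge_by_gene(list(mk_ds(v))), "A")
})

test_that("mouse datasets are joined through the ortholog map", {
  hum <- mk_ds(matrix(50, 1, dimnames = list("ERBB3", "cortex")), "gtex")
  mou <- mk_ds(matrix(80, 1, dimnames = list("Erbb3", "hc")), "gear",
               species = "mouse")
  map <- tibble::tibble(human_symbol = "ERBB3", mouse_symbol = "Erbb3")
  m <- merge_by_gene(list(hum, mou), ortholog_map = map)
  expect_equal(rownames(m), "ERBB3")
  expect_equal(unname(m["ERBB3", ]), c(50, 80))
  expect_error(merge_by_gene(list(hum, mou)), "ortholog_map")
})

test_that("log scaling keeps zero at zero and is strictly monotone", {
  expect_equal(log_scale(matrix(0)), matrix(0))
  expect_equal(log_scale(matrix(99))[1], 2)
  expect_equal(log_scale(matrix(100))[1], log10(101))
  expect_error(log_scale(matrix(-1)), "negative")
  x <- seq(0, 100, by = 0.5)
  expect_true(all(diff(log_scale(matrix(x))) > 0))
  expect_true(is.na(log_scale(matrix(NA_real_))[1]))
})

test_that("non-expressed genes stay at zero through the full chain", {
  fx <- expression_fixtures()
  merged <- merge_by_gene(lapply(fx[c("brain", "cochlea", "sgn")],
                                 normalize_dataset),
                          ortholog_map = fx$orthologs)
  disp <- log_scale(merged)
  for (g in c("MIR106B", "MIR25", "MIR93")) {
    expect_true(all(disp[g, ] == 0))
  }
  # ERBB3 is present and nonzero in all three datasets
  expect_true(all(disp["ERBB3", ] > 0))
  # AP4M1 is absent from the spiral ganglion dataset (0, not missing)
  expect_equal(disp["AP4M1", "sgn.sgn"], 0)
  expect_false(any(is.na(disp["AP4M1", ])))
})
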