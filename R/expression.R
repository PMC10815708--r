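# Cross-database expression summarization: heterogeneous datasets (TPM,
# RPKM, microarray intensity) are each rescaled to a common 0-100 range,
# merged by gene symbol (via an ortholog map for mouse datasets), and
# log10-scaled for display.

#' Construct an expression dataset
#'
#' @param name short dataset label (used to prefix tissue columns on merge).
#' @param values numeric matrix, genes in rownames, tissues in colnames;
#'   all values must be nonnegative.
#' @param unit free-text measurement unit (e.g. "TPM", "RPKM",
#'   "intensity"); informational only.
#' @param species "human" or "mouse"; mouse gene symbols are translated
#'   through the ortholog map at merge time.
#' @return object of class `expr_dataset`.
#' @export
expression_dataset <- function(name, values, unit = "TPM",
                               species = c("human", "mouse")) {
  species <- match.arg(species)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression_dataset: values needs gene rownames and tissue colnames")
  if (anyDuplicated(colnames(values)))
    stop("expression_dataset: duplicate tissue labels")
  if (any(values < 0, na.rm = TRUE))
    stop("expression_dataset: negative expression values")
  structure(list(name = name, unit = unit, species = species,
                 values = values),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset '%s': %d genes x %d tissues, unit=%s, %s>\n",
              x$name, nrow(x$values), ncol(x$values), x$unit, x$species))
  invisible(x)
}

#' Rescale a dataset to the 0-100 range
#'
#' Every value is divided by the dataset-wide maximum (over all genes and
#' all tissues, not per gene or per tissue) and multiplied by 100, so the
#' maximum of the rescaled dataset is exactly 100. The transform is
#' idempotent and invariant to multiplying the dataset by any positive
#' constant, which is what makes TPM, RPKM and arbitrary microarray units
#' comparable after the fact. An all-zero dataset is returned unchanged
#' with a warning (the rescaling is undefined).
#'
#' @param ds an [expression_dataset()].
#' @return the rescaled `expr_dataset`, unit tagged as "percent-of-max".
#' @export
normalize_dataset <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  m <- max(ds$values, na.rm = TRUE)
  if (!is.finite(m) || m == 0) {
    warning("normalize_dataset: all-zero dataset '", ds$name,
            "'; returned unchanged")
    return(ds)
  }
  ds$values <- 100 * ds$values / m
  ds$unit <- "percent-of-max"
  ds
}

#' Merge normalized datasets by gene symbol
#'
#' Produces the union of genes x the union of (dataset, tissue) columns
#' (named `<dataset>.<tissue>`). Genes absent from a dataset carry NA — an
#' explicit missing marker distinct from 0 expression. Mouse datasets are
#' translated to human symbols through `ortholog_map` before the join;
#' mouse genes without a mapping are dropped.
#'
#' @param datasets list of normalized [expression_dataset()] objects.
#' @param ortholog_map data frame with columns human_symbol, mouse_symbol;
#'   required when any dataset is mouse.
#' @return numeric matrix, human gene symbols in rownames.
#' @export
merge_by_gene <- function(datasets, ortholog_map = NULL) {
  stopifnot(length(datasets) >= 1)
  mats <- lapply(datasets, function(ds) {
    stopifnot(inherits(ds, "expr_dataset"))
    v <- ds$values
    if (ds$species == "mouse") {
      if (is.null(ortholog_map))
        stop("merge_by_gene: mouse dataset '", ds$name,
             "' needs an ortholog_map")
      idx <- match(rownames(v), ortholog_map$mouse_symbol)
      keep <- !is.na(idx)
      v <- v[keep, , drop = FALSE]
      rownames(v) <- ortholog_map$human_symbol[idx[keep]]
    }
    if (anyDuplicated(rownames(v)))
      stop("merge_by_gene: duplicate gene row in '", ds$name, "': ",
           rownames(v)[duplicated(rownames(v))][1])
    colnames(v) <- paste(ds$name, colnames(v), sep = ".")
    v
  })
  genes <- sort(unique(unlist(lapply(mats, rownames))))
  out <- do.call(cbind, lapply(mats, function(v) {
    full <- matrix(NA_real_, nrow = length(genes), ncol = ncol(v),
                   dimnames = list(genes, colnames(v)))
    full[rownames(v), ] <- v
    full
  }))
  out
}

#' Log-scale a merged expression matrix for display
#'
#' Applies `log10(v + 1)`: the pseudocount keeps exact zeros at 0 (a gene
#' not expressed anywhere stays visibly at the bottom of the scale) and the
#' map strictly monotone on `[0, 100]`, giving an output range of
#' `[0, log10(101)]`. Missing values stay missing.
#'
#' @param merged numeric matrix from [merge_by_gene()] (values in
#'   `[0, 100]` or NA).
#' @return matrix of the same shape.
#' @export
log_scale <- function(merged) {
  if (any(merged < 0, na.rm = TRUE))
    stop("log_scale: negative input")
  log10(merged + 1)
}

#' Write a merged expression matrix as TSV (genes in first column)
#' @param merged matrix from [merge_by_gene()] or [log_scale()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(merged, path) {
  df <- data.frame(gene = rownames(merged), merged, check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}

#' Read a gene x tissue expression TSV into an expression dataset
#'
#' First column is the gene symbol; remaining headered columns are tissues.
#'
#' @param path TSV path.
#' @inheritParams expression_dataset
#' @return an [expression_dataset()].
#' @export
read_expression_tsv <- function(path, name, unit = "TPM",
                                species = c("human", "mouse")) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- as.character(x[[1]])
  v <- as.matrix(x[, -1, drop = FALSE])
  rownames(v) <- genes
  expression_dataset(name, v, unit = unit, species = species)
}

#' Read an ortholog map TSV (columns human_symbol, mouse_symbol)
#' @param path TSV path.
#' @return tibble with human_symbol and mouse_symbol columns.
#' @export
read_ortholog_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("human_symbol", "mouse_symbol") %in% names(x)))
  x
}
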