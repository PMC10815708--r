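#!/usr/bin/env Rscript
# Cross-database expression profile of the candidate genes: rescale each
# dataset to 0-100 by its own maximum, merge by gene symbol through the
# human-mouse ortholog map, log10(x + 1)-scale for display, and write the
# display matrix (plus a heatmap when pheatmap is available).

library(svprior)

fx <- expression_fixtures()
norm <- lapply(fx[c("brain", "cochlea", "sgn")], normalize_dataset)
merged <- merge_by_gene(norm, ortholog_map = fx$orthologs)
disp <- log_scale(merged)

dir.create("results", showWarnings = FALSE)
write_expression_matrix(disp, "results/expression_matrix.tsv")

cat("display matrix:", nrow(disp), "genes x", ncol(disp), "columns\n")
cat("range:", round(range(disp, na.rm = TRUE), 3), "\n")
cat("genes with zero expression everywhere:",
    paste(rownames(disp)[apply(disp, 1, function(x) all(x == 0))],
          collapse = ", "), "\n")

if (requireNamespace("pheatmap", quietly = TRUE)) {
  grDevices::png("results/expression_heatmap.png", width = 1400,
                 height = 700, res = 130)
  pheatmap::pheatmap(disp, cluster_cols = FALSE, cluster_rows = FALSE,
                     main = "Candidate-gene expression (log10 of 0-100 scale)")
  grDevices::dev.off()
  cat("wrote results/expression_heatmap.png\n")
}
cat("wrote results/expression_matrix.tsv\n")
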