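#!/usr/bin/env Rscript
# Annotate the published candidate SVs against the population-database
# fixture (the gnomAD-style records overlapping them) and rank the
# candidate genes by constraint. Writes the match table and the
# constraint ranking under results/.

library(svprior)
library(dplyr)

cands <- candidate_sv_fixture()
db <- population_db_fixture()
cons <- constraint_fixture()

m <- find_popdb_overlaps(cands, db)
readr::write_tsv(m, "results/popdb_matches.tsv")

cat("population matches per candidate:\n")
print(m %>% count(candidate_idx))
cat("\nbest reciprocal overlap per deletion candidate:\n")
print(m %>% filter(cand_svtype == "DEL") %>% group_by(candidate_idx) %>%
        summarise(best_ro = max(ro)))

genes <- c("ERBB3", "AP4M1", "COPS6", "MCM7", "TAF6")
ranked <- cons %>% arrange(loeuf, desc(pli))
readr::write_tsv(ranked, "results/constraint_ranking.tsv")
cat("\nconstraint ranking (low LOEUF = most constrained):\n")
print(ranked)
cat("\nmost constrained candidate gene:",
    most_constrained_gene(genes, cons), "\n")
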