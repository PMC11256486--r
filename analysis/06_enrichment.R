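#!/usr/bin/env Rscript
# Step 6: peptide-level functional enrichment.  Regulated peptides (p <=
# 0.01 and |FC| >= FCT) are mapped to protein-group accessions and tested
# for term over-representation against the non-regulated background with
# two-sided Fisher exact tests; BH-adjusted p < 0.3 with at least two
# matched identifiers counts as significant.

library(sciserum)

peptides <- read_feature_matrix("results/preprocess/peptides_processed.tsv")
de <- read.delim("results/diffexp/peptide_de.tsv")
annotations <- read_gmt("results/sim/annotations.gmt")
cfg <- run_config()

reg_rows <- de$class == "significant_and_fc"
to_acc <- function(rows) {
  unique(unlist(peptides$feature_to_group[de$feature[rows]]))
}
regulated <- to_acc(reg_rows)
background <- setdiff(to_acc(!reg_rows), regulated)
cat(sprintf("%d regulated vs %d background identifiers\n",
            length(regulated), length(background)))

enr <- fisher_enrich(regulated, background, annotations,
                     min_matches = cfg$enrichment_min_matches,
                     adjp_threshold = cfg$enrichment_adjp)
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
write.table(enr, "results/enrichment/enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d terms tested, %d significant (adj p < %.1f); top terms:\n",
            nrow(enr), sum(enr$significant), cfg$enrichment_adjp))
print(head(enr[, c("term", "k", "n", "enrichment", "p", "adj_p")], 8),
      row.names = FALSE)
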