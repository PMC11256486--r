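#!/usr/bin/env Rscript
# Step 4: covariate-adjusted moderated differential abundance.  Linear
# models include recovery group, injury level, centre, sex, age and
# storage time (plus AIS grade at the protein level); empirical-Bayes
# moderated t-statistics, BH adjustment, and classification against the
# variance-adaptive fold-change threshold (log2 FCT = 1.47 x median SD;
# alpha 0.01 for peptides, 0.05 for proteins; protein FDR filter 0.1).

library(sciserum)

peptides <- read_feature_matrix("results/preprocess/peptides_processed.tsv")
proteins <- read_feature_matrix("results/preprocess/protein_matrix.tsv")
meta <- read_sample_metadata("results/sim/metadata.tsv")
cfg <- run_config()

run_level <- function(fm, level, alpha) {
  design <- make_design(meta, colnames(fm$values), level)
  fit <- moderate_fits(fit_feature_models(fm, design))
  thr <- compute_fct(fm, cfg$fct_multiplier)
  de <- classify_features(fit, thr, alpha, cfg$protein_fdr)
  cat(sprintf(
    "%s level: median SD %.4f -> FCT %.1f; %d pass p<=%.2g & FC (%d NR / %d SR), %d also FDR<=%.1f\n",
    level, thr$median_sd, thr$fct_rounded,
    as.integer(de$counts["significant_and_fc"]), alpha,
    as.integer(de$counts["enriched_NR"]),
    as.integer(de$counts["enriched_SR"]),
    as.integer(de$counts["fdr_pass"]), cfg$protein_fdr))
  list(de = de, thr = thr, fit = fit)
}

pep <- run_level(peptides, "peptide", cfg$peptide_alpha)
prot <- run_level(proteins, "protein", cfg$protein_alpha)

dir.create("results/diffexp", showWarnings = FALSE, recursive = TRUE)
write.table(pep$de$table, "results/diffexp/peptide_de.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(prot$de$table, "results/diffexp/protein_de.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# top FDR-passing proteins, reported like a results table: gene, logFC,
# per-direction fold, p, FDR
tab <- prot$de$table
top <- tab[tab$fdr_pass, c("feature", "logFC", "fold", "direction", "p",
                           "adj_p")]
top <- top[order(top$adj_p), ]
write.table(top, "results/diffexp/protein_de_fdr10.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("top of the FDR<=0.1 protein table:\n")
print(head(top, 10), row.names = FALSE)
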