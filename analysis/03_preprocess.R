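#!/usr/bin/env Rscript
# Step 3: preprocessing.  Removes peptides missing in more than 36% of
# either recovery group, imputes the remainder by iterative PCA, quantile-
# normalizes, removes TMT-plex and centre batch effects (protecting the
# group contrast), drops shared-group peptides, and rolls unique-group
# peptides up to proteins by 20% trimmed means.

library(sciserum)

peptides <- read_feature_matrix("results/assembly/peptide_matrix.tsv")
meta <- read_sample_metadata("results/sim/metadata.tsv")
cfg <- run_config()

kept <- filter_missing(peptides, meta, cfg$missing_fraction_threshold)
cat("missingness filter removed", attr(kept, "removed"), "peptides\n")
imputed <- impute_ipca(kept, cfg$ipca_components)
normalized <- quantile_normalize(imputed)
corrected <- remove_batch(normalized, meta)
unique_pep <- filter_unique_groups(corrected)
cat("unique-group filter removed", attr(unique_pep, "removed"),
    "shared peptides\n")
proteins <- rollup_proteins(unique_pep, cfg$trim_fraction)

dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)
write_feature_matrix(unique_pep, "results/preprocess/peptides_processed.tsv")
write_feature_matrix(proteins, "results/preprocess/protein_matrix.tsv")
cat(sprintf("final matrices: %d peptides, %d proteins x %d samples\n",
            nrow(unique_pep$values), nrow(proteins$values),
            ncol(proteins$values)))
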