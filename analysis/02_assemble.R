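#!/usr/bin/env Rscript
# Step 2: PSM-to-peptide assembly.  Filters PSMs (accession present,
# non-redundant, isolation interference <= 45%), applies the (identity, in
# the absence of a lot certificate) isotope impurity correction, median-
# scales reporter channels within each plex, forms log2 ratios to the
# pooled reference, and rolls PSMs up to a peptide matrix by medians.

library(sciserum)

psm <- read_psm_table("results/sim/psm.tsv", psm_dialect("canonical"))
meta <- read_sample_metadata("results/sim/metadata.tsv")
cfg <- run_config()

filtered <- filter_psms(psm, cfg$interference_threshold)
cat("PSM filter removed:",
    paste(names(attr(filtered, "removed")), attr(filtered, "removed"),
          collapse = ", "), "\n")
scaled <- median_scale(correct_impurities(filtered))
ratios <- compute_ratios(scaled, meta)
peptides <- rollup_peptides(ratios)

dir.create("results/assembly", showWarnings = FALSE, recursive = TRUE)
write_feature_matrix(peptides, "results/assembly/peptide_matrix.tsv")
cat(sprintf("peptide matrix: %d peptides x %d samples (%.1f%% missing)\n",
            nrow(peptides$values), ncol(peptides$values),
            100 * mean(is.na(peptides$values))))
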