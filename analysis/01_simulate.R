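#!/usr/bin/env Rscript
# Step 1: generate the synthetic TMT study that stands in for the (not
# publicly deposited) patient cohort: 20 NR + 10 SR patients in three TMT
# 11-plexes, each with a pooled reference channel; 34% of proteins carry a
# true +/-0.68 log2 NR-vs-SR effect; protein variability calibrated to a
# median SD of 0.4375.

library(sciserum)

out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

design <- study_design(rng_seed = 20240717L)
study <- generate_study(design)
annotations <- generate_annotations(study$truth, n_terms = 50,
                                    enriched_terms = 5,
                                    rng_seed = design$rng_seed)

write_psm_table(study$psm, file.path(out_dir, "psm.tsv"))
write_sample_metadata(study$meta, file.path(out_dir, "metadata.tsv"))
write.table(data.frame(protein = names(study$truth$protein_effects),
                       true_log2fc = unname(study$truth$protein_effects),
                       affected = names(study$truth$protein_effects) %in%
                         study$truth$affected),
            file.path(out_dir, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gmt(annotations, file.path(out_dir, "annotations.gmt"))

cat(sprintf("simulated %d PSMs over %d peptides, %d proteins (%d affected)\n",
            nrow(study$psm), length(unique(study$psm$peptide_sequence)),
            design$n_proteins, length(study$truth$affected)))
cat(sprintf("metadata: %d experimental samples + %d reference pools\n",
            sum(study$meta$role == "experimental"),
            sum(study$meta$role == "reference_pool")))
cat("wrote", out_dir, "\n")
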