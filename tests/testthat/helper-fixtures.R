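# Shared fixtures: a reduced synthetic design (fewer proteins/peptides than
# the full study, same 20 NR / 10 SR / 3-plex layout) and deterministic toy
# metadata for matrix-level unit tests.

small_design <- function(seed = 1, n_proteins = 120, ...) {
  study_design(n_proteins = n_proteins, peptides_per_protein = c(1, 8),
               psms_per_peptide = c(1, 3), rng_seed = seed, ...)
}

# Deterministic metadata: n experimental samples split NR/SR, round-robin
# plex and centre crossed with group, one 131C reference pool per plex.
toy_meta <- function(n_nr = 4, n_sr = 4, n_plexes = 1) {
  n <- n_nr + n_sr
  stopifnot(n <= n_plexes * 10)
  group <- c(rep("NR", n_nr), rep("SR", n_sr))
  plex <- paste0("plex", rep_len(seq_len(n_plexes), n))
  chans <- setdiff(TMT11_CHANNELS, "131C")
  channel <- ave(seq_len(n), plex, FUN = seq_along)
  exper <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    plex_id = plex, channel = chans[channel], role = "experimental",
    group = group,
    centre = rep_len(c("Murnau", "Toledo"), n),
    sex = rep_len(c("female", "male", "male", "female"), n),
    age = seq(20, 70, length.out = n),
    injury_level = rep_len(c("tetraplegia", "paraplegia"), n),
    ais_grade = rep_len(c("A", "A", "B"), n),
    storage_days = seq(100, 900, length.out = n),
    stringsAsFactors = FALSE)
  refs <- data.frame(
    sample_id = paste0("REF_plex", seq_len(n_plexes)),
    plex_id = paste0("plex", seq_len(n_plexes)), channel = "131C",
    role = "reference_pool", group = NA, centre = NA, sex = NA, age = NA,
    injury_level = NA, ais_grade = NA, storage_days = NA,
    stringsAsFactors = FALSE)
  validate_sample_metadata(rbind(exper, refs))
}

# Minimal PSM table with given intensities (list of length-11 vectors or a
# matrix), one plex by default.
toy_psm <- function(intensities, peptide = NULL, protein = NULL,
                    plex = "plex1", interference = 0, rank = 1L) {
  if (is.list(intensities)) intensities <- do.call(rbind, intensities)
  n <- nrow(intensities)
  colnames(intensities) <- intensity_columns()
  if (is.null(peptide)) peptide <- sprintf("PEPTIDE%02dK", seq_len(n))
  if (is.null(protein)) protein <- sprintf("P%04d", seq_len(n))
  validate_psm_table(cbind(
    data.frame(plex_id = rep_len(plex, n),
               peptide_sequence = peptide,
               protein_group = protein,
               isolation_interference = rep_len(interference, n),
               confidence_rank = rep_len(rank, n),
               stringsAsFactors = FALSE),
    as.data.frame(intensities)))
}
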