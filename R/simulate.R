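## Synthetic TMT study generator.  Emulates the statistical structure the
## pipeline assumes: 30 patients (20 NR / 10 SR) across three TMT 11-plexes,
## each with ten experimental channels plus one pooled-reference channel;
## additive-on-log2 protein/peptide/sample effects; plex and centre batch
## offsets; intensity-dependent (MNAR) missingness over an MCAR floor; a
## configurable fraction of proteins with a true NR-vs-SR effect.

#' Describe a synthetic TMT study design
#'
#' Defaults mirror the study being emulated: 20 NR and 10 SR patients in 3
#' plexes of 11 channels, a true log2 effect of 0.68 on 34% of proteins
#' (the complement of the study's estimated null proportion pi0 = 0.66),
#' and a median per-protein SD calibrated to 0.4375.  Demographics are
#' drawn to match the cohort's marginals (sex, injury level, AIS grade per
#' group).
#'
#' @param n_nr,n_sr patients with no / strong recovery (20 / 10).
#' @param n_plexes number of TMT 11-plexes (3).
#' @param channels_per_plex reporter channels per plex (11).
#' @param n_proteins simulated proteins (default 300; the emulated study
#'   quantified 2,649 -- smaller catalogues scale the counts, not the
#'   structure).
#' @param peptides_per_protein integer range, uniform (default 1--20).
#' @param psms_per_peptide integer range per peptide and plex (default
#'   1--5).
#' @param frac_affected fraction of proteins with a true group effect
#'   (default 0.34).
#' @param effect_size_log2 absolute NR-vs-SR log2 effect on affected
#'   proteins, random sign (default 0.68).
#' @param protein_sd_target calibration target for the median per-protein
#'   SD of the final protein matrix (default 0.4375).
#' @param plex_effect_sd,centre_effect_sd SDs of the additive log2 batch
#'   offsets (defaults 0.30 / 0.15).
#' @param missing_mcar completely-at-random missingness floor (default
#'   0.02).
#' @param missing_mnar_slope slope of the logistic intensity-dependent
#'   missingness (default 1; 0 disables MNAR).
#' @param frac_shared_peptides fraction of peptides assigned to a second
#'   protein group (default 0.08).
#' @param frac_unannotated fraction of PSMs lacking an accession (default
#'   0.02).
#' @param frac_redundant fraction of extra rank-2 PSMs (default 0.03).
#' @param rng_seed integer seed.
#' @return a `study_design` list.
#' @export
study_design <- function(n_nr = 20, n_sr = 10, n_plexes = 3,
                         channels_per_plex = 11, n_proteins = 300,
                         peptides_per_protein = c(1, 20),
                         psms_per_peptide = c(1, 5),
                         frac_affected = 0.34, effect_size_log2 = 0.68,
                         protein_sd_target = 0.4375,
                         plex_effect_sd = 0.30, centre_effect_sd = 0.15,
                         missing_mcar = 0.02, missing_mnar_slope = 1,
                         frac_shared_peptides = 0.08,
                         frac_unannotated = 0.02, frac_redundant = 0.03,
                         rng_seed = 1L) {
  design <- as.list(environment())
  fr <- c(frac_affected, missing_mcar, frac_shared_peptides,
          frac_unannotated, frac_redundant)
  stopifnot(all(fr >= 0), all(fr <= 1), effect_size_log2 >= 0,
            protein_sd_target > 0, n_proteins >= 1,
            channels_per_plex == length(TMT11_CHANNELS))
  if (n_nr + n_sr > n_plexes * (channels_per_plex - 1))
    stop("infeasible design: ", n_nr + n_sr, " samples exceed ",
         n_plexes * (channels_per_plex - 1), " experimental channels",
         call. = FALSE)
  structure(design, class = "study_design")
}

## Fixed secondary noise scales (log2): peptide ionization spread, per-cell
## peptide and PSM noise, reference-pool re-measurement noise, baseline
## spread.  The protein-level cell noise is derived from protein_sd_target
## by subtracting the expected contribution of peptide/PSM/reference noise
## after roll-up over a typical ~10-peptide protein.
sim_scales <- function(design) {
  list(baseline_mean = 17, baseline_sd = 1.2, peptide_offset_sd = 1.0,
       peptide_cell_sd = 0.25, psm_sd = 0.15, ref_sd = 0.10,
       protein_cell_sd = sqrt(max(design$protein_sd_target^2 - 0.008, 1e-4)))
}

#' Generate a synthetic TMT study
#'
#' Draws patient metadata, assigns samples to plexes and channels (the
#' pooled reference occupies channel 131C of every plex), simulates latent
#' log2 intensities as protein baseline + peptide offset + group effect +
#' plex offset + centre offset + protein- and peptide-level noise, emits
#' PSM-level reporter intensities (2^latent, with PSM noise), sets the
#' reference channel to the all-sample mean signal times a noise factor,
#' and applies missingness that rises as latent intensity falls (logistic
#' MNAR) over an MCAR floor.  A small fraction of PSMs is unannotated or
#' redundant and some isolation-interference values exceed 45%, so the
#' assembly filters have work to do.
#'
#' @param design a [study_design()].
#' @return list with `psm` (PSM table), `meta` (sample metadata) and
#'   `truth` (ground truth: per-protein signed effects, affected protein
#'   ids, per-sample batch offsets, the design).
#' @export
generate_study <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$rng_seed)
  sc <- sim_scales(design)
  meta <- simulate_metadata(design)
  exper <- meta[meta$role == "experimental", ]
  ns <- nrow(exper)

  ## ground truth
  prot_ids <- sprintf("P%04d", seq_len(design$n_proteins))
  n_aff <- round(design$frac_affected * design$n_proteins)
  affected <- sort(sample(prot_ids, n_aff))
  effects <- setNames(rep(0, design$n_proteins), prot_ids)
  if (n_aff > 0)
    effects[affected] <- design$effect_size_log2 *
      sample(c(-1, 1), n_aff, replace = TRUE)
  plex_off <- setNames(rnorm(design$n_plexes, 0, design$plex_effect_sd),
                       unique(exper$plex_id))
  centres <- unique(exper$centre)
  centre_off <- setNames(rnorm(length(centres), 0, design$centre_effect_sd),
                         centres)
  sample_off <- plex_off[exper$plex_id] + centre_off[exper$centre]

  ## peptide catalogue
  npep <- sample(design$peptides_per_protein[1]:design$peptides_per_protein[2],
                 design$n_proteins, replace = TRUE)
  pep_protein <- rep(prot_ids, npep)
  n_pep <- length(pep_protein)
  pep_seq <- random_peptides(n_pep)
  pep_groups <- pep_protein
  shared <- runif(n_pep) < design$frac_shared_peptides
  if (any(shared) && design$n_proteins > 1) {
    other <- vapply(pep_protein[shared], function(p) {
      sample(setdiff(prot_ids, p), 1)
    }, "")
    pep_groups[shared] <- paste(pep_protein[shared], other, sep = ";")
  }

  baseline <- setNames(rnorm(design$n_proteins, sc$baseline_mean,
                             sc$baseline_sd), prot_ids)
  pep_offset <- rnorm(n_pep, 0, sc$peptide_offset_sd)

  ## latent log2 intensity per peptide x experimental sample
  grp_sign <- ifelse(exper$group == "NR", +0.5, -0.5)
  eff_term <- outer(effects[pep_protein], grp_sign)       # pep x sample
  prot_noise <- matrix(rnorm(design$n_proteins * ns, 0, sc$protein_cell_sd),
                       design$n_proteins, ns)
  latent <- baseline[pep_protein] + pep_offset +
    eff_term + prot_noise[match(pep_protein, prot_ids), ] +
    matrix(rnorm(n_pep * ns, 0, sc$peptide_cell_sd), n_pep, ns) +
    matrix(sample_off, n_pep, ns, byrow = TRUE)

  ## reference pool: all-sample mean signal (linear scale) plus noise,
  ## re-measured in every plex
  ref_base <- log2(rowMeans(2^latent))
  plexes <- unique(exper$plex_id)
  ref_latent <- matrix(ref_base, n_pep, design$n_plexes) +
    matrix(rnorm(n_pep * design$n_plexes, 0, sc$ref_sd),
           n_pep, design$n_plexes)
  colnames(ref_latent) <- plexes

  ## PSM rows: per peptide and plex
  nps <- matrix(sample(design$psms_per_peptide[1]:design$psms_per_peptide[2],
                       n_pep * design$n_plexes, replace = TRUE),
                n_pep, design$n_plexes)
  mnar_threshold <- quantile(latent, 0.05)
  rows <- vector("list", design$n_plexes)
  for (pi in seq_len(design$n_plexes)) {
    plex <- plexes[pi]
    inplex <- which(exper$plex_id == plex)
    reps <- rep(seq_len(n_pep), nps[, pi])
    nrow_p <- length(reps)
    inten <- matrix(NA_real_, nrow_p, length(TMT11_CHANNELS),
                    dimnames = list(NULL, intensity_columns()))
    ref_ch <- meta$channel[meta$plex_id == plex & meta$role == "reference_pool"]
    for (j in seq_along(inplex)) {
      ch <- exper$channel[inplex[j]]
      lat <- latent[reps, inplex[j]] + rnorm(nrow_p, 0, sc$psm_sd)
      inten[, paste0("intensity_", ch)] <- 2^lat
      miss <- missing_prob(lat, mnar_threshold, design)
      inten[runif(nrow_p) < miss, paste0("intensity_", ch)] <- NA
    }
    lat_ref <- ref_latent[reps, plex] + rnorm(nrow_p, 0, sc$psm_sd)
    inten[, paste0("intensity_", ref_ch)] <- 2^lat_ref
    miss_ref <- missing_prob(lat_ref, mnar_threshold, design)
    inten[runif(nrow_p) < miss_ref, paste0("intensity_", ref_ch)] <- NA
    df <- data.frame(plex_id = plex,
                     peptide_sequence = pep_seq[reps],
                     protein_group = pep_groups[reps],
                     isolation_interference =
                       pmin(100, 100 * stats::rbeta(nrow_p, 1.3, 4)),
                     confidence_rank = 1L,
                     stringsAsFactors = FALSE)
    rows[[pi]] <- cbind(df, as.data.frame(inten))
  }
  psm <- do.call(rbind, rows)

  ## imperfections: unannotated and redundant PSMs
  n_psm <- nrow(psm)
  psm$protein_group[runif(n_psm) < design$frac_unannotated] <- ""
  n_red <- round(design$frac_redundant * n_psm)
  if (n_red > 0) {
    dup <- psm[sample(n_psm, n_red), ]
    dup$confidence_rank <- 2L
    psm <- rbind(psm, dup)
  }
  rownames(psm) <- NULL

  truth <- list(protein_effects = effects, affected = affected,
                sample_offsets = data.frame(sample_id = exper$sample_id,
                                            plex_offset = unname(plex_off[exper$plex_id]),
                                            centre_offset = unname(centre_off[exper$centre]),
                                            stringsAsFactors = FALSE),
                design = design)
  list(psm = validate_psm_table(psm), meta = meta, truth = truth)
}

missing_prob <- function(latent, threshold, design) {
  pmin(1, design$missing_mcar +
         (1 - design$missing_mcar) *
         plogis(design$missing_mnar_slope * (threshold - latent)))
}

random_peptides <- function(n) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]   # K/R reserved for the ends
  repeat {
    seqs <- vapply(sample(8:20, n, replace = TRUE), function(len) {
      paste(c(sample(aa, len - 1, replace = TRUE),
              sample(c("K", "R"), 1)), collapse = "")
    }, "")
    if (!anyDuplicated(seqs)) return(seqs)
  }
}

simulate_metadata <- function(design) {
  n <- design$n_nr + design$n_sr
  group <- c(rep("NR", design$n_nr), rep("SR", design$n_sr))
  ## cohort-like marginals per group (NR: 15M/5F, 12 tetra/8 para, 16 A/4 B;
  ## SR: 6M/4F, 6 tetra/4 para, 2 A/8 B), scaled for non-default sizes
  draw <- function(ng, k_ref, n_ref, levels) {
    k <- round(ng * k_ref / n_ref)
    sample(c(rep(levels[1], k), rep(levels[2], ng - k)))
  }
  sex <- c(draw(design$n_nr, 15, 20, c("male", "female")),
           draw(design$n_sr, 6, 10, c("male", "female")))
  injury <- c(draw(design$n_nr, 12, 20, c("tetraplegia", "paraplegia")),
              draw(design$n_sr, 6, 10, c("tetraplegia", "paraplegia")))
  ais <- c(draw(design$n_nr, 16, 20, c("A", "B")),
           draw(design$n_sr, 2, 10, c("A", "B")))
  centre <- c(draw(design$n_nr, 10, 20, c("Murnau", "Toledo")),
              draw(design$n_sr, 5, 10, c("Murnau", "Toledo")))
  age <- round(runif(n, 18, 79))
  storage <- round(runif(n, 200, 1200))
  ids <- sprintf("S%02d", seq_len(n))
  exper <- data.frame(sample_id = ids, group = group, centre = centre,
                      sex = sex, age = age, injury_level = injury,
                      ais_grade = ais, storage_days = storage,
                      stringsAsFactors = FALSE)
  ## round-robin plex assignment within each group keeps plex and group
  ## crossed (batch correction stays identifiable)
  plex_of <- integer(n)
  plex_of[sample(which(group == "NR"))] <-
    rep_len(seq_len(design$n_plexes), design$n_nr)
  plex_of[sample(which(group == "SR"))] <-
    rep_len(rev(seq_len(design$n_plexes)), design$n_sr)
  cap <- design$channels_per_plex - 1
  if (any(tabulate(plex_of, design$n_plexes) > cap)) {
    over <- which(tabulate(plex_of, design$n_plexes) > cap)
    for (p in over) {
      spare <- which(tabulate(plex_of, design$n_plexes) < cap)
      moving <- which(plex_of == p)[seq_len(sum(plex_of == p) - cap)]
      plex_of[moving] <- rep_len(spare, length(moving))
    }
  }
  exper$plex_id <- paste0("plex", plex_of)
  chans <- setdiff(TMT11_CHANNELS, "131C")
  exper$channel <- NA_character_
  for (p in seq_len(design$n_plexes)) {
    i <- which(plex_of == p)
    exper$channel[i] <- chans[seq_along(i)]
  }
  exper$role <- "experimental"
  refs <- data.frame(sample_id = paste0("REF_plex", seq_len(design$n_plexes)),
                     group = NA_character_, centre = NA_character_,
                     sex = NA_character_, age = NA_real_,
                     injury_level = NA_character_, ais_grade = NA_character_,
                     storage_days = NA_real_,
                     plex_id = paste0("plex", seq_len(design$n_plexes)),
                     channel = "131C", role = "reference_pool",
                     stringsAsFactors = FALSE)
  meta <- rbind(exper, refs)
  cols <- c("sample_id", "plex_id", "channel", "role", "group", "centre",
            "sex", "age", "injury_level", "ais_grade", "storage_days")
  meta <- meta[, cols]
  rownames(meta) <- NULL
  validate_sample_metadata(meta)
}

#' Generate synthetic term annotations
#'
#' Builds a term -> protein-set map in which `enriched_terms` terms draw
#' most of their members from the truly affected proteins (so downstream
#' enrichment has planted positives) and the remainder draw uniformly.
#'
#' @param truth ground truth from [generate_study()].
#' @param n_terms total number of terms (>= `enriched_terms`).
#' @param enriched_terms number of terms planted on affected proteins.
#' @param term_size integer range of term sizes (default 10--40).
#' @param affected_frac fraction of an enriched term's members drawn from
#'   affected proteins (default 0.8).
#' @param rng_seed integer seed.
#' @return named list term -> protein ids; planted term names start with
#'   `"ENR"`.
#' @export
generate_annotations <- function(truth, n_terms = 50, enriched_terms = 5,
                                 term_size = c(10, 40), affected_frac = 0.8,
                                 rng_seed = 1L) {
  stopifnot(n_terms >= enriched_terms, enriched_terms >= 0)
  set.seed(rng_seed)
  proteins <- names(truth$protein_effects)
  affected <- truth$affected
  unaffected <- setdiff(proteins, affected)
  sizes <- sample(term_size[1]:min(term_size[2], length(proteins)),
                  n_terms, replace = TRUE)
  sizes <- pmax(sizes, 1L)
  terms <- lapply(seq_len(n_terms), function(i) {
    if (i <= enriched_terms && length(affected)) {
      k_aff <- min(round(affected_frac * sizes[i]), length(affected))
      c(sample(affected, k_aff),
        sample(unaffected, min(sizes[i] - k_aff, length(unaffected))))
    } else {
      sample(proteins, sizes[i])
    }
  })
  names(terms) <- c(sprintf("ENR%03d", seq_len(enriched_terms)),
                    sprintf("TERM%03d", seq_len(n_terms - enriched_terms)))
  terms
}

#' Generate a synthetic ELISA plate
#'
#' Standards follow a serial dilution of a known 5PL truth curve, blanks
#' sit at the curve's zero-concentration asymptote, and every sample is
#' measured in duplicate at its diluted concentration.  OD noise is
#' multiplicative with the given CV (cv = 0 gives identical replicates).
#'
#' @param curve_params named list/vector of 5PL truth parameters
#'   `a, d, c, b, g` (see [fivepl()]).
#' @param n_standards number of standard concentrations (serial
#'   `dilution_step`-fold from `top_conc`); each standard is run in
#'   duplicate.
#' @param n_blanks number of blank wells.
#' @param sample_concs named numeric vector of neat sample concentrations.
#' @param dilutions dilution factor per sample, recycled (default 1).
#' @param groups optional group label per sample, recycled.
#' @param cv multiplicative OD noise coefficient of variation (default
#'   0.085).
#' @param top_conc highest standard concentration.
#' @param dilution_step fold step between standards (default 2, strictly
#'   decreasing series).
#' @param analyte analyte name stamped on the wells.
#' @param rng_seed integer seed.
#' @return ELISA plate data.frame: `well_id`, `role`
#'   (standard/blank/sample), `analyte`, `nominal_conc`, `od`,
#'   `replicate_id`, `dilution_factor`, `group`, `sample_id`.
#' @export
generate_elisa_plate <- function(curve_params = list(a = 0.05, d = 3.2,
                                                     c = 250, b = 1.2,
                                                     g = 1),
                                 n_standards = 7, n_blanks = 3,
                                 sample_concs, dilutions = 1, groups = NA,
                                 cv = 0.085, top_conc = 4000,
                                 dilution_step = 2, analyte = "analyte",
                                 rng_seed = 1L) {
  stopifnot(cv >= 0, dilution_step > 1, n_standards >= 2)
  set.seed(rng_seed)
  p <- as.list(curve_params)
  noisy <- function(od_true) {
    pmax(od_true * (1 + rnorm(length(od_true), 0, cv)), 0)
  }
  std_conc <- top_conc / dilution_step^(seq_len(n_standards) - 1)
  std <- data.frame(role = "standard",
                    nominal_conc = rep(std_conc, each = 2),
                    replicate_id = rep(1:2, n_standards),
                    dilution_factor = 1, group = NA_character_,
                    sample_id = rep(sprintf("STD%d", seq_len(n_standards)),
                                    each = 2),
                    stringsAsFactors = FALSE)
  std$od <- noisy(fivepl(std$nominal_conc, p$a, p$d, p$c, p$b, p$g))
  blank <- data.frame(role = "blank", nominal_conc = 0,
                      replicate_id = seq_len(n_blanks), dilution_factor = 1,
                      group = NA_character_,
                      sample_id = sprintf("BLANK%d", seq_len(n_blanks)),
                      stringsAsFactors = FALSE)
  blank$od <- noisy(rep(p$a, n_blanks))
  ns <- length(sample_concs)
  dilutions <- rep_len(dilutions, ns)
  groups <- rep_len(groups, ns)
  ids <- if (is.null(names(sample_concs)) || !all(nzchar(names(sample_concs))))
    sprintf("SAMPLE%02d", seq_len(ns)) else names(sample_concs)
  smp <- data.frame(role = "sample",
                    nominal_conc = rep(unname(sample_concs), each = 2),
                    replicate_id = rep(1:2, ns),
                    dilution_factor = rep(dilutions, each = 2),
                    group = rep(groups, each = 2),
                    sample_id = rep(ids, each = 2),
                    stringsAsFactors = FALSE)
  smp$od <- noisy(fivepl(smp$nominal_conc / smp$dilution_factor,
                         p$a, p$d, p$c, p$b, p$g))
  plate <- rbind(std, blank, smp)
  plate$analyte <- analyte
  plate$well_id <- sprintf("W%02d", seq_len(nrow(plate)))
  plate[, c("well_id", "role", "analyte", "nominal_conc", "od",
            "replicate_id", "dilution_factor", "group", "sample_id")]
}
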