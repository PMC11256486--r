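## End-to-end orchestration: PSM assembly -> preprocessing -> differential
## abundance at the peptide and protein levels -> functional enrichment.
## Stage order follows the source workflow exactly: PSM filtering, impurity
## correction, median scaling, reference ratios + log2, peptide roll-up;
## then missingness filter + imputation, quantile normalization, batch
## correction, unique-group filter, protein roll-up; then the models.

#' Run the full TMT analysis pipeline
#'
#' Executes every stage in order and collects a report of input/output
#' dimensions per stage (7 assembly entries and 5 preprocessing entries,
#' matching the workflow's own enumeration).  Deterministic given the
#' inputs and `config$rng_seed`.
#'
#' @param config a [run_config()].
#' @param psm PSM table.
#' @param meta sample metadata covering every (plex, channel) in `psm`.
#' @param annotations optional term -> protein map for enrichment.
#' @param impurity impurity matrix (default identity).
#' @return list: `peptides` (complete peptide matrix), `proteins` (protein
#'   matrix), `peptide_de` / `protein_de` (classified moderated results),
#'   `peptide_thresholds` / `protein_thresholds`, `enrichment` (or NULL),
#'   `report` (stage log data.frame).
#' @export
run_pipeline <- function(config = run_config(), psm, meta,
                         annotations = NULL,
                         impurity = identity_impurity_matrix()) {
  config <- validate_run_config(config)
  validate_sample_metadata(meta)
  set.seed(config$rng_seed)
  check_channel_coverage(psm, meta)
  stages <- list()
  log_stage <- function(name, phase, rows_in, rows_out, cols) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = name, phase = phase, rows_in = rows_in, rows_out = rows_out,
      cols = cols, stringsAsFactors = FALSE)
  }

  ## -- assembly -------------------------------------------------------
  n0 <- nrow(psm)
  annotated <- psm[nzchar(psm$protein_group) & psm$confidence_rank == 1L, ]
  log_stage("psm_annotation_filter", "assembly", n0, nrow(annotated), NA)
  filtered <- filter_psms(annotated, config$interference_threshold)
  log_stage("isolation_interference_filter", "assembly", nrow(annotated),
            nrow(filtered), NA)
  corrected <- correct_impurities(filtered, impurity)
  log_stage("impurity_correction", "assembly", nrow(filtered),
            nrow(corrected), NA)
  scaled <- median_scale(corrected)
  log_stage("median_scaling", "assembly", nrow(corrected), nrow(scaled), NA)
  ratios <- compute_ratios(scaled, meta)
  nsamp <- sum(meta$role == "experimental")
  log_stage("reference_ratios_log2", "assembly", nrow(scaled), nrow(ratios),
            nsamp)
  pep <- rollup_peptides(ratios)
  log_stage("peptide_rollup", "assembly", nrow(ratios), nrow(pep$values),
            ncol(pep$values))
  log_stage("peptide_matrix_assembly", "assembly", nrow(pep$values),
            nrow(pep$values), ncol(pep$values))

  ## -- preprocessing --------------------------------------------------
  kept <- filter_missing(pep, meta, config$missing_fraction_threshold)
  if (nrow(kept$values) == 0L)
    stop("missingness filter removed every peptide; nothing to impute",
         call. = FALSE)
  imputed <- impute_ipca(kept, n_components = config$ipca_components)
  log_stage("missingness_filter_imputation", "preprocessing",
            nrow(pep$values), nrow(imputed$values), ncol(imputed$values))
  normalized <- quantile_normalize(imputed)
  log_stage("quantile_normalization", "preprocessing",
            nrow(imputed$values), nrow(normalized$values),
            ncol(normalized$values))
  corrected_pep <- remove_batch(normalized, meta)
  log_stage("batch_correction", "preprocessing", nrow(normalized$values),
            nrow(corrected_pep$values), ncol(corrected_pep$values))
  unique_pep <- filter_unique_groups(corrected_pep)
  log_stage("unique_group_filter", "preprocessing",
            nrow(corrected_pep$values), nrow(unique_pep$values),
            ncol(unique_pep$values))
  proteins <- rollup_proteins(unique_pep, config$trim_fraction)
  log_stage("protein_rollup", "preprocessing", nrow(unique_pep$values),
            nrow(proteins$values), ncol(proteins$values))

  ## -- statistics -----------------------------------------------------
  pep_design <- make_design(meta, colnames(unique_pep$values), "peptide")
  pep_fit <- moderate_fits(fit_feature_models(unique_pep, pep_design))
  pep_thr <- compute_fct(unique_pep, config$fct_multiplier)
  pep_de <- classify_features(pep_fit, pep_thr, config$peptide_alpha,
                              config$protein_fdr)
  prot_design <- make_design(meta, colnames(proteins$values), "protein")
  prot_fit <- moderate_fits(fit_feature_models(proteins, prot_design))
  prot_thr <- compute_fct(proteins, config$fct_multiplier)
  prot_de <- classify_features(prot_fit, prot_thr, config$protein_alpha,
                               config$protein_fdr)

  ## -- enrichment -----------------------------------------------------
  enr <- NULL
  if (!is.null(annotations)) {
    reg_pep <- pep_de$table$class == "significant_and_fc"
    to_acc <- function(i) unique(unlist(unique_pep$feature_to_group[i]))
    regulated <- to_acc(which(reg_pep))
    background <- setdiff(to_acc(which(!reg_pep)), regulated)
    enr <- fisher_enrich(regulated, background, annotations,
                         min_matches = config$enrichment_min_matches,
                         adjp_threshold = config$enrichment_adjp)
  }

  list(peptides = unique_pep, proteins = proteins,
       peptide_de = pep_de, protein_de = prot_de,
       peptide_thresholds = pep_thr, protein_thresholds = prot_thr,
       peptide_fit = pep_fit, protein_fit = prot_fit,
       enrichment = enr,
       report = do.call(rbind, stages))
}

check_channel_coverage <- function(psm, meta) {
  used <- unique(psm$plex_id)
  known <- unique(meta$plex_id)
  orphan <- setdiff(used, known)
  if (length(orphan))
    stop("PSM data references plex(es) absent from metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
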