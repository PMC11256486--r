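## PSM tables, sample metadata, run configuration: core containers and
## tab-delimited readers/writers.
##
## A PSM table is a plain data.frame with one row per peptide-spectrum match:
##   plex_id, peptide_sequence, protein_group (";"-separated accessions, ""
##   when unannotated), isolation_interference (% in [0,100], NA allowed),
##   confidence_rank (1 = best), and 11 reporter intensity columns
##   intensity_126 ... intensity_131C (NA = not observed; zeros are kept as
##   zeros until the ratio step).

#' Canonical intensity column names for a PSM table
#' @param channels reporter channel labels
#' @return character vector, e.g. `"intensity_126"`
#' @export
intensity_columns <- function(channels = TMT11_CHANNELS) {
  paste0("intensity_", channels)
}

psm_scalar_columns <- c("plex_id", "peptide_sequence", "protein_group",
                        "isolation_interference", "confidence_rank")

#' Column-name dialect for PSM table files
#'
#' Maps the canonical field names used throughout the package to the headers
#' found in a given export flavour.  The `"pd"` dialect follows Proteome
#' Discoverer style multi-consensus exports; `"canonical"` uses the package's
#' own names (what [write_psm_table()] emits).  Export headers vary by
#' software version, so readers take the map as an argument rather than
#' hard-coding headers.
#'
#' @param flavour `"canonical"` or `"pd"`.
#' @return named character vector: canonical name -> file header.
#' @export
psm_dialect <- function(flavour = c("canonical", "pd")) {
  flavour <- match.arg(flavour)
  canon <- c(psm_scalar_columns, intensity_columns())
  if (flavour == "canonical") return(setNames(canon, canon))
  setNames(c("Plex", "Annotated Sequence", "Master Protein Accessions",
             "Isolation Interference in Percent", "Rank",
             paste("Abundance", TMT11_CHANNELS)),
           canon)
}

#' Read a PSM-level reporter intensity table
#'
#' Reads a tab-delimited PSM export into the canonical PSM table layout.
#' Empty intensity cells become `NA` (missing), never zero; explicit zeros
#' are preserved.  Row order is preserved.
#'
#' @param path path to a tab-delimited file.
#' @param dialect named map canonical field -> file header, see
#'   [psm_dialect()].  Headers matching the canonical names are also
#'   accepted, so files written by [write_psm_table()] read back under any
#'   dialect.
#' @return a PSM table data.frame.
#' @export
read_psm_table <- function(path, dialect = psm_dialect()) {
  stopifnot(file.exists(path))
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  canon <- c(psm_scalar_columns, intensity_columns())
  out <- vector("list", length(canon))
  names(out) <- canon
  for (field in canon) {
    header <- if (field %in% names(dialect)) dialect[[field]] else field
    col <- if (header %in% names(raw)) raw[[header]]
           else if (field %in% names(raw)) raw[[field]]
           else stop("PSM table is missing required column '", header,
                     "' (field '", field, "')", call. = FALSE)
    out[[field]] <- col
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  out$plex_id <- as.character(out$plex_id)
  out$peptide_sequence <- toupper(as.character(out$peptide_sequence))
  pg <- as.character(out$protein_group)
  pg[is.na(pg)] <- ""
  out$protein_group <- pg
  for (ic in intensity_columns()) {
    v <- out[[ic]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop("non-numeric intensity in column '", ic, "' at data row ",
             bad[1], call. = FALSE)
      v <- num
    }
    out[[ic]] <- v
  }
  out$isolation_interference <- as.numeric(out$isolation_interference)
  out$confidence_rank <- as.integer(out$confidence_rank)
  validate_psm_table(out)
}

#' Validate a PSM table's invariants
#' @param psm PSM table data.frame
#' @return `psm`, invisibly unchanged, or an error.
#' @export
validate_psm_table <- function(psm) {
  need <- c(psm_scalar_columns, intensity_columns())
  miss <- setdiff(need, names(psm))
  if (length(miss))
    stop("PSM table is missing required column '", miss[1], "'", call. = FALSE)
  ii <- psm$isolation_interference
  if (any(!is.na(ii) & (ii < 0 | ii > 100)))
    stop("isolation_interference must lie in [0,100]", call. = FALSE)
  for (ic in intensity_columns()) {
    v <- psm[[ic]]
    if (any(!is.na(v) & v < 0))
      stop("negative reporter intensity in ", ic, call. = FALSE)
  }
  psm
}

#' Write a PSM table as tab-delimited text
#' @param psm PSM table
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psm, path) {
  validate_psm_table(psm)
  write.table(psm, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read / write / validate the sample metadata table
#'
#' The metadata table declares, for every (plex, channel) used, the sample it
#' carries: columns `sample_id`, `plex_id`, `channel`, `role`
#' (`experimental` or `reference_pool`), `group` (`NR`/`SR`, experimental
#' only), `centre`, `sex`, `age`, `injury_level`, `ais_grade`,
#' `storage_days`.  The pooled reference channel is declared here rather
#' than assumed to sit at a fixed tag position.
#'
#' @param path tab-delimited file path.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  meta <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
  meta$plex_id <- as.character(meta$plex_id)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta metadata data.frame
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample_id", "plex_id", "channel", "role", "group", "centre",
            "sex", "age", "injury_level", "ais_grade", "storage_days")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sample metadata is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(meta$channel %in% TMT11_CHANNELS))
    stop("unknown reporter channel in metadata", call. = FALSE)
  if (!all(meta$role %in% c("experimental", "reference_pool")))
    stop("role must be 'experimental' or 'reference_pool'", call. = FALSE)
  exper <- meta[meta$role == "experimental", ]
  if (anyDuplicated(exper$sample_id))
    stop("duplicated sample_id in metadata", call. = FALSE)
  if (anyDuplicated(meta[, c("plex_id", "channel")]))
    stop("duplicated (plex, channel) assignment in metadata", call. = FALSE)
  nref <- tapply(meta$role == "reference_pool", meta$plex_id, sum)
  if (any(nref != 1))
    stop("each plex must declare exactly one reference_pool channel",
         call. = FALSE)
  if (!all(exper$group %in% c("NR", "SR")))
    stop("experimental samples must be labelled NR or SR", call. = FALSE)
  meta
}

#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles the tunable thresholds of the pipeline with their defaults: the
#' 45% isolation-interference cut-off, the ~36% per-group missingness
#' filter, the number of iPCA components, the trimmed-mean trim fraction,
#' the 1.47 multiplier of the variance-adaptive fold-change threshold, the
#' peptide/protein p-value cut-offs (0.01 / 0.05), the protein FDR filter
#' (0.10), and the enrichment reporting rules (adjusted p < 0.3, at least
#' two matched identifiers).
#'
#' @param ... named overrides of the defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    interference_threshold = 45,
    missing_fraction_threshold = 0.36,
    ipca_components = 2,
    trim_fraction = 0.2,
    fct_multiplier = 1.47,
    peptide_alpha = 0.01,
    protein_alpha = 0.05,
    protein_fdr = 0.10,
    enrichment_adjp = 0.30,
    enrichment_min_matches = 2,
    rng_seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  with(cfg, {
    stopifnot(interference_threshold >= 0, interference_threshold <= 100,
              missing_fraction_threshold >= 0, missing_fraction_threshold <= 1,
              ipca_components >= 1,
              trim_fraction >= 0, trim_fraction < 0.5,
              fct_multiplier > 0,
              peptide_alpha > 0, peptide_alpha < 1,
              protein_alpha > 0, protein_alpha < 1,
              protein_fdr > 0, protein_fdr < 1,
              enrichment_adjp > 0, enrichment_adjp <= 1,
              enrichment_min_matches >= 0)
  })
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname run_config
#' @param cfg a `run_config`
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
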