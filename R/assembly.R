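## PSM-to-peptide data assembly: PSM filtering, isotope impurity correction,
## per-channel median scaling, log2 ratios to the pooled reference channel,
## and median roll-up of PSMs into a peptide matrix.

#' Filter PSMs on annotation, redundancy and isolation interference
#'
#' Retains PSMs that (a) carry a protein-group accession, (b) are the rank-1
#' (non-redundant) match for their spectrum, and (c) have isolation
#' interference at or below the threshold.  PSMs with no recorded
#' interference are retained: the filter removes demonstrated co-isolation,
#' not missing QC values.  The boundary is inclusive (a PSM at exactly the
#' threshold is kept).  Removal counts per criterion are attached as the
#' `"removed"` attribute.
#'
#' @param psm PSM table.
#' @param interference_threshold maximum tolerated isolation interference,
#'   percent; default 45.
#' @return filtered PSM table.
#' @export
filter_psms <- function(psm, interference_threshold = 45) {
  stopifnot(interference_threshold >= 0, interference_threshold <= 100)
  validate_psm_table(psm)
  no_acc  <- !nzchar(psm$protein_group)
  redund  <- !no_acc & psm$confidence_rank != 1L
  interf  <- !no_acc & !redund & !is.na(psm$isolation_interference) &
             psm$isolation_interference > interference_threshold
  keep <- !(no_acc | redund | interf)
  out <- psm[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(no_accession = sum(no_acc),
                            redundant = sum(redund),
                            interference = sum(interf))
  if (nrow(out) == 0L) warning("all PSMs removed by filtering")
  out
}

#' Identity isotope impurity matrix
#'
#' Reporter lots ship with lot-specific cross-channel isotope impurities.
#' When no lot certificate is supplied the correction is the identity (a
#' no-op); user matrices are read with [read_impurity_matrix()].
#'
#' @param channels reporter channel labels.
#' @return 11 x 11 identity matrix with channel dimnames.
#' @export
identity_impurity_matrix <- function(channels = TMT11_CHANNELS) {
  m <- diag(length(channels))
  dimnames(m) <- list(observed = channels, true = channels)
  m
}

#' Read an impurity matrix from tab-delimited text
#'
#' Rows are observed channels, columns true channels; entries are fractions
#' of a channel's signal appearing in each observed channel.  Columns must
#' be non-negative and sum to at most 1 (+1e-6 slack).
#'
#' @param path file path: 11 columns with channel headers, 11 rows.
#' @return numeric 11 x 11 matrix.
#' @export
read_impurity_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  validate_impurity_matrix(m)
}

validate_impurity_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == length(TMT11_CHANNELS),
            ncol(m) == length(TMT11_CHANNELS))
  if (any(m < 0)) stop("impurity matrix entries must be >= 0", call. = FALSE)
  if (any(colSums(m) > 1 + 1e-6))
    stop("impurity matrix columns must sum to <= 1", call. = FALSE)
  m
}

#' Correct reporter intensities for isotope impurities
#'
#' Per PSM, solves `impurity %*% x = observed` for the true channel signals
#' `x`; negative solution components are clamped to zero.  Missing channels
#' are excluded from the solve by deleting the corresponding rows and
#' columns, and stay missing in the output.
#'
#' @param psm PSM table.
#' @param impurity 11 x 11 impurity matrix (observed x true), see
#'   [read_impurity_matrix()].
#' @return PSM table with corrected intensities.
#' @export
correct_impurities <- function(psm, impurity = identity_impurity_matrix()) {
  validate_impurity_matrix(impurity)
  if (abs(det(impurity)) < 1e-12)
    stop("impurity matrix is singular", call. = FALSE)
  cols <- intensity_columns()
  x <- as.matrix(psm[, cols, drop = FALSE])
  obs <- !is.na(x)
  complete <- rowSums(obs) == length(cols)
  if (any(complete))
    x[complete, ] <- t(pmax(solve(impurity, t(x[complete, , drop = FALSE])), 0))
  partial <- which(!complete & rowSums(obs) > 0L)
  for (i in partial) {
    idx <- which(obs[i, ])
    sub <- impurity[idx, idx, drop = FALSE]
    if (abs(det(sub)) < 1e-12)
      stop("impurity submatrix singular after removing missing channels",
           call. = FALSE)
    x[i, idx] <- pmax(solve(sub, x[i, idx]), 0)
  }
  psm[, cols] <- x
  psm
}

#' Median-scale reporter channels within each plex
#'
#' Within each plex, every channel's intensities are multiplied by
#' (grand median of the channel medians in that plex) / (that channel's
#' median), so that afterwards all channel medians within a plex are equal.
#' Scaling within plex (rather than across the experiment) is the natural
#' choice here because ratios to the reference pool are subsequently taken
#' within plex.  Channels whose intensities are all missing are left
#' unscaled with a warning.  The operation is idempotent.
#'
#' @param psm PSM table.
#' @return PSM table with scaled intensities.
#' @export
median_scale <- function(psm) {
  cols <- intensity_columns()
  for (plex in unique(psm$plex_id)) {
    rows <- psm$plex_id == plex
    meds <- vapply(cols, function(ic) {
      median(psm[rows, ic], na.rm = TRUE)
    }, numeric(1))
    if (anyNA(meds)) {
      warning("plex ", plex, ": channel(s) with all-missing intensities left unscaled")
    }
    grand <- median(meds, na.rm = TRUE)
    for (ic in cols[!is.na(meds) & meds > 0]) {
      psm[rows, ic] <- psm[rows, ic] * (grand / meds[[ic]])
    }
  }
  psm
}

#' Log2 ratios of experimental channels to the plex reference pool
#'
#' Divides each experimental sample's intensity by the intensity of the
#' reference-pool channel of the same plex and takes log2.  A ratio is
#' missing whenever either term is missing or zero (log of zero is
#' undefined, so zeros propagate to missing here).  The reference channel
#' itself is dropped.
#'
#' @param psm PSM table (intensity scale).
#' @param meta sample metadata declaring the reference_pool channel per
#'   plex; see [read_sample_metadata()].
#' @return data.frame with `peptide_sequence`, `protein_group`, `plex_id`
#'   and one log2-ratio column per experimental sample (NA outside the
#'   PSM's plex).
#' @export
compute_ratios <- function(psm, meta) {
  validate_sample_metadata(meta)
  plexes <- unique(psm$plex_id)
  orphan <- setdiff(plexes, meta$plex_id)
  if (length(orphan))
    stop("no metadata for plex(es): ", paste(orphan, collapse = ", "),
         call. = FALSE)
  exper <- meta[meta$role == "experimental", ]
  samples <- exper$sample_id
  ratios <- matrix(NA_real_, nrow(psm), length(samples),
                   dimnames = list(NULL, samples))
  for (plex in plexes) {
    rows <- psm$plex_id == plex
    refch <- meta$channel[meta$plex_id == plex & meta$role == "reference_pool"]
    ref <- psm[rows, paste0("intensity_", refch)]
    ref[!is.na(ref) & ref == 0] <- NA
    inplex <- exper[exper$plex_id == plex, ]
    for (j in seq_len(nrow(inplex))) {
      v <- psm[rows, paste0("intensity_", inplex$channel[j])]
      v[!is.na(v) & v == 0] <- NA
      ratios[rows, inplex$sample_id[j]] <- log2(v / ref)
    }
  }
  cbind(psm[, c("peptide_sequence", "protein_group", "plex_id")],
        as.data.frame(ratios, check.names = FALSE))
}

#' Roll PSM log2 ratios up to a peptide matrix
#'
#' One row per distinct peptide sequence; each cell is the median of that
#' peptide's observed PSM log2 ratios in that sample (missing when no PSM
#' was observed).  The peptide's accession set is the union over its
#' contributing PSMs.  Output is invariant to PSM row order.
#'
#' @param psm_ratios output of [compute_ratios()].
#' @return a [feature_matrix()] of peptides x samples.
#' @export
rollup_peptides <- function(psm_ratios) {
  samples <- setdiff(names(psm_ratios),
                     c("peptide_sequence", "protein_group", "plex_id"))
  peps <- sort(unique(psm_ratios$peptide_sequence))
  idx <- split(seq_len(nrow(psm_ratios)),
               factor(psm_ratios$peptide_sequence, levels = peps))
  vals <- matrix(NA_real_, length(peps), length(samples),
                 dimnames = list(peps, samples))
  rmat <- as.matrix(psm_ratios[, samples, drop = FALSE])
  for (i in seq_along(peps)) {
    block <- rmat[idx[[i]], , drop = FALSE]
    vals[i, ] <- apply(block, 2, median, na.rm = TRUE)
  }
  vals[is.nan(vals)] <- NA_real_
  groups <- vapply(idx, function(r) {
    paste(sort(unique(unlist(
      strsplit(psm_ratios$protein_group[r], ";", fixed = TRUE)))),
      collapse = ";")
  }, "")
  feature_matrix(vals, groups)
}
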