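## Peptide-matrix preprocessing: group-wise missingness filter, iterative-PCA
## imputation, quantile normalization, batch correction, unique-protein-group
## filter, trimmed-mean protein roll-up.

#' Filter peptides by per-group missingness
#'
#' A peptide is retained iff its fraction of missing values is at or below
#' `threshold` within *every* treatment group (the stricter reading of a
#' per-group rule; the `any`-group variant can be had by pre-splitting the
#' matrix).  The number of removed peptides is attached as attribute
#' `"removed"`.
#'
#' @param pep peptide [feature_matrix()].
#' @param meta sample metadata; every column of `pep` must appear with an
#'   `NR` or `SR` group label.
#' @param threshold maximum tolerated missing fraction per group
#'   (default 0.36).
#' @return filtered `feature_matrix`.
#' @export
filter_missing <- function(pep, meta, threshold = 0.36) {
  stopifnot(threshold >= 0, threshold <= 1)
  grp <- group_of(meta, colnames(pep$values))
  keep <- rep(TRUE, nrow(pep$values))
  for (g in c("NR", "SR")) {
    cols <- which(grp == g)
    if (!length(cols)) stop("group ", g, " has no samples", call. = FALSE)
    frac <- rowMeans(is.na(pep$values[, cols, drop = FALSE]))
    keep <- keep & frac <= threshold
  }
  out <- subset_features(pep, keep)
  attr(out, "removed") <- sum(!keep)
  out
}

group_of <- function(meta, sample_ids) {
  exper <- meta[meta$role == "experimental", ]
  miss <- setdiff(sample_ids, exper$sample_id)
  if (length(miss))
    stop("samples without metadata: ", paste(head(miss), collapse = ", "),
         call. = FALSE)
  setNames(exper$group[match(sample_ids, exper$sample_id)], sample_ids)
}

#' Impute missing values by iterative principal component analysis
#'
#' Deterministic EM-style iPCA: missing cells are initialised with their
#' feature (row) means, then the loop \{column-centre, rank-k truncated SVD
#' reconstruction, re-fill the missing cells\} repeats until the largest
#' absolute change in any imputed cell drops below `tol` or `max_iter` is
#' reached (warning with the final delta in that case).  Observed cells are
#' never altered.
#'
#' @param pep peptide `feature_matrix` (or plain matrix).
#' @param n_components rank of the reconstruction, must be smaller than
#'   both dimensions (default 2).
#' @param tol convergence tolerance on imputed cells (default 1e-6).
#' @param max_iter iteration cap (default 200).
#' @return complete `feature_matrix` (or matrix) with no missing cells.
#' @export
impute_ipca <- function(pep, n_components = 2, tol = 1e-6, max_iter = 200) {
  is_fm <- inherits(pep, "feature_matrix")
  x <- if (is_fm) pep$values else pep
  stopifnot(n_components >= 1, n_components < min(dim(x)))
  miss <- is.na(x)
  if (!any(miss)) return(pep)
  if (any(rowSums(!miss) == 0L))
    stop("matrix has a feature with no observed values", call. = FALSE)
  if (any(colSums(!miss) == 0L))
    stop("matrix has a sample with no observed values", call. = FALSE)
  rmean <- rowMeans(x, na.rm = TRUE)
  filled <- x
  filled[miss] <- rmean[row(x)[miss]]
  delta <- Inf
  for (iter in seq_len(max_iter)) {
    mu <- colMeans(filled)
    centred <- sweep(filled, 2, mu)
    sv <- svd(centred, nu = n_components, nv = n_components)
    d <- sv$d[seq_len(n_components)]
    recon <- sweep(sv$u %*% (d * t(sv$v)), 2, mu, `+`)
    delta <- max(abs(recon[miss] - filled[miss]))
    filled[miss] <- recon[miss]
    if (delta < tol) break
  }
  if (delta >= tol)
    warning(sprintf("iPCA imputation stopped at max_iter=%d (delta=%.3g)",
                    max_iter, delta))
  if (is_fm) feature_matrix(filled, pep$feature_to_group) else filled
}

#' Quantile-normalize a complete matrix
#'
#' Forces every sample (column) onto the common distribution given by the
#' row-wise means of the column order statistics, preserving within-column
#' ranks; ties share the mean of their would-be quantiles.  Delegates to
#' `limma::normalizeQuantiles`.  Idempotent.
#'
#' @param pep complete peptide `feature_matrix` (or plain matrix).
#' @return normalized object of the same class.
#' @export
quantile_normalize <- function(pep) {
  is_fm <- inherits(pep, "feature_matrix")
  x <- if (is_fm) pep$values else pep
  if (anyNA(x)) stop("quantile normalization requires a complete matrix",
                     call. = FALSE)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  if (is_fm) feature_matrix(out, pep$feature_to_group) else out
}

#' Remove TMT-plex and centre batch effects
#'
#' Per feature, fits least squares on the combined design \[protected
#' covariates | batch dummies\] and subtracts only the fitted batch
#' contribution, leaving group-related variation untouched.  The protected
#' design is the intercept plus the recovery group; batches are the TMT
#' plex and the medical centre (either may be dropped when it has a single
#' level).  Delegates to `limma::removeBatchEffect`, whose sum-to-zero
#' batch coding keeps the grand mean in place.  Idempotent.
#'
#' @param pep complete peptide `feature_matrix` (or matrix).
#' @param meta sample metadata.
#' @param batch_factors metadata columns to correct for
#'   (default `c("plex_id", "centre")`).
#' @return corrected object of the same class.
#' @export
remove_batch <- function(pep, meta, batch_factors = c("plex_id", "centre")) {
  is_fm <- inherits(pep, "feature_matrix")
  x <- if (is_fm) pep$values else pep
  exper <- meta[meta$role == "experimental", ]
  exper <- exper[match(colnames(x), exper$sample_id), ]
  grp <- factor(exper$group, levels = c("SR", "NR"))
  protected <- model.matrix(~grp)
  batches <- lapply(batch_factors, function(f) factor(exper[[f]]))
  batches <- batches[vapply(batches, nlevels, 0L) > 1L]
  if (!length(batches)) return(pep)
  for (b in batches) {
    if (qr(cbind(protected, model.matrix(~b)[, -1, drop = FALSE]))$rank <
        ncol(protected) + nlevels(b) - 1L)
      stop("batch factor is confounded with the protected design (aliased: ",
           paste(levels(b), collapse = "/"), ")", call. = FALSE)
  }
  out <- if (length(batches) == 1L) {
    limma::removeBatchEffect(x, batch = batches[[1]], design = protected)
  } else {
    limma::removeBatchEffect(x, batch = batches[[1]], batch2 = batches[[2]],
                             design = protected)
  }
  dimnames(out) <- dimnames(x)
  if (is_fm) feature_matrix(out, pep$feature_to_group) else out
}

#' Keep only peptides mapping to exactly one protein group
#'
#' Peptides whose accession set contains more than one protein group are
#' ambiguous for protein quantification and are removed.
#'
#' @param pep peptide `feature_matrix`.
#' @return filtered `feature_matrix` (warning when nothing is left).
#' @export
filter_unique_groups <- function(pep) {
  keep <- group_unique(pep)
  if (!any(keep)) warning("no unique-protein-group peptides remain")
  out <- subset_features(pep, keep)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Symmetric trimmed mean
#'
#' Removes `floor(trim * length(x))` values from each tail before
#' averaging; with fewer than 3 values the plain mean is returned.
#'
#' @param x numeric vector.
#' @param trim fraction trimmed from each tail, in \[0, 0.5).
#' @return scalar mean.
#' @export
trimmed_mean <- function(x, trim = 0.2) {
  stopifnot(trim >= 0, trim < 0.5)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n < 3L) return(mean(x))
  k <- floor(trim * n)
  if (k > 0L) x <- sort(x)[(k + 1L):(n - k)]
  mean(x)
}

#' Roll unique-group peptides up to a protein matrix
#'
#' Each protein's value in a sample is the symmetric trimmed mean of its
#' peptides' values in that sample.
#'
#' @param pep peptide `feature_matrix`; every peptide must map to exactly
#'   one protein group (see [filter_unique_groups()]).
#' @param trim_fraction trim fraction per tail (default 0.2).
#' @return protein `feature_matrix` (each protein maps to itself).
#' @export
rollup_proteins <- function(pep, trim_fraction = 0.2) {
  if (!all(group_unique(pep)))
    stop("rollup_proteins requires unique-group peptides; run filter_unique_groups first",
         call. = FALSE)
  acc <- vapply(pep$feature_to_group, `[[`, "", 1L)
  prots <- sort(unique(acc))
  idx <- split(seq_len(nrow(pep$values)), factor(acc, levels = prots))
  vals <- matrix(NA_real_, length(prots), ncol(pep$values),
                 dimnames = list(prots, colnames(pep$values)))
  for (i in seq_along(prots)) {
    block <- pep$values[idx[[i]], , drop = FALSE]
    vals[i, ] <- apply(block, 2, trimmed_mean, trim = trim_fraction)
  }
  feature_matrix(vals)
}
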