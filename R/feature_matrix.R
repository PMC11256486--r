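## Feature-by-sample log2-ratio matrices (peptide or protein level) with an
## explicit missingness convention (NA) and a feature -> protein-group map.

#' Construct a feature matrix
#'
#' A `feature_matrix` holds a features x samples numeric matrix on the log2
#' ratio scale (NA = missing) together with the mapping of each feature to
#' its protein-group accession(s).  Peptide matrices map peptides to one or
#' more accessions; protein matrices map each protein to itself.
#'
#' @param values numeric matrix, rownames = feature ids, colnames = sample
#'   ids.
#' @param feature_to_group named list (or ";"-separated character vector) of
#'   accession sets, one entry per feature.
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, feature_to_group = NULL) {
  # R normalizes zero-length rownames to NULL, so only require them when
  # there are features
  stopifnot(is.matrix(values),
            nrow(values) == 0L || !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids", call. = FALSE)
  if (is.null(feature_to_group))
    feature_to_group <- as.list(setNames(rownames(values), rownames(values)))
  if (is.character(feature_to_group))
    feature_to_group <- strsplit(feature_to_group, ";", fixed = TRUE)
  stopifnot(length(feature_to_group) == nrow(values))
  names(feature_to_group) <- rownames(values)
  structure(list(values = values, feature_to_group = feature_to_group),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features x %d samples (%.1f%% missing, %d unique-group features)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values)), sum(group_unique(x))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Per-feature indicator of belonging to exactly one protein group
#' @param fm a `feature_matrix`
#' @return logical vector, one entry per feature.
#' @export
group_unique <- function(fm) {
  vapply(fm$feature_to_group,
         function(g) length(unique(g[nzchar(g)])) == 1L, logical(1))
}

#' Subset a feature matrix by feature
#' @param fm a `feature_matrix`
#' @param keep logical or character index of features to retain
#' @return a `feature_matrix`
#' @export
subset_features <- function(fm, keep) {
  feature_matrix(fm$values[keep, , drop = FALSE], fm$feature_to_group[keep])
}

#' Write / read a feature matrix as tab-delimited text
#'
#' The first two columns hold the feature id and its ";"-separated accession
#' set; the remaining columns are samples.  Round-trips losslessly up to
#' numeric printing precision (15 significant digits are written).
#'
#' @param fm a `feature_matrix`
#' @param path file path
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(
    feature_id = rownames(fm$values),
    protein_group = vapply(fm$feature_to_group, paste, "", collapse = ";"),
    signif(fm$values, 15), check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$feature_id
  feature_matrix(vals, df$protein_group)
}
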