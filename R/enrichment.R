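## Fisher-exact over-representation of annotation terms among regulated
## features against the non-regulated background, with BH correction.

#' Fisher-exact term enrichment
#'
#' For each annotation term, builds the 2x2 table \{regulated, background\}
#' x \{in term, not in term\} and computes the two-sided Fisher exact
#' p-value (minimum-likelihood convention: the sum of hypergeometric
#' probabilities no larger than the observed table's).  Terms matching
#' fewer than `min_matches` regulated identifiers are not tested and are
#' absent from the output.  BH adjustment runs across tested terms only;
#' `significant` flags adjusted p below `adjp_threshold`.  The background
#' must be the non-regulated set, disjoint from the regulated one.
#'
#' @param regulated character set of regulated feature identifiers (e.g.
#'   gene names after mapping peptides through their protein group).
#' @param background character set of non-regulated identifiers.
#' @param annotations named list: term -> character vector of member
#'   identifiers (see [read_gmt()]).
#' @param min_matches minimum regulated identifiers matched per term
#'   (default 2).
#' @param adjp_threshold significance cut-off on adjusted p (default 0.3).
#' @return data.frame sorted by adjusted p with columns `term`, `k`
#'   (regulated in term), `K` (regulated total), `n` (background in term),
#'   `N` (background total), `enrichment` ((k/K)/(n/N)), `direction`
#'   (over/under), `p`, `adj_p`, `significant`.
#' @export
fisher_enrich <- function(regulated, background, annotations,
                          min_matches = 2, adjp_threshold = 0.3) {
  regulated <- unique(regulated)
  background <- unique(background)
  if (length(intersect(regulated, background)))
    stop("regulated and background sets must be disjoint", call. = FALSE)
  universe <- c(regulated, background)
  K <- length(regulated)
  N <- length(background)
  rows <- lapply(names(annotations), function(term) {
    members <- intersect(unique(annotations[[term]]), universe)
    k <- sum(members %in% regulated)
    if (k < min_matches) return(NULL)
    n <- length(members) - k
    tab <- matrix(c(k, K - k, n, N - n), 2,
                  dimnames = list(c("in_term", "out"), c("regulated", "background")))
    p <- min(fisher.test(tab, alternative = "two.sided")$p.value, 1)
    enr <- if (n == 0) Inf else (k / K) / (n / N)
    data.frame(term = term, k = k, K = K, n = n, N = N,
               enrichment = enr,
               direction = if (k / K >= n / N) "over" else "under",
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    warning("no annotation term matched at least ", min_matches,
            " regulated identifiers")
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), enrichment = numeric(),
                      direction = character(), p = numeric(),
                      adj_p = numeric(), significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < adjp_threshold
  out <- out[order(out$adj_p, out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Read / write GMT-style annotation files
#'
#' One term per line: term id, description, then tab-separated member
#' identifiers.
#'
#' @param path file path.
#' @return named list term -> member vector; descriptions in attribute
#'   `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(terms) <- vapply(parts, `[[`, "", 1L)
  attr(terms, "description") <- vapply(parts, `[[`, "", 2L)
  terms
}

#' @rdname read_gmt
#' @param annotations named list term -> members.
#' @param descriptions optional character vector of term descriptions.
#' @export
write_gmt <- function(annotations, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(annotations, "description")
  if (is.null(descriptions)) descriptions <- names(annotations)
  lines <- vapply(seq_along(annotations), function(i) {
    paste(c(names(annotations)[i], descriptions[i], annotations[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
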