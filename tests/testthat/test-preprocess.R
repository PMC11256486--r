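make_fm <- function(vals, groups = NULL) {
  if (is.null(rownames(vals))) rownames(vals) <- sprintf("PEP%02d", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- sprintf("S%02d", seq_len(ncol(vals)))
  feature_matrix(vals, groups)
}

test_that("missingness filter applies the threshold within every group", {
  meta <- toy_meta(n_nr = 20, n_sr = 10, n_plexes = 3)
  vals <- matrix(0, 3, 30,
                 dimnames = list(paste0("PEP", 1:3), meta$sample_id[1:30]))
  nr <- meta$sample_id[which(meta$group == "NR")]
  sr <- meta$sample_id[which(meta$group == "SR")]
  vals[1, sr[1:4]] <- NA                      # 40% missing in SR
  vals[2, sr[1:3]] <- NA                      # 30% in SR ...
  vals[2, nr[1:7]] <- NA                      # ... and 35% in NR
  fm <- make_fm(vals)
  out <- filter_missing(fm, meta, 0.36)
  expect_identical(rownames(out$values), c("PEP2", "PEP3"))
  expect_identical(attr(out, "removed"), 1L)
  expect_equal(nrow(filter_missing(fm, meta, 1)$values), 3)  # vacuous
})

test_that("iPCA imputation recovers masked cells of low-rank matrices", {
  # complete matrix: unchanged
  full <- make_fm(matrix(rnorm(40), 8, 5))
  expect_identical(impute_ipca(full, 2), full)

  # exact rank-1: masked cell recovered
  u <- seq(1, 2, length.out = 9)
  v <- seq(-1, 1.5, length.out = 6)
  M <- outer(u, v)
  truth <- M[3, 4]
  M[3, 4] <- NA
  imp <- impute_ipca(make_fm(M), 1, tol = 1e-9)
  expect_lt(abs(imp$values[3, 4] - truth), 1e-6)

  # exact rank-2 with k = 2
  set.seed(6)
  M2 <- tcrossprod(matrix(rnorm(20), 10, 2), matrix(rnorm(12), 6, 2))
  idx <- cbind(c(2, 7), c(5, 1))
  truth2 <- M2[idx]
  M2[idx] <- NA
  imp2 <- impute_ipca(make_fm(M2), 2, tol = 1e-10, max_iter = 2000)
  expect_lt(max(abs(imp2$values[idx] - truth2)), 1e-5)
})

test_that("imputation never alters observed cells and rejects empty rows", {
  set.seed(7)
  vals <- matrix(rnorm(60), 10, 6)
  vals[sample(60, 10)] <- NA
  fm <- make_fm(vals)
  imp <- impute_ipca(fm, 2)
  obs <- !is.na(vals)
  expect_identical(imp$values[obs], vals[obs])
  expect_false(anyNA(imp$values))
  bad <- vals
  bad[3, ] <- NA
  expect_error(impute_ipca(make_fm(bad), 2), "no observed values")
})

test_that("quantile normalization maps columns onto the mean order statistics", {
  # 2x2 toy: columns (1,2) and (3,4) -> order-stat means (2, 3) in rank order
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  out <- quantile_normalize(make_fm(m))$values
  expect_equal(unname(out), matrix(c(2, 3, 2, 3), 2, 2))

  set.seed(8)
  x <- matrix(rnorm(200, sd = rep(c(1, 3, 0.5, 2), each = 50)), 50, 4)
  qn <- quantile_normalize(make_fm(x))$values
  for (j in 2:4) expect_equal(unname(sort(qn[, j])), unname(sort(qn[, 1])))
  expect_equal(diff(range(colMeans(qn))), 0, tolerance = 1e-12)
  # rank preservation and idempotence
  expect_equal(unname(apply(qn, 2, rank)), unname(apply(x, 2, rank)))
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
})

test_that("batch correction removes additive plex offsets, sparing the group effect", {
  meta <- toy_meta(n_nr = 6, n_sr = 6, n_plexes = 2)
  exper <- meta[meta$role == "experimental", ]
  base <- matrix(rep(c(1, 0), times = c(6, 6)), 20, 12, byrow = TRUE)  # NR +1
  delta <- ifelse(exper$plex_id == "plex1", 0.7, -0.7)
  vals <- base + matrix(delta, 20, 12, byrow = TRUE)
  dimnames(vals) <- list(sprintf("PEP%02d", 1:20), exper$sample_id)
  out <- remove_batch(make_fm(vals), meta, batch_factors = "plex_id")$values
  for (f in 1:20) {
    m1 <- mean(out[f, exper$plex_id == "plex1"])
    m2 <- mean(out[f, exper$plex_id == "plex2"])
    expect_equal(m1 - m2, 0, tolerance = 1e-9)
  }
  gdiff <- rowMeans(out[, exper$group == "NR"]) -
           rowMeans(out[, exper$group == "SR"])
  expect_equal(unname(gdiff), rep(1, 20), tolerance = 1e-9)

  # no batch effect simulated: correction is (numerically) a no-op
  vals0 <- base
  dimnames(vals0) <- dimnames(vals)
  out0 <- remove_batch(make_fm(vals0), meta, batch_factors = "plex_id")$values
  expect_equal(out0, vals0, tolerance = 1e-9)
})

test_that("batch correction estimates simulated offsets accurately and is idempotent", {
  set.seed(9)
  st <- generate_study(small_design(9))
  res <- run_pipeline(run_config(), st$psm, st$meta)
  # re-add known plex offsets to the corrected matrix and remove them again
  pep <- res$peptides
  off <- st$truth$sample_offsets
  delta <- off$plex_offset[match(colnames(pep$values), off$sample_id)]
  dirty <- pep
  dirty$values <- pep$values + matrix(delta, nrow(pep$values),
                                      ncol(pep$values), byrow = TRUE)
  clean <- remove_batch(dirty, st$meta, batch_factors = "plex_id")
  est <- colMeans(dirty$values - clean$values)
  expect_gt(cor(est, delta), 0.99)
  twice <- remove_batch(clean, st$meta, batch_factors = "plex_id")
  expect_equal(twice$values, clean$values, tolerance = 1e-9)
})

test_that("single-level batch factors are dropped and confounding is caught", {
  meta <- toy_meta(n_nr = 3, n_sr = 3, n_plexes = 1)
  vals <- matrix(rnorm(30), 5, 6,
                 dimnames = list(sprintf("PEP%02d", 1:5),
                                 meta$sample_id[1:6]))
  fm <- make_fm(vals)
  expect_equal(remove_batch(fm, meta, batch_factors = "plex_id"), fm)

  conf <- toy_meta(n_nr = 4, n_sr = 4, n_plexes = 1)
  conf$centre <- ifelse(is.na(conf$group), NA,
                        ifelse(conf$group == "NR", "Murnau", "Toledo"))
  vals2 <- matrix(rnorm(40), 5, 8,
                  dimnames = list(sprintf("PEP%02d", 1:5),
                                  conf$sample_id[1:8]))
  expect_error(remove_batch(make_fm(vals2), conf, batch_factors = "centre"),
               "confounded")
})

test_that("unique-group filter and trimmed-mean protein roll-up", {
  vals <- matrix(rnorm(20), 4, 5)
  fm <- make_fm(vals, c("P1", "P1;P2", "P2", "P1"))
  out <- filter_unique_groups(fm)
  expect_identical(rownames(out$values), c("PEP01", "PEP03", "PEP04"))
  expect_error(rollup_proteins(fm), "unique-group")
  shared_only <- make_fm(vals[1:2, ], c("P1;P2", "P2;P3"))
  expect_warning(filter_unique_groups(shared_only), "no unique")

  expect_equal(trimmed_mean(c(0, 1, 2, 3, 100), 0.2), 2)  # trims 0 and 100
  expect_equal(trimmed_mean(5, 0.4), 5)
  expect_equal(trimmed_mean(c(7, 7, 7, 7), 0.2), 7)
  expect_equal(trimmed_mean(c(1, 3), 0.45), 2)            # < 3 values: mean

  pvals <- matrix(c(0, 1, 2, 3, 100), 5, 2)
  pfm <- make_fm(pvals, rep("P9", 5))
  prot <- rollup_proteins(pfm, 0.2)
  expect_equal(unname(prot$values["P9", ]), c(2, 2))
  expect_identical(prot$feature_to_group$P9, "P9")
})

test_that("filters never increase the row count", {
  st <- generate_study(small_design(2))
  res <- run_pipeline(run_config(), st$psm, st$meta)
  rep <- res$report
  filt <- rep[rep$stage %in% c("psm_annotation_filter",
                               "isolation_interference_filter",
                               "missingness_filter_imputation",
                               "unique_group_filter"), ]
  expect_true(all(filt$rows_out <= filt$rows_in))
})
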