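test_that("per-feature OLS matches hand fits and a normal-equations oracle", {
  # exact two-group fit: SR {0,0}, NR {1,1}
  X <- cbind("(Intercept)" = 1, groupNR = c(0, 0, 1, 1))
  Y <- matrix(c(0, 0, 1, 1), 1, 4,
              dimnames = list("f1", paste0("S", 1:4)))
  fit <- fit_feature_models(Y, X)
  expect_equal(unname(fit$logfc), 1)
  expect_equal(unname(fit$s2), 0)
  expect_equal(fit$df_residual, 2)

  # covariate orthogonal to the contrast leaves logFC unchanged
  set.seed(10)
  n <- 12
  g <- rep(c(0, 1), each = 6)
  z <- rep(c(-1, 1), 6)                      # orthogonal to g and intercept
  Y2 <- matrix(rnorm(5 * n), 5, n,
               dimnames = list(paste0("f", 1:5), paste0("S", 1:n)))
  f_plain <- fit_feature_models(Y2, cbind("(Intercept)" = 1, groupNR = g))
  f_cov <- fit_feature_models(Y2, cbind("(Intercept)" = 1, groupNR = g,
                                        z = z))
  expect_equal(f_cov$logfc, f_plain$logfc, tolerance = 1e-12)

  # normal-equations oracle
  X3 <- cbind("(Intercept)" = 1, groupNR = g, age = rnorm(n),
              sexmale = rep(c(1, 0), 6))
  Y3 <- matrix(rnorm(20 * n), 20, n,
               dimnames = list(paste0("f", 1:20), paste0("S", 1:n)))
  fit3 <- fit_feature_models(Y3, X3)
  XtXi <- solve(t(X3) %*% X3)
  beta_oracle <- XtXi %*% t(X3) %*% t(Y3)
  expect_equal(unname(fit3$logfc), unname(beta_oracle["groupNR", ]),
               tolerance = 1e-10)
  res <- t(Y3) - X3 %*% beta_oracle
  expect_equal(unname(fit3$s2), unname(colSums(res^2) / (n - 4)),
               tolerance = 1e-10)
  expect_equal(fit3$stdev_unscaled, sqrt(XtXi["groupNR", "groupNR"]),
               tolerance = 1e-12)

  # rank deficiency is reported with the aliased column
  Xbad <- cbind(X, dup = X[, "groupNR"])
  expect_error(fit_feature_models(Y, Xbad), "dup")
})

test_that("the design matrix uses the stated reference levels", {
  meta <- toy_meta(4, 4)
  ids <- meta$sample_id[1:8]
  X <- make_design(meta, ids, "peptide")
  expect_true(all(c("(Intercept)", "groupNR", "injury_leveltetraplegia",
                    "centreMurnau", "sexmale", "age", "storage_days")
                  %in% colnames(X)))
  expect_false("ais_gradeB" %in% colnames(X))
  Xp <- make_design(meta, ids, "protein")
  expect_true("ais_gradeB" %in% colnames(Xp))
  expect_equal(unname(X[, "groupNR"]),
               as.numeric(meta$group[1:8] == "NR"))
  expect_equal(sum(X[, "age"]), 0, tolerance = 1e-12)   # centred
})

test_that("variance moderation matches its scaled inverse-chi-square prior", {
  # identical variances: s0^2 equals the common value, moderated t = plain t
  X <- cbind("(Intercept)" = 1, groupNR = rep(c(0, 1), each = 4))
  Y <- matrix(rnorm(160), 20, 8,
              dimnames = list(paste0("f", 1:20), paste0("S", 1:8)))
  fit <- fit_feature_models(Y, X)
  fit$s2 <- rep(0.25, 20)
  mf <- moderate_fits(fit)
  expect_equal(mf$s2_prior, 0.25)
  expect_true(is.infinite(mf$df_prior))
  t_ord <- fit$logfc / (fit$stdev_unscaled * 0.5)
  expect_equal(mf$table$t, unname(t_ord), tolerance = 1e-12)

  # forced d0 = 0: ordinary t exactly
  fit2 <- fit_feature_models(Y, X)
  m0 <- moderate_fits(fit2, prior_df = 0)
  expect_equal(m0$table$t,
               unname(fit2$logfc / (fit2$stdev_unscaled * sqrt(fit2$s2))),
               tolerance = 1e-12)
  expect_equal(m0$table$p,
               unname(2 * pt(-abs(m0$table$t), df = fit2$df_residual)),
               tolerance = 1e-12)

  # shrinkage ordering: s2 below the prior moves up, above moves down
  set.seed(11)
  fit3 <- fit_feature_models(
    matrix(rnorm(200 * 8, sd = rep(runif(200, 0.2, 3), 8)), 200, 8,
           dimnames = list(paste0("f", 1:200), paste0("S", 1:8))), X)
  m3 <- moderate_fits(fit3)
  expect_true(is.finite(m3$df_prior))
  lo <- fit3$s2 < m3$s2_prior
  expect_true(all(m3$s2_post[lo] > fit3$s2[lo]))
  expect_true(all(m3$s2_post[!lo] < fit3$s2[!lo]))
  expect_true(all(m3$s2_post >= pmin(fit3$s2, m3$s2_prior) - 1e-12))
  expect_true(all(m3$s2_post <= pmax(fit3$s2, m3$s2_prior) + 1e-12))
})

test_that("prior parameters are recovered from simulated variances", {
  rec <- t(vapply(1:20, function(s) {
    set.seed(s)
    d0 <- 4; s02 <- 0.04; d <- 10; m <- 200
    sig2 <- d0 * s02 / rchisq(m, d0)
    fit <- structure(list(logfc = rnorm(m), s2 = sig2 * rchisq(m, d) / d,
                          df_residual = d, stdev_unscaled = rep(0.3, m),
                          coef = "groupNR",
                          feature_ids = paste0("f", seq_len(m))),
                     class = "feature_fit")
    mf <- moderate_fits(fit)
    c(mf$df_prior, mf$s2_prior)
  }, numeric(2)))
  expect_lt(abs(median(rec[, 1]) - 4) / 4, 0.30)
  expect_lt(abs(median(rec[, 2]) - 0.04) / 0.04, 0.15)
})

test_that("moderation agrees with an independent empirical-Bayes implementation", {
  set.seed(12)
  m <- 300; n <- 12
  X <- cbind("(Intercept)" = 1, groupNR = rep(c(0, 1), each = 6),
             cov = rnorm(n))
  sig2 <- 5 * 0.05 / rchisq(m, 5)
  Y <- matrix(rnorm(m * n, 0, sqrt(rep(sig2, n))), m, n,
              dimnames = list(paste0("f", 1:m), paste0("s", 1:n)))
  mf <- moderate_fits(fit_feature_models(Y, X))
  lf <- limma::eBayes(limma::lmFit(Y, X))
  expect_equal(mf$df_prior, unname(lf$df.prior), tolerance = 1e-8)
  expect_equal(mf$s2_prior, unname(lf$s2.prior), tolerance = 1e-8)
  expect_equal(mf$table$t, unname(lf$t[, "groupNR"]), tolerance = 1e-8)
  expect_equal(mf$table$p, unname(lf$p.value[, "groupNR"]), tolerance = 1e-8)
})

test_that("moderated p-values are approximately uniform under the null", {
  ks <- vapply(1:20, function(s) {
    set.seed(100 + s)
    X <- cbind("(Intercept)" = 1, groupNR = rep(c(0, 1), each = 5))
    Y <- matrix(rnorm(2000), 200, 10,
                dimnames = list(paste0("f", 1:200), paste0("S", 1:10)))
    mf <- moderate_fits(fit_feature_models(Y, X))
    suppressWarnings(stats::ks.test(mf$table$p, "punif")$p.value)
  }, numeric(1))
  expect_gt(mean(ks > 0.01), 0.8)   # KS at 1% rejects rarely
})

test_that("BH adjustment follows the step-up arithmetic", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.7), 0.7)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("the fold-change threshold follows log2(FCT) = multiplier x median SD", {
  thr <- fct_from_sd(0.4375, 1.47)
  expect_equal(thr$fct, 2^(1.47 * 0.4375), tolerance = 1e-12)
  expect_equal(thr$fct_rounded, 1.6)
  expect_equal(fct_from_sd(0)$fct, 1)
  # inverse: FCT 1.8 corresponds to median SD log2(1.8)/1.47
  expect_equal(fct_from_sd(log2(1.8) / 1.47)$fct, 1.8, tolerance = 1e-12)

  # matrix route: rows engineered so the median per-feature SD is exact
  set.seed(13)
  sds <- c(0.2, 0.4375, 0.9)
  vals <- t(sapply(sds, function(s) scale(rnorm(10))[, 1] * s))
  dimnames(vals) <- list(paste0("f", 1:3), paste0("S", 1:10))
  got <- compute_fct(vals)
  expect_equal(got$median_sd, 0.4375, tolerance = 1e-12)
  expect_equal(got$fct_rounded, 1.6)
})

test_that("classification applies both thresholds with the NR/SR sign convention", {
  tab <- data.frame(feature = paste0("f", 1:4),
                    logFC = c(1.2, 0, -0.9, 0.3),
                    t = 1, p = c(0.001, 0.2, 0.01, 0.04))
  tab$adj_p <- bh_adjust(tab$p)
  mf <- structure(list(table = tab), class = "moderated_fit")
  cls <- classify_features(mf, fct_from_sd(0.4375), alpha = 0.05, fdr = 0.1)
  expect_identical(cls$table$class,
                   c("significant_and_fc", "neither", "significant_and_fc",
                     "significant_only"))
  expect_identical(cls$table$direction[1:3], c("NR", "none", "SR"))
  expect_equal(unname(cls$counts["significant_and_fc"]), 2)
  expect_equal(unname(cls$counts["enriched_NR"]), 1)
  expect_equal(unname(cls$counts["enriched_SR"]), 1)
  # FDR subset is a subset of significant_and_fc
  expect_true(all(cls$table$class[cls$table$fdr_pass] == "significant_and_fc"))
  # invariance to feature order
  perm <- mf
  perm$table <- tab[c(3, 1, 4, 2), ]
  cls2 <- classify_features(perm, fct_from_sd(0.4375), alpha = 0.05)
  expect_identical(cls2$counts, cls$counts)
})

test_that("logFC converts to fold enrichment at reported precision", {
  expect_equal(logfc_to_fold(1.58), 2.99)
  expect_equal(logfc_to_fold(-1.047), 2.07)
  expect_equal(logfc_to_fold(-1.144), 2.21)
  expect_equal(logfc_to_fold(0), 1)
  expect_equal(logfc_to_fold(1), 2)
})

test_that("every reported logFC/fold pair is reproduced at printed precision", {
  tab <- read.delim(system.file("extdata", "reported_protein_folds.tsv",
                                package = "sciserum"))
  digits <- ifelse(tab$fold_printed %% 1 == 0, 0, 2)
  recomputed <- 2^abs(tab$log2fc_nr_vs_sr)
  # printed folds come from logFCs themselves rounded to 3 decimals, so
  # agreement is to one unit in the last printed digit
  ulp <- 10^(-digits)
  expect_true(all(abs(recomputed - tab$fold_printed) <= 1.05 * ulp))
  # and most rows round exactly
  expect_gte(sum(round(recomputed, 2) == tab$fold_printed), 20)
  # sign convention: negative logFC = enriched in SR
  expect_identical(unique(tab$enriched_in[tab$log2fc_nr_vs_sr < 0]), "SR")
  expect_identical(unique(tab$enriched_in[tab$log2fc_nr_vs_sr > 0]), "NR")
})
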