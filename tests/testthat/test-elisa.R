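true5pl <- list(a = 0.05, d = 3.2, c = 250, b = 1.2, g = 1.4)

test_that("standard-curve fitting recovers a known 5PL and picks linear when linear", {
  conc <- 4000 / 2^(0:6)
  od <- fivepl(conc, true5pl$a, true5pl$d, true5pl$c, true5pl$b, true5pl$g)
  cv <- fit_standard_curve(rep(conc, each = 2), rep(od, each = 2))
  expect_identical(cv$model, "5pl")
  expect_equal(cv$r2, 1, tolerance = 1e-9)
  for (p in names(true5pl)) {
    expect_equal(cv$params[[p]], true5pl[[p]], tolerance = 1e-3)
  }
  expect_true(cv$r2_pass)

  # exactly linear standards: linear wins with exact coefficients
  lconc <- seq(10, 100, length.out = 6)
  lcv <- fit_standard_curve(lconc, 0.1 + 0.02 * lconc)
  expect_identical(lcv$model, "linear")
  expect_equal(lcv$params$slope, 0.02, tolerance = 1e-10)
  expect_equal(lcv$params$intercept, 0.1, tolerance = 1e-10)

  # heavy noise: neither model clears r2 > 0.99
  set.seed(14)
  noisy <- fit_standard_curve(rep(conc, each = 2),
                              rep(od, each = 2) * runif(14, 0.3, 1.7))
  expect_false(noisy$r2_pass)
})

test_that("interpolation inverts the curve and scales with dilution", {
  conc <- 4000 / 2^(0:6)
  od <- fivepl(conc, true5pl$a, true5pl$d, true5pl$c, true5pl$b, true5pl$g)
  cv <- fit_standard_curve(rep(conc, each = 2), rep(od, each = 2))
  # loop closure: each standard's OD maps back to its concentration
  back <- interpolate_conc(cv, od, 1)
  expect_equal(back$conc, conc, tolerance = 1e-3)
  # dilution factor scales linearly
  one <- interpolate_conc(cv, od[3], 1)$conc
  hundred <- interpolate_conc(cv, od[3], 100)$conc
  expect_equal(hundred, 100 * one, tolerance = 1e-12)
  # inflection of a symmetric curve maps to c
  sym <- structure(list(model = "5pl",
                        params = list(a = 0, d = 2, c = 300, b = 1, g = 1),
                        r2 = 1, r2_5pl = 1, r2_linear = 0.5, r2_pass = TRUE,
                        range = c(1, 4000)), class = "calibration_curve")
  expect_equal(interpolate_conc(sym, 1, 1)$conc, 300, tolerance = 1e-9)
  expect_equal(interpolate_conc(sym, 1, 35)$conc, 300 * 35, tolerance = 1e-6)
  # out-of-range ODs are flagged
  expect_identical(interpolate_conc(sym, 2.5, 1)$flag, "non_invertible")
  expect_identical(interpolate_conc(sym, 1.999999, 1)$flag, "above_range")
})

test_that("limits of blank and detection follow the CLSI formulas", {
  blanks <- c(0.08, 0.10, 0.12)                 # mean 0.1, sd 0.02
  lows <- c(0.27, 0.30, 0.33)                   # sd 0.03
  dl <- detection_limits(blanks, lows)
  expect_equal(dl$lob, 0.1 + 1.645 * 0.02, tolerance = 1e-12)  # 0.1329
  expect_equal(dl$lod, dl$lob + 1.645 * 0.03, tolerance = 1e-12)  # 0.18225
  expect_gte(dl$lod, dl$lob)
  # zero blank spread: LoB = mean blank
  expect_equal(detection_limits(c(0.1, 0.1), lows)$lob, 0.1)
  # shift equivariance under a constant OD offset
  dl2 <- detection_limits(blanks + 0.5, lows + 0.5)
  expect_equal(dl2$lob, dl$lob + 0.5, tolerance = 1e-12)
  expect_equal(dl2$lod, dl$lod + 0.5, tolerance = 1e-12)
})

test_that("duplicate CV follows sd/mean and flags singletons", {
  plate <- data.frame(role = "sample",
                      sample_id = c("A", "A", "B", "B", "C"),
                      od = c(1, 1, 90, 110, 2))
  qc <- qc_cv(plate)
  expect_equal(qc$per_sample$cv[qc$per_sample$sample_id == "A"], 0)
  expect_equal(qc$per_sample$cv[qc$per_sample$sample_id == "B"],
               sqrt(200) / 100, tolerance = 1e-12)        # ~0.1414
  expect_identical(qc$per_sample$flag[qc$per_sample$sample_id == "C"],
                   "single_replicate")
  expect_equal(qc$mean_cv, mean(c(0, sqrt(200) / 100)))
})

test_that("synthetic plates honour the noise and replicate contracts", {
  concs <- setNames(c(500, 120, 0), c("X1", "X2", "X0"))
  plate <- generate_elisa_plate(sample_concs = concs, cv = 0,
                                dilutions = c(2, 1, 1), rng_seed = 5)
  smp <- plate[plate$role == "sample", ]
  expect_true(all(table(smp$sample_id) == 2))
  # cv = 0: duplicates identical
  expect_equal(qc_cv(plate)$mean_cv, 0)
  # concentration-zero sample reads the lower asymptote
  expect_equal(unique(smp$od[smp$sample_id == "X0"]), 0.05)
  # blanks at the lower asymptote
  expect_equal(unique(plate$od[plate$role == "blank"]), 0.05)
  # reproducible
  plate2 <- generate_elisa_plate(sample_concs = concs, cv = 0,
                                 dilutions = c(2, 1, 1), rng_seed = 5)
  expect_identical(plate, plate2)
  # generator CV calibration; the two-replicate sd underestimates sigma by
  # the known factor c4(2) = sqrt(2/pi), so compare after de-biasing
  cvs <- vapply(1:8, function(s) {
    p <- generate_elisa_plate(sample_concs = setNames(runif(24, 50, 2000),
                                                      paste0("S", 1:24)),
                              cv = 0.085, rng_seed = s)
    qc_cv(p)$mean_cv
  }, numeric(1))
  expect_lt(abs(mean(cvs) / sqrt(2 / pi) - 0.085), 0.02)
})

test_that("group comparisons are gated by Shapiro normality", {
  set.seed(15)
  x <- rnorm(20, 10, 1)
  y <- rnorm(20, 11, 1)
  g <- compare_groups(x, y)
  expect_identical(g$test, "t")
  expect_true(all(g$shapiro_p >= 0.05))

  skewed <- exp(rnorm(20, 0, 1.5))
  g2 <- compare_groups(skewed, y)
  expect_identical(g2$test, "mann-whitney")

  # exact small-sample Mann-Whitney: {1,2,3} vs {4,5,6}.  Oracle: enumerate
  # all choose(6,3) = 20 assignments of the ranks to group 1 and count
  # rank sums at least as extreme (two-sided) as the observed one.
  ranks <- 1:6
  obs <- sum(1:3)
  sums <- combn(ranks, 3, sum)
  p_oracle <- mean(abs(sums - mean(ranks) * 3) >= abs(obs - mean(ranks) * 3))
  expect_equal(p_oracle, 0.1)
  g3 <- compare_groups(c(1, 2, 3), c(4, 5, 6), shapiro_alpha = 1.1)
  expect_identical(g3$test, "mann-whitney")
  expect_equal(g3$p.value, p_oracle, tolerance = 1e-12)

  # constant group: Shapiro undefined -> Mann-Whitney fallback
  g4 <- compare_groups(c(5, 5, 5), c(5, 5, 5))
  expect_identical(g4$test, "mann-whitney")
  expect_equal(g4$p.value, 1)
})
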