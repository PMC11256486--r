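## ELISA plate reduction: 5PL / linear standard curves chosen by r^2,
## interpolation with dilution factors, limit of blank / detection, duplicate
## CV quality control, and Shapiro-gated two-group comparisons.

#' Five-parameter logistic response
#'
#' OD = d + (a - d) / (1 + (x / c)^b)^g with `a` the zero-concentration
#' asymptote, `d` the infinite-concentration asymptote, `c` the inflection
#' concentration, `b` the slope and `g` the asymmetry (g = 1 is the
#' symmetric 4PL).
#'
#' @param x concentration (>= 0).
#' @param a,d,c,b,g curve parameters.
#' @return optical density.
#' @export
fivepl <- function(x, a, d, c, b, g = 1) {
  d + (a - d) / (1 + (x / c)^b)^g
}

#' Invert a five-parameter logistic
#'
#' @param od optical density strictly between the asymptotes.
#' @inheritParams fivepl
#' @return concentration; NA outside the invertible range.
#' @export
fivepl_inverse <- function(od, a, d, c, b, g = 1) {
  frac <- (a - d) / (od - d)
  out <- rep(NA_real_, length(od))
  ok <- is.finite(frac) & frac > 1       # od strictly between a and d
  out[ok] <- c * (frac[ok]^(1 / g) - 1)^(1 / b)
  out[is.finite(od) & od == a] <- 0
  out
}

#' Fit a standard curve, choosing 5PL or linear by r^2
#'
#' Fits both a 5PL (Levenberg-Marquardt least squares on OD versus
#' concentration) and a simple linear regression to the standards and
#' returns the model with the higher coefficient of determination; both
#' r^2 values are reported, and `r2_pass` flags whether the chosen model
#' clears the acceptance rule r^2 > 0.99.  5PL non-convergence falls back
#' to the linear model with a warning.
#'
#' @param conc standard concentrations (> 0; at least 5 points for the 5PL
#'   to be attempted).
#' @param od optical densities.
#' @return a `calibration_curve` list: `model` ("5pl" or "linear"),
#'   `params`, `r2`, `r2_5pl`, `r2_linear`, `r2_pass`, `range` (lowest and
#'   highest standard concentration).
#' @export
fit_standard_curve <- function(conc, od) {
  stopifnot(length(conc) == length(od), all(conc > 0), length(conc) >= 4)
  sstot <- sum((od - mean(od))^2)
  r2_of <- function(fitted) 1 - sum((od - fitted)^2) / sstot
  lin <- lm(od ~ conc)
  r2_linear <- r2_of(fitted(lin))
  fit5 <- NULL
  r2_5pl <- NA_real_
  if (length(unique(conc)) >= 5) {
    increasing <- coef(lin)[["conc"]] >= 0
    start <- list(a = if (increasing) min(od) else max(od),
                  d = if (increasing) max(od) else min(od),
                  c = exp(mean(log(range(conc)))), b = 1, g = 1)
    fit5 <- tryCatch(
      minpack.lm::nlsLM(od ~ d + (a - d) / (1 + (conc / c)^b)^g,
                        start = start,
                        lower = c(a = -Inf, d = -Inf, c = 1e-12, b = 1e-3,
                                  g = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit5)) r2_5pl <- r2_of(fitted(fit5))
  }
  if (is.null(fit5) && length(unique(conc)) >= 5)
    warning("5PL fit did not converge; falling back to linear model")
  use5 <- !is.null(fit5) && (is.na(r2_linear) || r2_5pl >= r2_linear)
  model <- if (use5) "5pl" else "linear"
  params <- if (use5) as.list(coef(fit5))
            else list(intercept = unname(coef(lin)[1]),
                      slope = unname(coef(lin)[2]))
  r2 <- if (use5) r2_5pl else r2_linear
  structure(list(model = model, params = params, r2 = r2,
                 r2_5pl = r2_5pl, r2_linear = r2_linear,
                 r2_pass = is.finite(r2) && r2 > 0.99,
                 range = range(conc)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: %s, r2 = %.5f (5PL %.5f / linear %.5f)%s\n",
              x$model, x$r2,
              ifelse(is.na(x$r2_5pl), NaN, x$r2_5pl), x$r2_linear,
              if (x$r2_pass) "" else "  [FAILS r2 > 0.99]"))
  invisible(x)
}

#' Interpolate sample concentrations from a standard curve
#'
#' Inverts the calibration curve at each OD and multiplies by the dilution
#' factor.  ODs outside the curve's invertible range are flagged
#' (`"non_invertible"` for a 5PL OD beyond the asymptotes) and
#' concentrations outside the standard range are flagged
#' (`"below_range"` / `"above_range"`).
#'
#' @param curve a `calibration_curve`.
#' @param od optical densities.
#' @param dilution_factor dilution factor(s), recycled (default 1).
#' @return data.frame with `od`, `conc` (back-diluted), `flag`.
#' @export
interpolate_conc <- function(curve, od, dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  neat <- if (curve$model == "5pl") {
    do.call(fivepl_inverse, c(list(od = od), curve$params))
  } else {
    (od - curve$params$intercept) / curve$params$slope
  }
  flag <- rep("ok", length(od))
  flag[is.na(neat)] <- "non_invertible"
  flag[!is.na(neat) & neat < curve$range[1]] <- "below_range"
  flag[!is.na(neat) & neat > curve$range[2]] <- "above_range"
  data.frame(od = od, conc = neat * dilution_factor, flag = flag,
             stringsAsFactors = FALSE)
}

#' Limit of blank and limit of detection
#'
#' CLSI-style limits on the OD scale:
#' LoB = mean(blank) + 1.645 sd(blank);
#' LoD = LoB + 1.645 sd(lowest-concentration standard).
#' Sample ODs at or below the LoD should be dismissed and the sample
#' re-assayed concentrated.
#'
#' @param blank_ods replicate blank ODs (>= 2).
#' @param lowest_standard_ods replicate ODs of the lowest standard (>= 2).
#' @return a `detection_limits` list: `lob`, `lod`, `mean_blank`,
#'   `sd_blank`, `sd_lowest_standard`.
#' @export
detection_limits <- function(blank_ods, lowest_standard_ods) {
  stopifnot(length(blank_ods) >= 2, length(lowest_standard_ods) >= 2)
  lob <- mean(blank_ods) + 1.645 * sd(blank_ods)
  lod <- lob + 1.645 * sd(lowest_standard_ods)
  structure(list(lob = lob, lod = lod,
                 mean_blank = mean(blank_ods), sd_blank = sd(blank_ods),
                 sd_lowest_standard = sd(lowest_standard_ods)),
            class = "detection_limits")
}

#' Duplicate coefficient of variation QC
#'
#' CV = sd / mean over a sample's replicate ODs; the plate summary is the
#' mean CV across samples.  Samples with a single replicate get NA and a
#' flag.
#'
#' @param plate ELISA plate data.frame (see [generate_elisa_plate()]) with
#'   columns `sample_id`, `role`, `od`.
#' @return list with per-sample data.frame (`sample_id`, `n`, `cv`,
#'   `flag`) and `mean_cv`.
#' @export
qc_cv <- function(plate) {
  wells <- plate[plate$role == "sample", ]
  by_sample <- split(wells$od, wells$sample_id)
  cv <- vapply(by_sample, function(v) {
    if (length(v) < 2) NA_real_ else sd(v) / mean(v)
  }, numeric(1))
  per <- data.frame(sample_id = names(by_sample),
                    n = lengths(by_sample),
                    cv = unname(cv),
                    flag = ifelse(is.na(cv), "single_replicate", "ok"),
                    stringsAsFactors = FALSE)
  list(per_sample = per, mean_cv = mean(cv, na.rm = TRUE))
}

#' Shapiro-gated two-group comparison
#'
#' Each group is tested for normality with the Shapiro-Wilk test at the
#' 0.05 level; if either group rejects (or the test is undefined, e.g. a
#' constant group), the two-sided Mann-Whitney test is used (exact for
#' small tie-free samples, normal approximation with continuity correction
#' otherwise); otherwise the two-sided Student's t-test (pooled variance).
#'
#' @param x,y numeric vectors of analyte levels for the two groups (>= 3
#'   each).
#' @param shapiro_alpha normality gate level (default 0.05).
#' @return list: `test` ("mann-whitney" or "t"), `statistic`, `p.value`,
#'   `shapiro_p` (per group).
#' @export
compare_groups <- function(x, y, shapiro_alpha = 0.05) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  shap <- vapply(list(x, y), function(v) {
    tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
  }, numeric(1))
  normal <- all(shap >= shapiro_alpha)
  if (normal) {
    tt <- t.test(x, y, var.equal = TRUE)
    list(test = "t", statistic = unname(tt$statistic),
         p.value = tt$p.value, shapiro_p = shap)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
    p <- wt$p.value
    if (is.nan(p)) p <- 1          # complete-tie degeneracy: no evidence
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         p.value = p, shapiro_p = shap)
  }
}
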