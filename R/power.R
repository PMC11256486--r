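## FDR-controlled power and sample size for the two-sample comparison, plus
## Storey-style estimation of the null proportion pi0.

#' Estimate the proportion of true nulls (pi0) from p-values
#'
#' Storey's smoother: pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) is
#' evaluated on a lambda grid, a natural cubic smoothing spline with 3
#' degrees of freedom is fitted, and the estimate is the spline value at
#' the largest lambda, clipped into (0, 1].
#'
#' @param p vector of p-values (warns below 100, where the smoother is
#'   unstable).
#' @param lambda evaluation grid (default `seq(0.05, 0.95, 0.05)`).
#' @return pi0 estimate in (0, 1].
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (length(p) < 100)
    warning("fewer than 100 p-values; pi0 estimate is unstable")
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fitted <- if (length(lambda) >= 4) {
    sp <- smooth.spline(lambda, pi0_l, df = 3)
    predict(sp, x = max(lambda))$y
  } else {
    pi0_l[which.max(lambda)]
  }
  min(max(fitted, 1 / m), 1)
}

#' Two-sided power of the two-sample t-test at a given alpha
#'
#' @param alpha per-comparison significance level.
#' @param df degrees of freedom, `2(n-1)` for equal groups of n.
#' @param ncp noncentrality, `delta / (sigma * sqrt(2/n))`.
#' @return rejection probability under the noncentral t alternative.
#' @export
t_test_power <- function(alpha, df, ncp) {
  tc <- qt(1 - alpha / 2, df)
  # suppressed: noncentral pt warns about its last-digit precision, far
  # below the bisection tolerance used on alpha
  suppressWarnings(pt(-tc, df, ncp = ncp) + 1 - pt(tc, df, ncp = ncp))
}

#' FDR-controlled average power for a two-sample design
#'
#' Solves, by bisection, for the per-comparison level alpha_c at which
#' declaring all p <= alpha_c significant yields the target false discovery
#' rate among a mixture of pi0 true nulls and 1 - pi0 alternatives of
#' effect size delta:
#'
#'   pi0 * alpha_c / ((1 - pi0) * P(alpha_c)) = fdr / (1 - fdr),
#'
#' where P(alpha) is the two-sided noncentral-t power with df = 2(n - 1)
#' and ncp = delta / (sigma * sqrt(2/n)).  Equivalently the fixed point
#' targets realized FDR FP/(FP+TP) = fdr.  Returns the achieved average
#' power P(alpha_c).  Equal per-group sizes are assumed (a study with
#' unequal groups is summarised by its smaller group).
#'
#' @param n per-group sample size (>= 2).
#' @param delta effect size on the log2 scale (study value 0.68).
#' @param sigma common standard deviation (study value 0.4375).
#' @param pi0 proportion of true nulls (study value 0.66).
#' @param fdr target false discovery rate (study value 0.1).
#' @param tol bisection tolerance on alpha (default 1e-10).
#' @return a `power_result` list: `power`, `alpha_c`, `df`, `ncp`, plus the
#'   inputs; when no alpha in the bracket satisfies the constraint, power 0
#'   with a diagnostic message field.
#' @export
fdr_power <- function(n, delta = 0.68, sigma = 0.4375, pi0 = 0.66,
                      fdr = 0.1, tol = 1e-10) {
  stopifnot(n >= 2, sigma > 0, pi0 > 0, pi0 < 1, fdr > 0, fdr < 1,
            delta >= 0)
  df <- 2 * (n - 1)
  ncp <- delta / (sigma * sqrt(2 / n))
  target <- fdr / (1 - fdr)
  g <- function(a) pi0 * a / ((1 - pi0) * t_test_power(a, df, ncp)) - target
  lo <- 1e-12
  hi <- 0.5
  res <- list(n = n, delta = delta, sigma = sigma, pi0 = pi0, fdr = fdr,
              df = df, ncp = ncp)
  if (g(lo) > 0) {
    res$power <- 0
    res$alpha_c <- NA_real_
    res$note <- "no per-comparison level in (0, 0.5] satisfies the FDR constraint (pi0 too high for this target)"
    return(structure(res, class = "power_result"))
  }
  if (g(hi) < 0) {
    alpha <- hi          # constraint still slack at the bracket edge
  } else {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    alpha <- (lo + hi) / 2
  }
  res$alpha_c <- alpha
  res$power <- t_test_power(alpha, df, ncp)
  structure(res, class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("FDR-controlled power: n=%d/group, delta=%.3g, sigma=%.4g, pi0=%.2f, FDR=%.2g\n",
              x$n, x$delta, x$sigma, x$pi0, x$fdr))
  cat(sprintf("  alpha_c = %.5g, power = %.4f (df=%d, ncp=%.3f)\n",
              x$alpha_c, x$power, x$df, x$ncp))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Smallest per-group sample size reaching a target power
#'
#' Integer search over n using [fdr_power()]; power is increasing in n, so
#' the first n meeting the target is returned.
#'
#' @param target_power required average power, in (0, 1).
#' @param n_max search cap (error when even `n_max` falls short).
#' @inheritParams fdr_power
#' @return smallest integer n with power >= `target_power`.
#' @export
min_n_for_power <- function(target_power, delta = 0.68, sigma = 0.4375,
                            pi0 = 0.66, fdr = 0.1, n_max = 1000) {
  stopifnot(target_power > 0, target_power < 1)
  for (n in 2:n_max) {
    if (fdr_power(n, delta, sigma, pi0, fdr)$power >= target_power)
      return(n)
  }
  stop("no n <= ", n_max, " reaches power ", target_power, call. = FALSE)
}
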