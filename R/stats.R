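## The statistical decision tree used throughout the group comparisons:
## Shapiro-Wilk normality on each group; if both normal, an F-test for
## equal variance routes to a Student or Welch t-test; any non-normal
## group routes to a Mann-Whitney test. All tests two-sided at alpha 0.05.
## ROUT robust outlier removal (constant-only model) is available ahead of
## the comparison.

#' Run the test-selection decision tree on two samples
#'
#' @param x,y numeric samples (n >= 3 each).
#' @param alpha significance level for the gates and the test (0.05).
#' @param outliers "none" (default) or "rout": remove ROUT-flagged points
#'   from each sample before testing.
#' @param rout_q ROUT false-discovery rate (default 0.001, i.e. Q = 0.1%).
#' @return An object of class \code{test_report}: list with
#'   \code{test_used} ("student_t", "welch_t" or "mann_whitney"),
#'   \code{normality_p} (per group), \code{variance_p}, \code{statistic},
#'   \code{p_value}, \code{significant}, \code{outliers_flagged} (list of
#'   flagged indices per group) and \code{alpha}.
#' @export
choose_and_run <- function(x, y, alpha = 0.05, outliers = c("none", "rout"),
                           rout_q = 0.001) {
  outliers <- match.arg(outliers)
  if (length(x) < 3L || length(y) < 3L)
    stop_input("each group needs at least 3 observations")
  flagged <- list(x = integer(0), y = integer(0))
  if (outliers == "rout") {
    if (length(x) >= 5L) flagged$x <- which(rout_outliers(x, rout_q))
    if (length(y) >= 5L) flagged$y <- which(rout_outliers(y, rout_q))
    if (length(flagged$x)) x <- x[-flagged$x]
    if (length(flagged$y)) y <- y[-flagged$y]
    if (length(x) < 3L || length(y) < 3L)
      stop_input("fewer than 3 observations remain after outlier removal")
  }
  swx <- stats::shapiro.test(x)$p.value
  swy <- stats::shapiro.test(y)$p.value
  variance_p <- NA_real_
  if (swx > alpha && swy > alpha) {
    variance_p <- stats::var.test(x, y)$p.value
    if (variance_p > alpha) {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      used <- "student_t"
    } else {
      ht <- stats::t.test(x, y)
      used <- "welch_t"
    }
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    used <- "mann_whitney"
  }
  structure(list(test_used = used,
                 normality_p = c(x = swx, y = swy),
                 variance_p = variance_p,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 significant = ht$p.value < alpha,
                 outliers_flagged = flagged,
                 alpha = alpha),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("test_report: %s, p = %.4g (%ssignificant at alpha %.2g)\n",
              x$test_used, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  cat(sprintf("  normality p: x %.3g, y %.3g; variance p: %.3g\n",
              x$normality_p[["x"]], x$normality_p[["y"]], x$variance_p))
  invisible(x)
}

#' ROUT outlier flags for a single sample
#'
#' Robust-regression-and-outlier-removal applied to the constant-only
#' model: robust location is the median; robust scale (RSDR) is the
#' 68.27th percentile of the absolute residuals with the small-sample
#' correction n / (n - 1); residual t-scores (df = n - 1) are tested
#' largest-first by Benjamini-Hochberg FDR at rate Q. Flags are invariant
#' to permutations of the sample.
#'
#' @param x numeric sample (n >= 5).
#' @param q false-discovery rate (default 0.001 = 0.1%).
#' @return logical vector of flags in the original order.
#' @export
rout_outliers <- function(x, q = 0.001) {
  n <- length(x)
  if (n < 5L) stop_input("ROUT needs at least 5 observations")
  r <- x - stats::median(x)
  ar <- abs(r)
  rsdr <- stats::quantile(ar, 0.6827, names = FALSE) * n / (n - 1L)
  if (rsdr == 0) return(ar > 0)
  tt <- ar / rsdr
  p <- 2 * stats::pt(tt, df = n - 1L, lower.tail = FALSE)
  stats::p.adjust(p, method = "BH") <= q
}

#' Type-I error and power of the decision tree
#'
#' Simulation harness: draws paired samples (null and effect-shifted),
#' runs the full decision tree on each, and reports the rejection rates
#' at alpha 0.05. Gaussian noise by default; exponential noise exercises
#' the Mann-Whitney branch.
#'
#' @param effect mean shift in units of the noise scale.
#' @param n per-group sample size.
#' @param reps number of simulation replicates (>= 100).
#' @param seed RNG seed.
#' @param dist "gaussian" or "exponential".
#' @param alpha level (default 0.05).
#' @return list with \code{type_I_error}, \code{power}, \code{reps},
#'   \code{routing} (table of tests chosen under the null).
#' @export
typeI_power_suite <- function(effect, n, reps = 1000L, seed = 1L,
                              dist = c("gaussian", "exponential"),
                              alpha = 0.05) {
  dist <- match.arg(dist)
  if (reps < 100L) stop_input("reps must be >= 100")
  with_seed(seed, {
    draw <- function() switch(dist,
                              gaussian = stats::rnorm(n),
                              exponential = stats::rexp(n) - 1)
    rej0 <- logical(reps); rej1 <- logical(reps)
    routing <- character(reps)
    for (r in seq_len(reps)) {
      rep0 <- choose_and_run(draw(), draw(), alpha = alpha)
      rej0[r] <- rep0$p_value < alpha
      routing[r] <- rep0$test_used
      if (effect != 0) {
        rep1 <- choose_and_run(draw(), draw() + effect, alpha = alpha)
        rej1[r] <- rep1$p_value < alpha
      }
    }
    list(type_I_error = mean(rej0),
         power = if (effect != 0) mean(rej1) else NA_real_,
         reps = reps,
         routing = table(routing))
  })
}
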