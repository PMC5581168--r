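#' Stratified selection of validation beats from an RR series
#'
#' Randomly selects one beat from each of three RR strata: below the 10th
#' percentile, above the 90th percentile, and within the interquartile range
#' (inclusive bounds). Percentiles use linear interpolation between order
#' statistics (R quantile type 7). The draw is seeded and deterministic.
#'
#' @param rr_series numeric vector of RR intervals in ms, one per beat
#'   (length >= 10).
#' @param seed integer seed for the draw.
#' @return named integer vector of beat indices (`low`, `iqr`, `high`).
#' @export
select_validation_beats <- function(rr_series, seed) {
  if (length(rr_series) < 10L) stop("need at least 10 beats")
  qs <- stats::quantile(rr_series, c(0.10, 0.25, 0.75, 0.90),
                        names = FALSE, type = 7)
  strata <- list(low = which(rr_series < qs[1L]),
                 iqr = which(rr_series >= qs[2L] & rr_series <= qs[3L]),
                 high = which(rr_series > qs[4L]))
  for (nm in names(strata))
    if (!length(strata[[nm]]))
      stop(sprintf("empty RR stratum '%s'", nm))
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  vapply(strata, function(ix) ix[sample.int(length(ix), 1L)], integer(1L))[
    c("low", "iqr", "high")]
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences `d = x - y`; bias is their mean, limits of agreement are
#' `bias +/- 1.96 * sample SD(d)`.
#'
#' @param x,y paired measurements (ms), equal length, n >= 2.
#' @return list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = n)
}

#' Pearson correlation with a Fisher-transform confidence interval
#'
#' @param x,y paired measurements, equal length, n >= 3, both with nonzero
#'   variance.
#' @param alpha two-sided significance level (default 0.05).
#' @return list with `r`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_ci <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - alpha / 2)
  list(r = r, ci_low = tanh(z - q * se), ci_high = tanh(z + q * se), n = n)
}

#' Two-way mixed absolute-agreement intraclass correlation
#'
#' ICC for a complete subjects-by-raters matrix under the two-way mixed
#' model with absolute agreement (McGraw & Wong A-1 and A-k): single-measure
#' and average-measure coefficients from the two-way mean-squares
#' decomposition, with F-based confidence bounds.
#'
#' @param m numeric matrix, n subjects x k raters, complete (no missing
#'   cells), n >= 2, k >= 2.
#' @param alpha two-sided significance level (default 0.05).
#' @return list with `icc_single`, `icc_average`, their confidence bounds
#'   (`single_ci`, `average_ci`), and the mean squares (`msr`, `msc`, `mse`).
#' @export
icc_agreement <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not allowed (no imputation)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)          # rows (subjects)
  msc <- n * sum((colm - grand)^2) / (k - 1)          # columns (raters)
  sse <- sum((m - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))                    # residual
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  # confidence bounds for A-1 (Satterthwaite df), transformed for A-k
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  step_up <- function(r) k * r / (1 + (k - 1) * r)
  list(icc_single = icc1, icc_average = icck,
       single_ci = c(lo1, hi1),
       average_ci = c(step_up(lo1), step_up(hi1)),
       msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Full method-agreement report for two paired QT series
#'
#' Bundles the Pearson correlation (with Fisher CI), the two-way mixed
#' absolute-agreement ICC of the n x 2 matrix, and the Bland-Altman bias and
#' limits of agreement.
#'
#' @param x,y paired QT measurements in ms.
#' @param alpha significance level for the confidence intervals.
#' @return list of class `agreement_report`.
#' @export
agreement_report <- function(x, y, alpha = 0.05) {
  p <- pearson_ci(x, y, alpha)
  icc <- icc_agreement(cbind(x, y), alpha)
  ba <- bland_altman(x, y)
  structure(list(pearson = p, icc = icc, bland_altman = ba,
                 n = length(x)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs\n", x$n))
  cat(sprintf("  Pearson r      %.3f (95%% CI %.3f-%.3f)\n",
              x$pearson$r, x$pearson$ci_low, x$pearson$ci_high))
  cat(sprintf("  ICC single     %.3f (95%% CI %.3f-%.3f)\n",
              x$icc$icc_single, x$icc$single_ci[1], x$icc$single_ci[2]))
  cat(sprintf("  ICC average    %.3f (95%% CI %.3f-%.3f)\n",
              x$icc$icc_average, x$icc$average_ci[1], x$icc$average_ci[2]))
  cat(sprintf("  Bias           %.2f ms\n", x$bland_altman$bias))
  cat(sprintf("  LoA            %.2f to %.2f ms\n",
              x$bland_altman$loa_low, x$bland_altman$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of pairwise means against differences with the bias and the
#' limits of agreement drawn as horizontal lines.
#'
#' @inheritParams bland_altman
#' @param main plot title.
#' @return the [bland_altman] summary, invisibly.
#' @export
plot_bland_altman <- function(x, y, main = "Bland-Altman") {
  ba <- bland_altman(x, y)
  graphics::plot((x + y) / 2, x - y, pch = 16, cex = 0.6,
                 xlab = "Mean of methods (ms)",
                 ylab = "Difference (ms)", main = main)
  graphics::abline(h = ba$bias, lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}
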