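# Agreement statistics for comparing two Ki-67 examination series:
# Spearman's rank correlation (average ranks for ties, large-sample t
# approximation for the p-value) and Bland-Altman analysis on linear or
# logarithmic scale.

#' Spearman's rank correlation between two Ki-67 series
#'
#' Rank correlation using average ranks for ties; the p-value comes from
#' the large-sample t approximation with n - 2 degrees of freedom.
#' Invariant under strictly monotone transforms of either series.
#'
#' @param a,b numeric vectors of equal length >= 3; neither may be
#'   constant.
#' @return list with \code{rho} and \code{pValue}.
#' @examples
#' spearmanRho(1:10, (1:10)^2)  # rho = 1
#' @export
spearmanRho <- function(a, b) {
  if (length(a) != length(b))
    stop("series must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 3L) stop("need at least 3 paired cases", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant series: rank correlation undefined", call. = FALSE)
  rho <- stats::cor(rank(a), rank(b))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, pValue = p)
}

#' Bland-Altman agreement analysis
#'
#' Per-case differences (a - b) against per-case means ((a + b)/2) on the
#' chosen scale, with the mean difference and mean +/- 1.96 SD limits of
#' agreement. The log scale uses base-10 logarithms of (value +
#' \code{logOffset}) so that Ki-67 = 0 cases remain usable; Spearman's rho
#' of the raw series is included in the report.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @param scale \code{"linear"} (default) or \code{"log"}.
#' @param logOffset offset added before taking logs (default 0.1).
#' @return an \linkS4class{AgreementReport}.
#' @examples
#' r <- blandAltman(c(10, 20, 30, 5), c(11, 19, 33, 5))
#' r@meanDifference
#' @export
blandAltman <- function(a, b, scale = c("linear", "log"), logOffset = 0.1) {
  scale <- match.arg(scale)
  if (length(a) != length(b))
    stop("series must have equal length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 paired cases", call. = FALSE)
  sp <- spearmanRho(a, b)
  if (scale == "log") {
    if (any(a + logOffset <= 0) || any(b + logOffset <= 0))
      stop("log scale requires value + offset > 0 for all cases",
           call. = FALSE)
    a <- log10(a + logOffset)
    b <- log10(b + logOffset)
  }
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  if (is.na(sdd)) sdd <- 0
  new("AgreementReport", spearmanRho = sp$rho, pValue = sp$pValue,
      meanDifference = md, loaLower = md - 1.96 * sdd,
      loaUpper = md + 1.96 * sdd, differences = d, means = m,
      scale = scale)
}

#' Bland-Altman plot of an agreement report
#'
#' Differences against means with the mean-difference line (solid) and the
#' 1.96 SD limits of agreement (dashed), on the report's scale.
#'
#' @param report an \linkS4class{AgreementReport}.
#' @param main plot title.
#' @return invisibly, the report.
#' @export
plotBlandAltman <- function(report, main = "Bland-Altman agreement") {
  xlab <- if (report@scale == "log") "mean of log10 Ki-67 (%)" else
    "mean Ki-67 (%)"
  ylab <- if (report@scale == "log") "difference of log10 Ki-67" else
    "difference of Ki-67 (%)"
  graphics::plot(report@means, report@differences, pch = 19,
                 xlab = xlab, ylab = ylab, main = main,
                 ylim = range(c(report@differences, report@loaLower,
                                report@loaUpper)))
  graphics::abline(h = report@meanDifference, lty = 1)
  graphics::abline(h = c(report@loaLower, report@loaUpper), lty = 2)
  invisible(report)
}

#' Compare two Ki-67 series from a CSV file
#'
#' Reads columns \code{ki67_a} and \code{ki67_b} (plus optional
#' \code{case_id}) and produces linear- and log-scale agreement reports.
#'
#' @param path CSV file path.
#' @return list with \code{linear} and \code{log}
#'   \linkS4class{AgreementReport}s.
#' @export
compareKi67Series <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("ki67_a", "ki67_b") %in% names(df)))
    stop("CSV must contain columns ki67_a and ki67_b", call. = FALSE)
  list(linear = blandAltman(df$ki67_a, df$ki67_b, "linear"),
       log = blandAltman(df$ki67_a, df$ki67_b, "log"))
}
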