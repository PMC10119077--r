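# Test-retest reproducibility (bias, variability) and reliability (ICC)
# of regional outcome measures, plus cross-method DVR regression.

#' Test-retest bias
#'
#' Per-subject percent change `(retest - test) / test * 100` and its mean.
#'
#' @param test,retest Per-subject outcome values (e.g. DVR); equal length,
#'   `test` strictly positive.
#' @return List with `per_subject` (percent) and `mean` (percent).
#' @export
trt_bias <- function(test, retest) {
  if (length(test) != length(retest)) stop("test/retest lengths differ")
  if (length(test) < 1) stop("need at least one subject")
  if (any(test <= 0)) stop("test values must be positive")
  b <- (retest - test) / test * 100
  list(per_subject = b, mean = mean(b))
}

#' Test-retest variability
#'
#' The sample standard deviation (n - 1 denominator) of the per-subject
#' biases, in percent.
#'
#' @param biases Per-subject biases (percent), length >= 2.
#' @export
trt_variability <- function(biases) {
  if (length(biases) < 2) stop("variability needs at least 2 subjects")
  stats::sd(biases)
}

#' Intraclass correlation coefficient for a two-session design
#'
#' One-way ANOVA decomposition with k = 2 sessions per subject:
#' `BSMSS = k * sum((subject mean - grand mean)^2) / (n - 1)`,
#' `WSMSS = sum((value - subject mean)^2) / (n * (k - 1))`,
#' `ICC = (BSMSS - WSMSS) / (BSMSS + WSMSS)`.  Values in [-1, 1];
#' negative estimates are reported as computed.
#'
#' @param test,retest Per-subject values for the two sessions.
#' @return The ICC, with the between- and within-subject mean squares
#'   attached as attributes `bsmss` and `wsmss`.
#' @export
icc <- function(test, retest) {
  if (length(test) != length(retest)) stop("test/retest lengths differ")
  n <- length(test)
  if (n < 2) stop("ICC needs at least 2 subjects")
  m <- (test + retest) / 2
  grand <- mean(c(test, retest))
  bsmss <- 2 * sum((m - grand)^2) / (n - 1)
  wsmss <- sum((test - m)^2 + (retest - m)^2) / n
  if (bsmss + wsmss == 0)
    stop(structure(class = c("petkin_undefined_icc", "error", "condition"),
                   list(message = "ICC undefined: all values identical",
                        call = sys.call())))
  structure((bsmss - wsmss) / (bsmss + wsmss), bsmss = bsmss, wsmss = wsmss)
}

#' Linear regression between two sets of DVR estimates
#'
#' Ordinary least squares of `y` on `x`, used to compare reference-model
#' DVRs against the arterial gold standard across regions or subjects.
#'
#' @param x,y DVR vectors of equal length (>= 3).
#' @return List with `slope`, `intercept` and `r2`.
#' @export
dvr_regression <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 3) stop("regression needs at least 3 points")
  if (stats::var(x) == 0) stop("zero variance in x")
  f <- stats::lm(y ~ x)
  ssr <- sum(stats::resid(f)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(f)[2]),
       intercept = unname(stats::coef(f)[1]),
       r2 = if (sst > 0) 1 - ssr / sst else 1)
}

#' Regional test-retest report
#'
#' Computes, for each region, the mean test and retest outcome, ICC, mean
#' bias and variability.  Biases are computed per subject and then
#' averaged.  Two pooled summaries are attached: `pooled_regional`
#' averages the regional statistics, and `pooled_all` recomputes them on
#' the pooled subject-by-region values (both conventions are defensible
#' for a study-level figure, so both are reported, labelled).
#'
#' @param test,retest Numeric matrices, subjects in rows and regions in
#'   columns (same dimnames).
#' @param method,ref_region Labels carried into the report.
#' @return Object of class `trt_report`: a data frame with one row per
#'   region and columns `region`, `method`, `ref_region`, `dvr_test`,
#'   `dvr_test_sd`, `dvr_retest`, `dvr_retest_sd`, `icc`, `bias`, `var`,
#'   with the pooled summaries as attributes.
#' @export
trt_report <- function(test, retest, method = "LREF", ref_region = "") {
  test <- as.matrix(test); retest <- as.matrix(retest)
  if (!all(dim(test) == dim(retest))) stop("test/retest dimensions differ")
  regions <- colnames(test)
  if (is.null(regions)) regions <- paste0("region", seq_len(ncol(test)))
  # an undefined ICC (all values identical) is reported as NA, not an error
  safe_icc <- function(a, b) tryCatch(as.numeric(icc(a, b)),
                                      petkin_undefined_icc = function(e)
                                        NA_real_)
  one <- function(a, b) {
    bias <- trt_bias(a, b)
    c(dvr_test = mean(a), dvr_test_sd = stats::sd(a),
      dvr_retest = mean(b), dvr_retest_sd = stats::sd(b),
      icc = safe_icc(a, b), bias = bias$mean,
      var = trt_variability(bias$per_subject))
  }
  tab <- t(vapply(seq_along(regions),
                  function(j) one(test[, j], retest[, j]), numeric(7)))
  out <- data.frame(region = regions, method = method,
                    ref_region = ref_region, tab, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  pooled_regional <- colMeans(tab[, c("icc", "bias", "var"), drop = FALSE])
  pooled_all <- {
    a <- as.vector(test); b <- as.vector(retest)
    bias <- trt_bias(a, b)
    c(icc = safe_icc(a, b), bias = bias$mean,
      var = trt_variability(bias$per_subject))
  }
  structure(out, pooled_regional = pooled_regional, pooled_all = pooled_all,
            class = c("trt_report", "data.frame"))
}

#' @export
print.trt_report <- function(x, digits = 3, ...) {
  cat(sprintf("Test-retest report: %s (reference: %s), %d regions\n",
              x$method[1], x$ref_region[1], nrow(x)))
  print.data.frame(x, digits = digits, ...)
  pr <- attr(x, "pooled_regional"); pa <- attr(x, "pooled_all")
  cat(sprintf("pooled (mean of regional): ICC %.3f, bias %.2f%%, VAR %.2f%%\n",
              pr["icc"], pr["bias"], pr["var"]))
  cat(sprintf("pooled (region x subject): ICC %.3f, bias %.2f%%, VAR %.2f%%\n",
              pa["icc"], pa["bias"], pa["var"]))
  invisible(x)
}
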