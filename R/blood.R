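# Arterial blood processing: whole-blood and plasma curves, metabolite
# (parent-fraction) correction, plasma free fraction, and assembly of the
# metabolite- and fp-corrected arterial input function
#   AIF(t) = PPf(t) * fwb * Cwb(t) * fp(t).
# All fractions are dimensionless in [0, 1] in memory; percent appears
# only in file formats.

#' Raw arterial blood dataset
#'
#' Container for manually drawn arterial samples: the whole-blood activity
#' curve, plasma activity on a subset of draws, and the sparse parent
#' fraction (fraction of plasma activity that is intact tracer) and free
#' fraction (fraction of plasma tracer not protein-bound) measurements.
#'
#' @param time_wb,cwb Whole-blood sample times (minutes) and activities
#'   (kBq/mL).
#' @param time_cp,cp Plasma sample times (a subset of `time_wb`) and
#'   activities (kBq/mL); optional.
#' @param time_pf,pf Parent-fraction sample times and fractions in [0,1].
#' @param time_fp,fp Free-fraction sample times and fractions in [0,1].
#' @return Object of class `blood_dataset`.
#' @export
blood_dataset <- function(time_wb, cwb, time_cp = NULL, cp = NULL,
                          time_pf = NULL, pf = NULL,
                          time_fp = NULL, fp = NULL) {
  chk_curve <- function(t, v, what, frac = FALSE) {
    if (is.null(t)) return(invisible())
    if (length(t) != length(v)) stop(what, ": time and value lengths differ")
    if (any(t < 0)) stop(what, ": negative sample time")
    if (is.unsorted(t, strictly = TRUE)) stop(what, ": times must be strictly increasing")
    if (any(!is.finite(v))) stop(what, ": non-finite values")
    if (frac && any(v < 0 | v > 1)) stop(what, ": fractions must lie in [0, 1]")
  }
  chk_curve(time_wb, cwb, "whole blood")
  chk_curve(time_cp, cp, "plasma")
  chk_curve(time_pf, pf, "parent fraction", frac = TRUE)
  chk_curve(time_fp, fp, "free fraction", frac = TRUE)
  structure(list(time_wb = time_wb, cwb = cwb, time_cp = time_cp, cp = cp,
                 time_pf = time_pf, pf = pf, time_fp = time_fp, fp = fp,
                 fwb = NULL),
            class = "blood_dataset")
}

#' @export
print.blood_dataset <- function(x, ...) {
  cat(sprintf("Arterial blood dataset: %d whole-blood, %d plasma, %d parent-fraction, %d fp samples\n",
              length(x$time_wb), length(x$time_cp), length(x$time_pf),
              length(x$time_fp)))
  if (!is.null(x$fwb))
    cat(sprintf("  plasma-to-whole-blood ratio fwb = %.3f\n", x$fwb))
  invisible(x)
}

#' Estimate the plasma-to-whole-blood activity ratio
#'
#' The ratio fwb = Cp/Cwb is computed at every paired sample and averaged;
#' the plasma curve is thereafter defined as `fwb * Cwb(t)`.
#'
#' @param dataset A [blood_dataset()] with plasma samples.
#' @return List with `mean`, `sd` (sample SD) and the per-sample `ratios`.
#' @export
estimate_fwb <- function(dataset) {
  stopifnot(inherits(dataset, "blood_dataset"))
  if (is.null(dataset$time_cp) || length(dataset$time_cp) < 2)
    stop("need at least 2 paired plasma samples to estimate fwb")
  i <- match(dataset$time_cp, dataset$time_wb)
  if (any(is.na(i))) stop("plasma sample times must be a subset of whole-blood times")
  cwb <- dataset$cwb[i]
  cp <- dataset$cp
  # draws taken before tracer appearance carry no ratio information
  blank <- cwb == 0 & cp == 0
  cwb <- cwb[!blank]; cp <- cp[!blank]
  if (length(cwb) < 2)
    stop("need at least 2 paired plasma samples to estimate fwb")
  if (any(cwb <= 0)) stop("non-positive whole-blood activity at a paired sample")
  r <- cp / cwb
  list(mean = mean(r), sd = stats::sd(r), ratios = r)
}

#' Fit the one-exponential plasma parent-fraction model
#'
#' Models the fraction of plasma activity that is unmetabolized tracer as
#' \deqn{PPf(t) = 1 - A_0 (1 - e^{-\ln 2\, t / T})}
#' a monotone decline from 1 towards the plateau `1 - A0` with half-rise
#' time `T` minutes.  Fitted by unweighted least squares with a multi-start
#' grid over `T` in \{1, 5, 10, 30, 60\} min and `A0` in \{0.01, 0.05,
#' 0.2\} (bounds `0 <= A0 <= 1`, `0.1 <= T <= 500`) to avoid local minima
#' in the flat-plateau regime.
#'
#' @param time Sample times in minutes.
#' @param fraction Parent fractions in [0, 1].
#' @return Object of class `parent_fraction_fit` with elements `A0`, `T`,
#'   `ssr`, `n` and logical `plateau_unidentifiable` (set when `A0`
#'   collapses to 0, leaving `T` meaningless).
#' @export
fit_parent_fraction <- function(time, fraction) {
  if (inherits(time, "blood_dataset")) {
    fraction <- time$pf; time <- time$time_pf
  }
  if (length(time) < 3) stop("need at least 3 parent-fraction samples")
  if (length(unique(time)) < 3) stop("parent-fraction sample times must be distinct")
  if (any(fraction < 0 | fraction > 1)) stop("fractions must lie in [0, 1]")
  obj <- function(p) sum((fraction - ppf_model(p[1], p[2], time))^2)
  best <- NULL
  for (T0 in c(1, 5, 10, 30, 60)) for (A00 in c(0.01, 0.05, 0.2)) {
    f <- try(stats::optim(c(A00, T0), obj, method = "L-BFGS-B",
                          lower = c(0, 0.1), upper = c(1, 500)), silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (is.null(best))
    stop("parent-fraction fit failed to converge from every start")
  structure(list(A0 = best$par[1], T = best$par[2], ssr = best$value,
                 n = length(time),
                 plateau_unidentifiable = best$par[1] < 1e-8),
            class = "parent_fraction_fit")
}

ppf_model <- function(A0, T, t) 1 - A0 * (1 - exp(-log(2) * t / T))

#' @export
print.parent_fraction_fit <- function(x, ...) {
  cat(sprintf("One-exponential parent-fraction fit: A0 = %.4f, T = %.3f min (SSR %.3g, n = %d)\n",
              x$A0, x$T, x$ssr, x$n))
  if (x$plateau_unidentifiable)
    cat("  note: A0 ~ 0; half-rise time T is unidentifiable\n")
  invisible(x)
}

#' @export
coef.parent_fraction_fit <- function(object, ...) c(A0 = object$A0, T = object$T)

#' Evaluate a fitted parent-fraction curve
#' @param object A `parent_fraction_fit`.
#' @param times Times in minutes (must be non-negative).
#' @param ... Unused.
#' @export
predict.parent_fraction_fit <- function(object, times, ...) {
  if (any(times < 0)) stop("negative time in parent-fraction evaluation")
  ppf_model(object$A0, object$T, times)
}

#' Build the plasma free-fraction time course
#'
#' The free fraction fp is measured on a handful of samples only.  Two
#' conventions are supported: `"time-varying"` interpolates linearly
#' between samples (constant extrapolation outside the sampled range, the
#' primary analysis), and `"late-mean"` uses a single constant equal to
#' the mean of samples drawn at or after `late_threshold` minutes (early
#' fp measurements of slowly equilibrating tracers are unreliable).
#'
#' @param time,fp Sample times (minutes) and fractions in [0, 1].
#' @param mode `"time-varying"` or `"late-mean"`.
#' @param late_threshold Minutes; samples at `t >= late_threshold` enter
#'   the late mean (default 30).
#' @return A function of time (minutes) with attributes `mode` and
#'   (for late-mean) `value`.
#' @export
build_fp <- function(time, fp, mode = c("time-varying", "late-mean"),
                     late_threshold = 30) {
  mode <- match.arg(mode)
  if (length(time) < 1) stop("need at least one fp sample")
  if (any(fp < 0 | fp > 1)) stop("fp must lie in [0, 1]")
  if (mode == "time-varying") {
    if (length(time) < 2) stop("time-varying fp needs at least 2 samples")
    f <- stats::approxfun(time, fp, rule = 2)
  } else {
    keep <- time >= late_threshold
    if (!any(keep)) stop("no fp samples at or after the late threshold")
    v <- mean(fp[keep])
    f <- function(t) rep(v, length(t))
    attr(f, "value") <- v
  }
  attr(f, "mode") <- mode
  f
}

# Whole-blood interpolant: linear rise from (0, 0) to the first sample,
# piecewise linear across samples, single-exponential tail fitted to the
# last three samples beyond the final draw.
whole_blood_fun <- function(dataset) {
  t <- dataset$time_wb; v <- dataset$cwb
  if (length(t) < 3) stop("need at least 3 whole-blood samples")
  tt <- t; vv <- v
  if (t[1] > 0) { tt <- c(0, t); vv <- c(0, v) }
  core <- stats::approxfun(tt, vv, rule = 2)
  n <- length(t)
  tl <- t[(n - 2):n]; vl <- v[(n - 2):n]
  if (all(vl > 0) && stats::var(log(vl)) > 0) {
    cf <- stats::coef(stats::lm(log(vl) ~ tl))
    k_tail <- max(-cf[2], 1e-6)      # enforce a decaying tail
    a_tail <- v[n]
  } else {
    k_tail <- 1e-6; a_tail <- v[n]
  }
  t_last <- t[n]
  function(x) {
    out <- core(x)
    late <- x > t_last
    if (any(late)) out[late] <- a_tail * exp(-k_tail * (x[late] - t_last))
    pmax(out, 0)
  }
}

#' Assemble the metabolite- and free-fraction-corrected input function
#'
#' Combines the interpolated whole-blood curve, the mean plasma-to-whole-
#' blood ratio, the fitted parent-fraction curve and the free-fraction
#' time course into the arterial input function
#' `AIF(t) = PPf(t) * fwb * Cwb(t) * fp(t)`, clipped at zero, evaluated on
#' a dense time grid.  All components are retained for audit.
#'
#' @param dataset A [blood_dataset()].
#' @param pf_fit A [fit_parent_fraction()] result.
#' @param fp_fun A [build_fp()] function.
#' @param grid Evaluation grid in minutes (strictly increasing, from 0 to
#'   at least the last TAC frame end); see [default_aif_grid()].
#' @param fwb Plasma-to-whole-blood ratio; estimated from `dataset` via
#'   [estimate_fwb()] when `NULL`.
#' @param max_extrapolation Minutes the grid may extend past the last
#'   blood sample before an error is raised (default 30).
#' @return Object of class `input_function` with elements `grid`, `aif`,
#'   and audit components `cwb`, `cp`, `ppf`, `fp`, `fwb`, `fp_mode`.
#' @export
assemble_aif <- function(dataset, pf_fit, fp_fun, grid, fwb = NULL,
                         max_extrapolation = 30) {
  stopifnot(inherits(dataset, "blood_dataset"))
  if (is.unsorted(grid, strictly = TRUE) || any(grid < 0))
    stop("grid must be non-negative and strictly increasing")
  if (max(grid) > max(dataset$time_wb) + max_extrapolation)
    stop("grid extends more than ", max_extrapolation,
         " min past the last blood sample")
  if (is.null(fwb)) fwb <- estimate_fwb(dataset)$mean
  cwb_f <- whole_blood_fun(dataset)
  cwb <- cwb_f(grid)
  ppf <- predict(pf_fit, grid)
  fp <- fp_fun(grid)
  aif <- pmax(ppf * fwb * cwb * fp, 0)
  structure(list(grid = grid, aif = aif, cwb = cwb, cp = fwb * cwb,
                 ppf = ppf, fp = fp, fwb = fwb,
                 fp_mode = attr(fp_fun, "mode")),
            class = "input_function")
}

#' Default dense evaluation grid for input functions
#'
#' Fine spacing over the bolus passage, coarser later: 0.05-min steps to
#' 3 min, 0.25-min to 10 min, 0.5-min steps beyond.
#'
#' @param t_end Grid end in minutes (last frame end of the TAC).
#' @export
default_aif_grid <- function(t_end = 225) {
  g <- c(seq(0, 3, by = 0.05), seq(3.25, 10, by = 0.25),
         seq(10.5, t_end, by = 0.5))
  if (max(g) < t_end) g <- c(g, t_end)
  g
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("Arterial input function on [%g, %g] min (%d points), fwb = %.3f, fp mode: %s\n",
              min(x$grid), max(x$grid), length(x$grid), x$fwb,
              if (is.null(x$fp_mode)) "fixed" else x$fp_mode))
  cat(sprintf("  peak %.2f kBq/mL at %.2f min\n",
              max(x$aif), x$grid[which.max(x$aif)]))
  invisible(x)
}

#' @export
plot.input_function <- function(x, log = "x", ...) {
  keep <- x$grid > 0
  graphics::matplot(x$grid[keep], cbind(x$cwb, x$cp, x$aif)[keep, ],
                    type = "l", lty = 1, log = log,
                    xlab = "time (min)", ylab = "activity (kBq/mL)", ...)
  graphics::legend("topright", c("whole blood", "plasma", "AIF"),
                   col = 1:3, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

# linear interpolation of an input_function onto arbitrary times
interp_input <- function(inp, times, what = "aif") {
  stats::approx(inp$grid, inp[[what]], xout = times, rule = 2)$y
}
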