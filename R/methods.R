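# Shared S3 methods for fitted kinetic models ("kinfit" objects).

#' @export
print.kinfit <- function(x, ...) {
  cat(sprintf("%s fit, region '%s'", x$model, x$region))
  if (!is.null(x$ref_region) && nzchar(x$ref_region))
    cat(sprintf(" (reference: %s)", x$ref_region))
  cat("\n  parameters: ",
      paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$vt)) cat(sprintf("  Vt = %.3f mL/mL\n", x$vt))
  if (!is.null(x$dvr)) cat(sprintf("  DVR = %.4f (BP = %.4f)\n", x$dvr, x$bp))
  if (!is.null(x$gof))
    cat(sprintf("  SSR = %.4g on %d frames, AIC = %.2f\n",
                x$gof$ssr, x$gof$n, x$gof$aic))
  if (!is.null(x$r2))
    cat(sprintf("  linear segment: t* = %g min, %d points, R2 = %.4f\n",
                x$t_star, x$n_points, x$r2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.kinfit <- function(object, ...) object$par

#' @export
fitted.kinfit <- function(object, ...) object$fitted

#' @export
residuals.kinfit <- function(object, ...) {
  if (is.null(object$fitted)) return(NULL)
  object$observed - object$fitted
}

#' @export
AIC.kinfit <- function(object, ..., k = 2) object$gof$aic

#' @export
summary.kinfit <- function(object, ...) {
  out <- list(model = object$model, region = object$region,
              par = object$par, vt = object$vt, dvr = object$dvr,
              gof = object$gof,
              rmse = if (!is.null(object$fitted))
                sqrt(mean((object$observed - object$fitted)^2)) else NA_real_,
              flags = object$flags)
  class(out) <- "summary.kinfit"
  out
}

#' @export
print.summary.kinfit <- function(x, ...) {
  cat(sprintf("Model: %s   region: %s\n", x$model, x$region))
  print(x$par)
  if (!is.null(x$vt)) cat(sprintf("Vt: %.3f\n", x$vt))
  if (!is.null(x$dvr)) cat(sprintf("DVR: %.4f\n", x$dvr))
  if (!is.null(x$gof))
    cat(sprintf("SSR: %.4g  AIC: %.2f  RMSE: %.4g\n",
                x$gof$ssr, x$gof$aic, x$rmse))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.kinfit <- function(x, ...) {
  if (inherits(x, c("logan_fit", "loganref_fit"))) {
    graphics::plot(x$x, x$y, xlab = "normalized integrated input",
                   ylab = "normalized integrated tissue",
                   main = sprintf("%s, %s (slope %.3f)", x$model, x$region,
                                  x$par[1]), ...)
    graphics::abline(x$intercept, x$par[1], col = 2)
  } else {
    mt <- frame_midtimes(x$schedule)
    graphics::plot(mt, x$observed, xlab = "time (min)",
                   ylab = "activity (kBq/mL)",
                   main = sprintf("%s, %s", x$model, x$region), ...)
    graphics::lines(mt, x$fitted, col = 2)
    graphics::legend("bottomright", c("observed", "fitted"),
                     pch = c(1, NA), lty = c(NA, 1), col = 1:2, bty = "n")
  }
  invisible(x)
}
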