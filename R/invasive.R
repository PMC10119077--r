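# Invasive (arterial-input) kinetic models.
#
# The measured PET signal is modelled with a fractional blood-volume term,
#   PET(t) = Vb * Cwb(t) + (1 - Vb) * C_T(t),
# where C_T is the tissue response.  For the one-tissue model
#   C_T(t) = K1 * int_0^t exp(-k2 (t - s)) AIF(s) ds.
# Convolutions with piecewise-linear inputs are computed in closed form
# per linear segment (exponential-times-linear antiderivative), and frame
# averages are obtained exactly from the identity
#   int_0^t E(s) ds = (int_0^t f - E(t)) / k,   E = f (x) exp(-k t),
# so no quadrature error enters the forward model.

# (1 - exp(-x)) / x with a series guard for small x
.em1x <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-5
  out[small] <- 1 - x[small] / 2 + x[small]^2 / 6
  out[!small] <- (1 - exp(-x[!small])) / x[!small]
  out
}

# E(t_i) = int_0^{t_i} exp(-k (t_i - s)) f(s) ds at all grid nodes,
# exact for piecewise-linear f.
conv_exp_nodes <- function(grid, f, k) {
  n <- length(grid)
  if (k < 1e-9) return(cumtrapz(grid, f))
  d <- diff(grid)
  ekd <- exp(-k * d)
  g1 <- d * .em1x(k * d)            # int_0^D exp(-k(D-u)) du
  g2 <- (d - g1) / k                # int_0^D exp(-k(D-u)) u du
  b <- diff(f) / d
  inc <- utils::head(f, -1) * g1 + b * g2
  E <- numeric(n)
  for (i in seq_len(n - 1)) E[i + 1] <- E[i] * ekd[i] + inc[i]
  E
}

# Exact per-frame time-averages of E(t) (convolution with exp(-k t)) and
# of the piecewise-linear input itself, on a grid containing frame edges.
# ia/ib: indices of frame starts/ends in grid; returns list(conv, input).
.frame_averages <- function(grid, f, k, ia, ib) {
  intf <- cumtrapz(grid, f)
  dur <- grid[ib] - grid[ia]
  if (k < 1e-9) {
    iintf <- cumtrapz(grid, intf)   # near-exact on the dense grid
    conv_avg <- (iintf[ib] - iintf[ia]) / dur
  } else {
    E <- conv_exp_nodes(grid, f, k)
    iE <- (intf - E) / k            # int_0^t E, exact
    conv_avg <- (iE[ib] - iE[ia]) / dur
  }
  list(conv = conv_avg, input = (intf[ib] - intf[ia]) / dur)
}

# Computation grid: union of the input grid and the frame edges (minutes).
.model_grid <- function(inp, schedule) {
  edges <- sort(unique(c(schedule$start, schedule$end))) / 60
  if (max(edges) > max(inp$grid) + 1e-9)
    stop("input-function grid does not cover the frame schedule")
  g <- sort(unique(c(inp$grid, edges)))
  ia <- match(round(schedule$start / 60, 10), round(g, 10))
  ib <- match(round(schedule$end / 60, 10), round(g, 10))
  if (any(is.na(ia)) || any(is.na(ib))) stop("internal: frame edge not on grid")
  list(g = g, ia = ia, ib = ib,
       aif = interp_input(inp, g, "aif"), cwb = interp_input(inp, g, "cwb"))
}

#' One-tissue compartment forward model
#'
#' Frame-averaged model TAC for parameters (K1, k2, Vb) given an arterial
#' input function and whole-blood curve.
#'
#' @param K1 Influx rate, mL/(min*mL).
#' @param k2 Efflux rate, 1/min.
#' @param Vb Fractional blood volume in [0, 1].
#' @param aif An `input_function` (its `cwb` component supplies the
#'   whole-blood term).
#' @param schedule A [frame_schedule()] covered by the input grid.
#' @return Numeric vector of per-frame model values (kBq/mL).
#' @export
forward_1tc <- function(K1, k2, Vb, aif, schedule) {
  mg <- .model_grid(aif, schedule)
  fa <- .frame_averages(mg$g, mg$aif, k2, mg$ia, mg$ib)
  wb <- .frame_averages(mg$g, mg$cwb, 1, mg$ia, mg$ib)$input
  Vb * wb + (1 - Vb) * K1 * fa$conv
}

# macro-rate constants of the serial two-tissue system
.twotc_alphas <- function(k2, k3, k4) {
  s <- k2 + k3 + k4
  disc <- sqrt(max(s^2 - 4 * k2 * k4, 0))
  a1 <- (s - disc) / 2
  a2 <- (s + disc) / 2
  if (a2 - a1 < 1e-10) a2 <- a1 + 1e-10
  c(a1, a2)
}

#' Two-tissue compartment forward model
#'
#' Serial two-tissue system `dC1/dt = K1 AIF - (k2 + k3) C1 + k4 C2`,
#' `dC2/dt = k3 C1 - k4 C2`, `C_T = C1 + C2`, solved in closed form as a
#' sum of two exponential convolutions, with the blood-volume term as in
#' [forward_1tc()].
#'
#' @inheritParams forward_1tc
#' @param k3,k4 Exchange rates with the second (bound) compartment, 1/min.
#' @export
forward_2tc <- function(K1, k2, k3, k4, Vb, aif, schedule) {
  mg <- .model_grid(aif, schedule)
  al <- .twotc_alphas(k2, k3, k4)
  c1 <- (k3 + k4 - al[1]) / (al[2] - al[1])
  c2 <- (al[2] - k3 - k4) / (al[2] - al[1])
  e1 <- .frame_averages(mg$g, mg$aif, al[1], mg$ia, mg$ib)$conv
  e2 <- .frame_averages(mg$g, mg$aif, al[2], mg$ia, mg$ib)$conv
  wb <- .frame_averages(mg$g, mg$cwb, 1, mg$ia, mg$ib)$input
  Vb * wb + (1 - Vb) * K1 * (c1 * e1 + c2 * e2)
}

#' Frame weights for kinetic fitting
#'
#' The default scheme `"frame-decay"` is the standard count-statistics
#' surrogate `w_j = dt_j * exp(-2 lambda t_j)` (frame duration times the
#' squared decay factor at the frame mid-time), normalized to mean 1;
#' `"uniform"` weights all frames equally.
#'
#' @param schedule A [frame_schedule()].
#' @param scheme `"frame-decay"` or `"uniform"`.
#' @param constants [decay_constants()] used by the decay factor.
#' @export
kin_weights <- function(schedule, scheme = c("frame-decay", "uniform"),
                        constants = decay_constants()) {
  scheme <- match.arg(scheme)
  n <- nrow(schedule)
  if (scheme == "uniform") return(rep(1, n))
  w <- frame_durations(schedule) *
    exp(-2 * constants$lambda * frame_midtimes(schedule))
  w / mean(w)
}

.resolve_weights <- function(weights, schedule, constants) {
  if (is.character(weights)) return(kin_weights(schedule, weights, constants))
  if (is.null(weights)) return(kin_weights(schedule, "frame-decay", constants))
  if (length(weights) != nrow(schedule))
    stop("weights must have one entry per frame")
  weights
}

.region_values <- function(x, region) {
  stopifnot(inherits(x, "tac"))
  if (is.null(region)) region <- x$regions[1]
  if (!region %in% x$regions) stop("unknown region: ", region)
  list(y = x$values[, region], region = region)
}

# weighted least squares for PET = th1 * basis + th2 * wb under
# 0 <= th2 <= vb_max, 0 <= th1 <= th1_max; returns c(th1, th2)
.solve_linear_pair <- function(y, basis, wb, w, vb_max = 0.2, th1_max = 10) {
  solve_th1 <- function(th2) {
    r <- y - th2 * wb
    denom <- sum(w * basis^2)
    th1 <- if (denom > 0) sum(w * basis * r) / denom else 0
    min(max(th1, 0), th1_max)
  }
  A <- cbind(basis, wb)
  M <- crossprod(A * sqrt(w))
  b <- crossprod(A, w * y)
  th <- try(solve(M, b), silent = TRUE)
  ok <- !inherits(th, "try-error") && all(is.finite(th))
  if (ok && th[2] >= 0 && th[2] <= vb_max && th[1] >= 0 && th[1] <= th1_max)
    return(c(th[1], th[2]))
  # project Vb onto its bounds and refit the tissue amplitude
  cand <- lapply(c(0, vb_max), function(v) c(solve_th1(v), v))
  ssr <- vapply(cand, function(p) sum(w * (y - p[1] * basis - p[2] * wb)^2),
                numeric(1))
  cand[[which.min(ssr)]]
}

.gof <- function(ssr, n, k) {
  list(ssr = ssr, n = n, k = k,
       aic = if (ssr > 0 && n > k) aic(ssr, n, k) else -Inf)
}

#' Fit the one-tissue compartment model to a regional TAC
#'
#' Weighted least squares against [forward_1tc()].  The problem is solved
#' by profiling: for fixed `k2` the model is linear in the tissue
#' amplitude `(1 - Vb) K1` and in `Vb`, so a global grid search over `k2`
#' (log-spaced over its bounds) with an exact linear subfit, followed by a
#' 1-D refinement, finds the optimum robustly.  Bounds: `K1` in [0, 10],
#' `k2` in [1e-4, 1], `Vb` in [0, 0.2].
#'
#' @param x A [tac()] object.
#' @param aif An `input_function`.
#' @param region Region name (default: first region of `x`).
#' @param weights `"frame-decay"` (default), `"uniform"`, or a numeric
#'   vector per frame; see [kin_weights()].
#' @param constants [decay_constants()] for the weighting scheme.
#' @param k2_grid Number of grid points for the profile search.
#' @return Object of class `c("onetc_fit", "kinfit")` with elements
#'   `par` (K1, k2, Vb), `vt` (= K1/k2), `gof` (SSR, n, k, AIC),
#'   `fitted`, `observed`, `weights`.
#' @export
fit_1tc <- function(x, aif, region = NULL, weights = "frame-decay",
                    constants = decay_constants(), k2_grid = 60) {
  rv <- .region_values(x, region)
  y <- rv$y
  sch <- x$schedule
  if (nrow(sch) < 6) stop("need at least 6 frames for a 1TC fit")
  w <- .resolve_weights(weights, sch, constants)
  mg <- .model_grid(aif, sch)
  wb <- .frame_averages(mg$g, mg$cwb, 1, mg$ia, mg$ib)$input
  eval_k2 <- function(k2) {
    basis <- .frame_averages(mg$g, mg$aif, k2, mg$ia, mg$ib)$conv
    th <- .solve_linear_pair(y, basis, wb, w)
    ssr <- sum(w * (y - th[1] * basis - th[2] * wb)^2)
    list(ssr = ssr, th = th, basis = basis)
  }
  grid <- exp(seq(log(1e-4), log(1), length.out = k2_grid))
  ssrs <- vapply(grid, function(k) eval_k2(k)$ssr, numeric(1))
  i <- which.min(ssrs)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(function(k) eval_k2(k)$ssr, c(lo, hi), tol = 1e-10)
  k2 <- opt$minimum
  best <- eval_k2(k2)
  Vb <- best$th[2]
  K1 <- best$th[1] / (1 - Vb)
  fitted <- best$th[1] * best$basis + Vb * wb
  structure(list(model = "1TC", region = rv$region,
                 par = c(K1 = K1, k2 = k2, Vb = Vb), vt = K1 / k2,
                 gof = .gof(best$ssr, length(y), 3),
                 fitted = fitted, observed = y, weights = w,
                 schedule = sch, flags = character()),
            class = c("onetc_fit", "kinfit"))
}

#' Fit the two-tissue compartment model to a regional TAC
#'
#' As [fit_1tc()], with the serial two-tissue system of [forward_2tc()].
#' The three nonlinear rates (k2, k3, k4) are optimized by bounded
#' multi-start quasi-Newton search (8 starts) with the two linear
#' parameters profiled out exactly at every step.  Estimates pinned at a
#' rate bound (a hallmark of unidentifiable k3/k4 for very slow kinetics)
#' are flagged in `flags`.
#'
#' @inheritParams fit_1tc
#' @return Object of class `c("twotc_fit", "kinfit")`; `vt` is
#'   `(K1/k2) (1 + k3/k4)` (infinite when k4 = 0, flagged).
#' @export
fit_2tc <- function(x, aif, region = NULL, weights = "frame-decay",
                    constants = decay_constants()) {
  rv <- .region_values(x, region)
  y <- rv$y
  sch <- x$schedule
  if (nrow(sch) < 6) stop("need at least 6 frames for a 2TC fit")
  w <- .resolve_weights(weights, sch, constants)
  mg <- .model_grid(aif, sch)
  wb <- .frame_averages(mg$g, mg$cwb, 1, mg$ia, mg$ib)$input
  basis_fun <- function(p) {
    al <- .twotc_alphas(p[1], p[2], p[3])
    c1 <- (p[2] + p[3] - al[1]) / (al[2] - al[1])
    c2 <- (al[2] - p[2] - p[3]) / (al[2] - al[1])
    c1 * .frame_averages(mg$g, mg$aif, al[1], mg$ia, mg$ib)$conv +
      c2 * .frame_averages(mg$g, mg$aif, al[2], mg$ia, mg$ib)$conv
  }
  obj <- function(p) {
    basis <- basis_fun(p)
    th <- .solve_linear_pair(y, basis, wb, w)
    sum(w * (y - th[1] * basis - th[2] * wb)^2)
  }
  lower <- c(1e-4, 0, 0); upper <- c(1, 1, 1)
  starts <- as.matrix(expand.grid(k2 = c(0.01, 0.05), k3 = c(0.005, 0.05),
                                  k4 = c(0.005, 0.05)))
  # seed from the nested one-tissue solution (k3 = 0): guarantees the
  # 2TC fit is never worse than the best 1TC fit on the same data
  k2_1tc <- {
    grid <- exp(seq(log(1e-4), log(1), length.out = 40))
    vals <- vapply(grid, function(k) obj(c(k, 0, 0.005)), numeric(1))
    i <- which.min(vals)
    stats::optimize(function(k) obj(c(k, 0, 0.005)),
                    c(grid[max(i - 1, 1)], grid[min(i + 1, length(grid))]),
                    tol = 1e-10)$minimum
  }
  starts <- rbind(starts, c(k2_1tc, 0, 0.005), c(k2_1tc, 0.01, 0.005))
  best <- NULL; diags <- list()
  for (s in seq_len(nrow(starts))) {
    ps <- pmax(abs(starts[s, ]), 1e-2)   # scale steps to rate magnitudes
    f <- try(stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(factr = 1e4, parscale = ps)),
             silent = TRUE)
    if (inherits(f, "try-error")) { diags[[s]] <- as.character(f); next }
    diags[[s]] <- f$value
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (is.null(best))
    stop("2TC fit failed to converge from every start; per-start diagnostics: ",
         paste(unlist(diags), collapse = "; "))
  polish <- try(stats::optim(best$par, obj, method = "L-BFGS-B",
                             lower = lower, upper = upper,
                             control = list(factr = 10, maxit = 500,
                                            parscale = pmax(abs(best$par),
                                                            1e-3))),
                silent = TRUE)
  if (!inherits(polish, "try-error") && polish$value <= best$value)
    best <- polish
  p <- best$par
  basis <- basis_fun(p)
  th <- .solve_linear_pair(y, basis, wb, w)
  Vb <- th[2]
  K1 <- th[1] / (1 - Vb)
  flags <- character()
  tol <- 1e-6
  if (p[2] <= tol || p[3] <= tol || any(abs(p - upper) < tol))
    flags <- c(flags, "rate-at-bound")
  vt <- if (p[3] > 0) (K1 / p[1]) * (1 + p[2] / p[3]) else Inf
  if (!is.finite(vt)) flags <- c(flags, "vt-undefined")
  fitted <- th[1] * basis + Vb * wb
  structure(list(model = "2TC", region = rv$region,
                 par = c(K1 = K1, k2 = p[1], k3 = p[2], k4 = p[3], Vb = Vb),
                 vt = vt, gof = .gof(best$value, length(y), 5),
                 fitted = fitted, observed = y, weights = w,
                 schedule = sch, flags = flags),
            class = c("twotc_fit", "kinfit"))
}

# Cumulative integral of a frame-sampled curve up to each frame mid-time.
# Frame values are time-averages, so within frames the exact increment is
# value * duration (half of it up to the mid-time).  Gaps between
# acquisition parts are bridged by integrating a cubic spline through the
# origin and the mid-time points: slowly clearing tracers can peak inside
# a between-part break, which a straight chord would clip.
.tac_cumint <- function(schedule, v) {
  mt <- frame_midtimes(schedule)
  st <- schedule$start / 60; en <- schedule$end / 60
  dt <- en - st
  n <- length(v)
  inc <- v * dt
  gap <- c(0, st[-1] - en[-n])
  gap_int <- numeric(n)
  idx <- which(gap > 1e-9)
  if (length(idx)) {
    bridge <- if (n >= 4) stats::splinefun(c(0, mt), c(0, v), method = "fmm")
      else stats::approxfun(c(0, mt), c(0, v), rule = 2)
    for (i in idx)
      gap_int[i] <- stats::integrate(bridge, en[i - 1], st[i],
                                     subdivisions = 200L)$value
  }
  cumsum(inc + gap_int) - inc / 2
}

#' Logan graphical analysis with arterial input
#'
#' Ordinary least squares on the transformed variables
#' `y(Tf) = int_0^Tf C_T / C_T(Tf)` against
#' `x(Tf) = int_0^Tf AIF / C_T(Tf)` over frames with mid-time beyond
#' `t_star`; the slope estimates the total distribution volume Vt.  The
#' tissue integral treats frame values as frame averages (increment
#' value x duration), bridging the inter-part gap by a trapezoid; no
#' blood-volume correction is applied.
#'
#' @inheritParams fit_1tc
#' @param t_star Start of the linear segment, minutes (default 60), or
#'   `"auto"` to choose the earliest start whose points deviate from the
#'   line by less than `max_rel_dev` relative.
#' @param max_rel_dev Maximum relative deviation for the automatic
#'   `t_star` selector.
#' @return Object of class `c("logan_fit", "kinfit")` with `vt` (slope),
#'   `intercept`, `t_star`, `n_points` and `r2`.
#' @export
logan_vt <- function(x, aif, region = NULL, t_star = 60, max_rel_dev = 0.1) {
  rv <- .region_values(x, region)
  mt <- frame_midtimes(x$schedule)
  ct <- rv$y
  int_ct <- .tac_cumint(x$schedule, ct)
  int_in <- cumtrapz(aif$grid, aif$aif)
  int_in <- stats::approx(aif$grid, int_in, xout = mt, rule = 2)$y
  res <- .logan_regress(int_ct / ct, int_in / ct, mt, ct, t_star, max_rel_dev)
  structure(list(model = "LOGAN", region = rv$region,
                 par = c(Vt = res$slope), vt = res$slope,
                 intercept = res$intercept, t_star = res$t_star,
                 n_points = res$n, r2 = res$r2, schedule = x$schedule,
                 x = res$x, y = res$y),
            class = c("logan_fit", "kinfit"))
}

# shared Logan-type regression with window selection and validity checks
.logan_regress <- function(yv, xv, mt, ct, t_star, max_rel_dev) {
  if (identical(t_star, "auto")) {
    t_star <- .auto_t_star(xv, yv, mt, max_rel_dev)
  }
  if (t_star >= max(mt)) stop("t_star lies beyond the last frame")
  keep <- mt > t_star
  if (sum(keep) < 3) stop("need at least 3 frames beyond t_star")
  if (any(ct[keep] <= 0))
    stop("non-positive TAC values in the Logan window")
  fit <- stats::lm(yv[keep] ~ xv[keep])
  ssr <- sum(stats::resid(fit)^2)
  sst <- sum((yv[keep] - mean(yv[keep]))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       t_star = t_star, n = sum(keep), r2 = min(max(r2, 0), 1),
       x = xv[keep], y = yv[keep])
}

.auto_t_star <- function(xv, yv, mt, max_rel_dev) {
  ok <- is.finite(xv) & is.finite(yv) & abs(yv) > 0
  n <- length(mt)
  for (s in seq_len(n - 2)) {
    i <- which(ok & seq_len(n) >= s)
    if (length(i) < 3) break
    f <- stats::lm(yv[i] ~ xv[i])
    if (max(abs(stats::resid(f)) / abs(yv[i])) <= max_rel_dev)
      return(if (s == 1) 0 else (mt[s - 1] + mt[s]) / 2)
  }
  stop("no linear segment satisfies the deviation criterion")
}

#' Akaike information criterion from a least-squares fit
#'
#' `AIC = n log(SSR / n) + 2 k`, the form appropriate for comparing
#' least-squares kinetic models on the same data.
#'
#' @param ssr Residual sum of squares (> 0).
#' @param n Number of data points (> k).
#' @param k Number of fitted parameters.
#' @export
aic <- function(ssr, n, k) {
  if (n <= k) stop("AIC requires more data points than parameters")
  if (!is.finite(ssr) || ssr < 0) stop("invalid SSR")
  if (ssr == 0) stop("SSR is exactly zero; AIC is -Inf (degenerate fit)")
  n * log(ssr / n) + 2 * k
}

#' Distribution volume ratio from two total distribution volumes
#'
#' @param vt_roi Vt of the target region (mL/mL).
#' @param vt_ref Vt of the reference region (> 0).
#' @export
dvr_from_vt <- function(vt_roi, vt_ref) {
  if (any(vt_ref <= 0)) stop("reference Vt must be positive")
  vt_roi / vt_ref
}
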