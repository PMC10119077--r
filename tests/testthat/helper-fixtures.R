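# Shared fixtures (built once per test run) and independent numerical
# oracles for the convolution-based forward models.

fx <- new.env()
fx$sch <- default_schedule()
fx$profile <- input_profile()
fx$inp <- generate_input_profile(fx$profile)
fx$presets <- region_presets()

preset_row <- function(name) fx$presets[fx$presets$name == name, ]

# noise-free 1TC tissue curve (optionally with blood volume) as a tac
make_1tc_tac <- function(K1, k2, Vb = 0, name = "roi", inp = fx$inp,
                         sch = fx$sch) {
  tac(sch, matrix(forward_1tc(K1, k2, Vb, inp, sch), ncol = 1),
      regions = name)
}

make_pair_tac <- function(roi, ref, Vb_roi = 0, Vb_ref = 0, inp = fx$inp,
                          sch = fx$sch) {
  v <- cbind(forward_1tc(roi$K1, roi$k2, Vb_roi, inp, sch),
             forward_1tc(ref$K1, ref$k2, Vb_ref, inp, sch))
  tac(sch, v, regions = c("roi", "ref"))
}

# ---- independent dense-grid numeric convolution oracle -------------------
# First-order trapezoidal quadrature of int exp(-k(t-s)) f(s) ds on a
# fine uniform grid, kept numerically stable by stepping the exponential.
oracle_conv_dense <- function(tg, f, k) {
  n <- length(tg)
  C <- numeric(n)
  d <- diff(tg)
  e <- exp(-k * d)
  for (i in seq_len(n - 1))
    C[i + 1] <- C[i] * e[i] + d[i] / 2 * (f[i] * e[i] + f[i + 1])
  C
}

oracle_cumint <- function(tg, y) {
  c(0, cumsum(diff(tg) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

# frame averages of a densely sampled curve; frame edges must lie on tg
oracle_frame_avg <- function(tg, y, sch) {
  ci <- oracle_cumint(tg, y)
  ia <- match(round(sch$start / 60, 8), round(tg, 8))
  ib <- match(round(sch$end / 60, 8), round(tg, 8))
  (ci[ib] - ci[ia]) / (tg[ib] - tg[ia])
}

# dense grid covering the acquisition with every frame edge and mid-time
# on-grid (edges are multiples of 0.25 min, mid-times of 0.125 min)
oracle_grid <- function(t_end = 225, step = 0.005) seq(0, t_end, by = step)

# relative deviation with a floor so empty early frames do not blow up
rel_dev <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-3 * max(abs(b))))

# count-statistics frame noise used by the generator
frame_noise_sd <- function(mu, alpha, sch = fx$sch,
                           constants = decay_constants()) {
  alpha * sqrt(pmax(mu, 0) /
                 (frame_durations(sch) *
                    exp(-constants$lambda * frame_midtimes(sch))))
}
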