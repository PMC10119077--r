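test_that("1TC forward model agrees with the dense numeric convolution oracle", {
  tg <- oracle_grid()
  fd <- approx(fx$inp$grid, fx$inp$aif, tg, rule = 2)$y
  wd <- approx(fx$inp$grid, fx$inp$cwb, tg, rule = 2)$y
  set.seed(21)
  for (i in 1:10) {
    K1 <- runif(1, 0.2, 2); k2 <- runif(1, 0.005, 0.2); Vb <- runif(1, 0, 0.1)
    dense <- Vb * wd + (1 - Vb) * K1 * oracle_conv_dense(tg, fd, k2)
    expect_lt(rel_dev(forward_1tc(K1, k2, Vb, fx$inp, fx$sch),
                      oracle_frame_avg(tg, dense, fx$sch)), 0.001)
  }
})

test_that("1TC forward limiting cases", {
  # K1 = 0: pure blood-volume signal
  wbavg <- forward_1tc(0, 0.01, 1, fx$inp, fx$sch)
  expect_equal(forward_1tc(0, 0.05, 0.04, fx$inp, fx$sch), 0.04 * wbavg)
  # k2 -> 0: tissue term approaches K1 * cumulative integral of the AIF
  tg <- oracle_grid()
  fd <- approx(fx$inp$grid, fx$inp$aif, tg, rule = 2)$y
  lim <- oracle_frame_avg(tg, 2 * oracle_cumint(tg, fd), fx$sch)
  expect_lt(rel_dev(forward_1tc(2, 1e-10, 0, fx$inp, fx$sch), lim), 0.01)
})

test_that("1TC fit recovers noise-free generated parameters to <0.5%", {
  for (nm in c("cingulate", "cerebellum_wm")) {
    p <- preset_row(nm)
    x <- simulate_region_tac(nm, fx$inp, fx$sch, alpha = 0)
    f <- fit_1tc(x, fx$inp)
    expect_lt(max(abs(coef(f) / c(p$K1, p$k2, p$Vb) - 1)), 0.005)
    # Vt identity holds exactly
    expect_identical(f$vt, unname(coef(f)["K1"] / coef(f)["k2"]))
  }
  # null signal
  z <- tac(fx$sch, matrix(0, 32, 1), "null")
  fz <- fit_1tc(z, fx$inp)
  expect_lt(coef(fz)["K1"], 1e-8)
})

test_that("2TC fit: nesting and parameter recovery", {
  # k3 = 0 collapses to 1TC: fitted Vt matches K1/k2 within 1%
  p <- preset_row("cingulate")
  x1 <- make_1tc_tac(p$K1, p$k2, 0.03)
  f2 <- fit_2tc(x1, fx$inp)
  expect_lt(abs(f2$vt / (p$K1 / p$k2) - 1), 0.01)
  # genuine 2TC data are recovered within 1%
  truth <- c(K1 = 0.5, k2 = 0.05, k3 = 0.02, k4 = 0.01, Vb = 0.03)
  y <- forward_2tc(truth["K1"], truth["k2"], truth["k3"], truth["k4"],
                   truth["Vb"], fx$inp, fx$sch)
  f <- fit_2tc(tac(fx$sch, matrix(y, ncol = 1), "r2t"), fx$inp)
  expect_lt(max(abs(coef(f) / truth - 1)), 0.01)
  vt_truth <- (truth["K1"] / truth["k2"]) * (1 + truth["k3"] / truth["k4"])
  expect_lt(abs(f$vt / vt_truth - 1), 0.01)
  # nested-model SSR ordering on identical data
  f1 <- fit_1tc(x1, fx$inp)
  f2b <- fit_2tc(x1, fx$inp)
  expect_lte(f2b$gof$ssr, f1$gof$ssr + max(1e-12, 1e-8 * f1$gof$ssr))
})

test_that("Logan graphical slope recovers Vt on noise-free data", {
  p <- preset_row("cingulate")
  x <- make_1tc_tac(p$K1, p$k2, 0)
  lg <- logan_vt(x, fx$inp, t_star = 60)
  expect_lt(abs(lg$vt / p$vt - 1), 0.01)
  expect_equal(lg$n_points, sum(frame_midtimes(fx$sch) > 60))
  expect_gt(lg$r2, 0.999)
  expect_error(logan_vt(x, fx$inp, t_star = 300), "beyond the last frame")
})

test_that("Logan regression returns exact parameters on constructed linear data", {
  mt <- 1:10
  xv <- seq(2, 20, by = 2)
  yv <- 5 * xv - 2
  res <- petkin:::.logan_regress(yv, xv, mt, rep(1, 10), t_star = 3,
                                 max_rel_dev = 0.1)
  expect_equal(res$slope, 5)
  expect_equal(res$intercept, -2)
  expect_equal(res$r2, 1)
})

test_that("automatic t_star selects an early start on noise-free data", {
  p <- preset_row("cingulate")
  x <- make_1tc_tac(p$K1, p$k2, 0)
  lg <- logan_vt(x, fx$inp, t_star = "auto")
  expect_lt(lg$t_star, 60)
  expect_lt(abs(lg$vt / p$vt - 1), 0.02)
})

test_that("Logan slope is negatively biased under frame noise", {
  p <- preset_row("cingulate")
  mu <- forward_1tc(p$K1, p$k2, 0, fx$inp, fx$sch)
  sdj <- frame_noise_sd(mu, 0.6)
  set.seed(31)
  slopes <- replicate(60, {
    y <- mu + rnorm(length(mu), 0, sdj)
    logan_vt(tac(fx$sch, matrix(y, ncol = 1), "roi", noise_floor = -50),
             fx$inp, t_star = 60)$vt
  })
  expect_lt(mean(slopes), p$vt)
})

test_that("AIC identities and scale invariance of model ordering", {
  expect_equal(aic(32, 32, 3), 6)
  expect_equal(aic(16, 32, 3) - aic(32, 32, 3), -32 * log(2))
  expect_error(aic(0, 32, 3), "zero")
  expect_error(aic(1, 3, 3), "more data points")
  # rescaling all activities by c shifts every AIC equally (relative
  # weights), leaving model ordering unchanged
  d_orig <- aic(10, 32, 3) - aic(7, 32, 5)
  d_scaled <- aic(10 * 4, 32, 3) - aic(7 * 4, 32, 5)
  expect_equal(d_orig, d_scaled)
})

test_that("DVR from Vt is the plain ratio with a positivity guard", {
  expect_equal(dvr_from_vt(5, 5), 1)
  expect_equal(dvr_from_vt(98.4, 68.7), 1.432, tolerance = 1e-3)
  expect_error(dvr_from_vt(5, 0), "positive")
})
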