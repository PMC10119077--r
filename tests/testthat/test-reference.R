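test_that("SRTM forward model agrees with the dense numeric convolution oracle", {
  ref <- preset_row("cerebellum_wm")
  xref <- make_1tc_tac(ref$K1, ref$k2, 0, name = "ref")
  knots <- list(t = c(0, frame_midtimes(fx$sch)), v = c(0, xref$values[, 1]))
  tg <- oracle_grid()
  crefd <- approx(knots$t, knots$v, tg, rule = 2)$y
  mt <- frame_midtimes(fx$sch)
  set.seed(22)
  for (i in 1:8) {
    R1 <- runif(1, 0.5, 1.5); k2 <- runif(1, 0.01, 0.2); BP <- runif(1, 0, 1)
    k2a <- k2 / (1 + BP)
    dense <- R1 * crefd + (k2 - R1 * k2a) * oracle_conv_dense(tg, crefd, k2a)
    expect_lt(rel_dev(forward_srtm(R1, k2, BP, knots, fx$sch), approx(tg, dense, mt)$y),
              0.001)
  }
})

test_that("SRTM forward limiting cases", {
  ref <- preset_row("cerebellum_wm")
  xref <- make_1tc_tac(ref$K1, ref$k2, 0, name = "ref")
  knots <- list(t = c(0, frame_midtimes(fx$sch)), v = c(0, xref$values[, 1]))
  # BP = 0, R1 = 1: target indistinguishable from reference
  expect_equal(forward_srtm(1, 0.05, 0, knots, fx$sch), xref$values[, 1],
               tolerance = 1e-12)
  # null reference gives a null model
  zero <- list(t = c(0, frame_midtimes(fx$sch)), v = rep(0, 33))
  expect_equal(forward_srtm(0.9, 0.05, 0.4, zero, fx$sch), rep(0, 32))
})

test_that("SRTM basis fit is self-consistent and exact for ROI = reference", {
  ref <- preset_row("cerebellum_wm")
  xref <- make_1tc_tac(ref$K1, ref$k2, 0, name = "ref")
  knots <- list(t = c(0, frame_midtimes(fx$sch)), v = c(0, xref$values[, 1]))
  truth <- c(R1 = 0.9, k2 = 0.05, BP = 0.4)
  y <- forward_srtm(truth["R1"], truth["k2"], truth["BP"], knots, fx$sch)
  pair <- tac(fx$sch, cbind(y, xref$values[, 1]), c("roi", "ref"))
  f <- fit_srtm(pair, "roi", "ref")
  expect_lt(max(abs(coef(f) / truth - 1)), 0.005)
  expect_identical(f$dvr - f$bp, 1)
  same <- tac(fx$sch, cbind(xref$values[, 1], xref$values[, 1]),
              c("roi", "ref"))
  fs <- fit_srtm(same, "roi", "ref")
  expect_equal(fs$bp, 0, tolerance = 1e-8)
  expect_equal(unname(coef(fs)["R1"]), 1, tolerance = 1e-8)
})

test_that("reference methods recover the Vt ratio of a 1TC region pair", {
  roi <- preset_row("cingulate"); ref <- preset_row("cerebellum_wm")
  dvr_truth <- roi$vt / ref$vt              # 1.436 from the preset table
  pair <- make_pair_tac(roi, ref)
  fs <- fit_srtm(pair, "roi", "ref")
  expect_lt(abs(fs$dvr / dvr_truth - 1), 0.03)
  lr <- logan_ref(pair, "roi", "ref", t_star = 60)
  expect_lt(abs(lr$dvr / dvr_truth - 1), 0.02)
  expect_identical(lr$dvr - lr$bp, 1)
})

test_that("reference Logan is insensitive to the k2' term at late t_star", {
  roi <- preset_row("cingulate"); ref <- preset_row("cerebellum_wm")
  pair <- make_pair_tac(roi, ref)
  with_k2p <- logan_ref(pair, "roi", "ref", t_star = 90, k2_prime = 0.015)
  without <- logan_ref(pair, "roi", "ref", t_star = 90)
  expect_lt(abs(with_k2p$dvr - without$dvr) / with_k2p$dvr, 0.02)
})

test_that("ROI identical to reference gives DVR exactly 1 in reference Logan", {
  ref <- preset_row("cerebellum_wm")
  x <- make_1tc_tac(ref$K1, ref$k2, 0)
  same <- tac(fx$sch, cbind(x$values[, 1], x$values[, 1]), c("roi", "ref"))
  for (ts in c(30, 60, 90)) {
    lr <- logan_ref(same, "roi", "ref", t_star = ts)
    expect_equal(lr$dvr, 1, tolerance = 1e-10)
  }
})

test_that("fitted DVR increases strictly with the generating ROI Vt", {
  ref <- preset_row("cerebellum_wm")
  K1 <- 1.2
  vts <- c(60, 80, 100, 120)
  dvr_s <- dvr_l <- numeric(length(vts))
  for (i in seq_along(vts)) {
    pair <- make_pair_tac(list(K1 = K1, k2 = K1 / vts[i]), ref)
    dvr_s[i] <- fit_srtm(pair, "roi", "ref")$dvr
    dvr_l[i] <- logan_ref(pair, "roi", "ref", t_star = 60)$dvr
  }
  expect_true(all(diff(dvr_s) > 0))
  expect_true(all(diff(dvr_l) > 0))
})

test_that("reference Logan DVR is less noise-sensitive than SRTM DVR", {
  roi <- preset_row("cingulate"); ref <- preset_row("cerebellum_wm")
  mu_r <- forward_1tc(roi$K1, roi$k2, roi$Vb, fx$inp, fx$sch)
  mu_w <- forward_1tc(ref$K1, ref$k2, ref$Vb, fx$inp, fx$sch)
  set.seed(17)
  res <- t(replicate(40, {
    y1 <- mu_r + rnorm(32, 0, frame_noise_sd(mu_r, 0.05))
    y2 <- mu_w + rnorm(32, 0, frame_noise_sd(mu_w, 0.05))
    pr <- tac(fx$sch, cbind(y1, y2), c("roi", "ref"), noise_floor = -50)
    c(lref = logan_ref(pr, "roi", "ref", 60)$dvr,
      srtm = fit_srtm(pr, "roi", "ref")$dvr)
  }))
  expect_lt(var(res[, "lref"]), var(res[, "srtm"]))
})
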