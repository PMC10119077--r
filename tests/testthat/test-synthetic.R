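test_that("input profile: appearance delay, continuity, component identity", {
  prof <- fx$profile
  grid <- seq(0, 225, by = 0.25)
  inp <- generate_input_profile(prof, grid)
  expect_true(all(inp$cwb[grid <= prof$delay] == 0))
  expect_true(all(inp$aif >= 0))
  # parent fraction has plateaued by the last sampling time
  expect_equal(inp$ppf[grid == 205], 1 - prof$A0, tolerance = 1e-4)
  # AIF / (Cwb * fwb * fp) equals PPf wherever Cwb > 0
  pos <- inp$cwb > 0
  expect_equal(inp$aif[pos] / (inp$cwb[pos] * prof$fwb * inp$fp[pos]),
               inp$ppf[pos], tolerance = 1e-12)
  expect_error(input_profile(rise_rate = 0.005), "rise rate")
})

test_that("blood sampling schedule matches the arterial protocol", {
  ts <- blood_sampling_times()
  expect_equal(length(ts$wb), 28)
  expect_equal(length(ts$plasma), 18)
  expect_true(all(ts$plasma %in% c(0.25, ts$wb)))
  expect_equal(length(blood_sampling_times(include_t0 = TRUE)$wb), 29)
  bd <- sample_blood(fx$profile, noise = 0.02, seed = 4)
  expect_equal(length(bd$time_cp), 18)
  expect_equal(bd$time_pf, c(2, 10, 30, 90, 205))
})

test_that("zero noise reproduces closed forms; same seed reproduces bits", {
  bd0 <- sample_blood(fx$profile, noise = 0, seed = 1)
  expect_equal(bd0$cwb, profile_cwb(fx$profile, bd0$time_wb))
  a <- sample_blood(fx$profile, noise = 0.05, seed = 9)
  b <- sample_blood(fx$profile, noise = 0.05, seed = 9)
  expect_identical(a, b)
  x0 <- simulate_region_tac("cingulate", fx$inp, fx$sch, alpha = 0)
  p <- preset_row("cingulate")
  expect_equal(x0$values[, 1], forward_1tc(p$K1, p$k2, p$Vb, fx$inp, fx$sch))
})

test_that("TAC noise scales linearly with alpha", {
  mu <- simulate_region_tac("cingulate", fx$inp, fx$sch, alpha = 0)
  a <- simulate_region_tac("cingulate", fx$inp, fx$sch, alpha = 0.3, seed = 5)
  b <- simulate_region_tac("cingulate", fx$inp, fx$sch, alpha = 0.6, seed = 5)
  na <- a$values - mu$values
  nb <- b$values - mu$values
  nz <- abs(na) > 1e-12
  expect_true(any(nz))
  expect_equal(nb[nz] / na[nz], rep(2, sum(nz)), tolerance = 1e-9)
})

test_that("noise-free fit of generated parent fractions returns the configured model", {
  bd <- sample_blood(fx$profile, noise = 0, seed = 2)
  fit <- fit_parent_fraction(bd$time_pf, bd$pf)
  expect_lt(abs(fit$A0 / fx$profile$A0 - 1), 0.01)
  expect_lt(abs(fit$T / fx$profile$T - 1), 0.01)
})

test_that("study generator: determinism, degenerate config, ground-truth DVR", {
  cfg <- study_config(n_subjects = 2, regions = c("cingulate", "cerebellum_wm"),
                      seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$ground_truth), 2 * 2 * 2)
  # zero variability and zero noise: all subjects and sessions identical
  cfg0 <- study_config(n_subjects = 3, regions = c("cingulate", "cerebellum_wm"),
                       bs_cv = 0, global_cv = 0, ws_cv = 0, alpha = 0,
                       blood_noise = 0, seed = 1)
  s0 <- simulate_study(cfg0)
  v1 <- s0$subjects$subject1$test$tac$values
  for (sn in names(s0$subjects)) for (sess in c("test", "retest"))
    expect_identical(s0$subjects[[sn]][[sess]]$tac$values, v1)
  # ground-truth DVR at zero CV is the preset Vt ratio
  gt <- s0$ground_truth
  vt_cg <- gt$vt[gt$region == "cingulate"][1]
  vt_wm <- gt$vt[gt$region == "cerebellum_wm"][1]
  expect_equal(vt_cg / vt_wm, preset_row("cingulate")$vt /
                 preset_row("cerebellum_wm")$vt, tolerance = 1e-12)
  expect_error(study_config(n_subjects = 0), "at least one subject")
  expect_error(study_config(bs_cv = -0.1), "non-negative")
  expect_error(study_config(regions = "nonexistent"), "unknown region preset")
})

test_that("noise-free simulate-fit round trip recovers DVR for every preset", {
  # end-to-end consistency of generator + all three estimators, Vb = 0;
  # for kinetics this slow the reference-Logan needs its k2' term to
  # stay unbiased at t* = 60, so the true reference efflux is supplied
  ref <- preset_row("cerebellum_wm")
  for (nm in c("cingulate", "raphe_dorsal", "frontal_wm")) {
    roi <- preset_row(nm)
    dvr_truth <- roi$vt / ref$vt
    pair <- make_pair_tac(roi, ref)
    inv <- dvr_from_vt(fit_1tc(pair, fx$inp, region = "roi")$vt,
                       fit_1tc(pair, fx$inp, region = "ref")$vt)
    expect_lt(abs(inv / dvr_truth - 1), 0.03)
    expect_lt(abs(fit_srtm(pair, "roi", "ref")$dvr / dvr_truth - 1), 0.03)
    lr <- logan_ref(pair, "roi", "ref", 60, k2_prime = ref$k2)
    expect_lt(abs(lr$dvr / dvr_truth - 1), 0.03)
  }
})
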