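test_that("fwb estimation averages per-sample plasma/whole-blood ratios", {
  bd <- blood_dataset(time_wb = c(1, 2), cwb = c(2, 4),
                      time_cp = c(1, 2), cp = c(4, 6))
  r <- estimate_fwb(bd)
  expect_equal(r$ratios, c(2, 1.5))
  expect_equal(r$mean, 1.75)
  same <- blood_dataset(time_wb = 1:4, cwb = c(5, 8, 6, 3),
                        time_cp = 1:4, cp = c(5, 8, 6, 3))
  expect_equal(estimate_fwb(same)$mean, 1)
  expect_equal(estimate_fwb(same)$sd, 0)
  # invariant under common rescaling of both curves
  sc <- blood_dataset(time_wb = 1:4, cwb = 7.3 * c(5, 8, 6, 3),
                      time_cp = 1:4, cp = 7.3 * c(5, 8, 6, 3))
  expect_equal(estimate_fwb(sc)$mean, estimate_fwb(same)$mean)
  bad <- blood_dataset(time_wb = c(1, 2), cwb = c(0, 4),
                       time_cp = c(1, 2), cp = c(1, 2))
  expect_error(estimate_fwb(bad), "non-positive whole-blood")
  expect_error(estimate_fwb(blood_dataset(time_wb = 1, cwb = 1,
                                          time_cp = 1, cp = 1)),
               "at least 2")
})

test_that("cohort-mean fwb of the reference table reproduces the published 1.79", {
  ref <- f13640_blood_reference()
  expect_equal(mean(ref$fwb), 1.79, tolerance = 0.005)
})

test_that("parent-fraction model fits and recovers known parameters", {
  # noise-free forward-generated samples at the metabolite sampling times
  t5 <- c(2, 10, 30, 90, 205)
  truth <- c(A0 = 0.10, T = 20)
  y <- 1 - truth["A0"] * (1 - exp(-log(2) * t5 / truth["T"]))
  fit <- fit_parent_fraction(t5, y)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-6)
  # degenerate all-parent case: plateau collapses, T is meaningless
  flat <- fit_parent_fraction(t5, rep(1, 5))
  expect_equal(flat$A0, 0, tolerance = 1e-8)
  expect_true(flat$plateau_unidentifiable)
  expect_error(fit_parent_fraction(c(1, 2), c(1, 0.9)), "at least 3")
})

test_that("fitted parent-fraction curve has the one-exponential properties", {
  fit <- structure(list(A0 = 0.046, T = 9.06), class = "parent_fraction_fit")
  expect_equal(predict(fit, 0), 1)
  expect_equal(predict(fit, 1e7), 1 - 0.046, tolerance = 1e-9)
  # half-rise: at t = T the drop is half of A0
  expect_equal(predict(fit, 9.06), 1 - 0.046 / 2)
  expect_error(predict(fit, -1), "negative")
  # monotone non-increasing from 1 toward the plateau
  v <- predict(fit, seq(0, 300, by = 1))
  expect_true(all(diff(v) <= 0))
  expect_true(all(v >= 1 - 0.046 & v <= 1))
})

test_that("free-fraction builder supports time-varying and late-mean modes", {
  t5 <- c(2, 10, 30, 90, 205)
  v5 <- c(0.0048, 0.0082, 0.0114, 0.0190, 0.0161)
  f <- build_fp(t5, v5)
  expect_equal(f(t5), v5)                       # interpolation nodes
  expect_equal(f(0), v5[1])                     # constant extrapolation
  expect_equal(f(300), v5[5])
  g <- build_fp(t5, v5, mode = "late-mean", late_threshold = 30)
  expect_equal(attr(g, "value"), mean(v5[3:5]))
  expect_equal(g(c(1, 100)), rep(mean(v5[3:5]), 2))
  cst <- build_fp(t5, rep(0.02, 5))
  expect_equal(cst(c(0, 50, 300)), rep(0.02, 3))
  expect_error(build_fp(t5, v5, mode = "late-mean", late_threshold = 1000),
               "no fp samples")
})

test_that("assembled AIF is the product of its corrected components", {
  # direct product at one grid point
  bd <- blood_dataset(time_wb = c(1, 50, 100, 200), cwb = rep(100, 4),
                      time_cp = c(1, 50, 100, 200), cp = rep(179, 4))
  pf_fit <- structure(list(A0 = 0.046, T = 9.06),
                      class = "parent_fraction_fit")
  fp_fun <- build_fp(c(1, 200), c(0.018, 0.018))
  inp <- assemble_aif(bd, pf_fit, fp_fun, grid = c(0, 50, 100, 150))
  i <- which(inp$grid == 100)
  ppf100 <- predict(pf_fit, 100)
  expect_equal(inp$aif[i], ppf100 * 1.79 * 100 * 0.018)
  expect_equal(inp$ppf[i], ppf100)
  # identity components give back the whole-blood curve
  unit_pf <- fit_parent_fraction(c(1, 50, 100), rep(1, 3))
  unit_fp <- build_fp(c(1, 200), c(1, 1))
  inp1 <- assemble_aif(bd, unit_pf, unit_fp, grid = c(0, 50, 100, 150),
                       fwb = 1)
  expect_equal(inp1$aif, inp1$cwb, tolerance = 1e-9)
})

test_that("AIF reconstruction from noise-free generated blood matches the closed form", {
  bd <- sample_blood(fx$profile, noise = 0, seed = 1)
  pf_fit <- fit_parent_fraction(bd$time_pf, bd$pf)
  fp_fun <- build_fp(bd$time_fp, bd$fp)
  grid <- sort(unique(c(bd$time_wb, seq(0, 205, by = 2.5))))
  inp <- assemble_aif(bd, pf_fit, fp_fun, grid = grid)
  truth <- generate_input_profile(fx$profile, grid = grid)
  at <- match(bd$time_wb, grid)
  expect_equal(inp$aif[at], truth$aif[at], tolerance = 1e-6)
  expect_equal(inp$fwb, fx$profile$fwb, tolerance = 1e-12)
  # non-negative everywhere, zero before tracer appearance
  expect_true(all(inp$aif >= 0))
  expect_true(all(inp$aif[grid < fx$profile$delay] == 0))
  # extrapolation guard
  expect_error(assemble_aif(bd, pf_fit, fp_fun, grid = seq(0, 300, 5)),
               "past the last blood sample")
})

test_that("noise-free parent-fraction fit brackets its samples", {
  bd <- sample_blood(fx$profile, noise = 0, seed = 1)
  fit <- fit_parent_fraction(bd$time_pf, bd$pf)
  pred <- predict(fit, bd$time_pf)
  expect_true(all(pred <= 1 + 1e-9 & pred >= min(bd$pf) - 1e-6))
})
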