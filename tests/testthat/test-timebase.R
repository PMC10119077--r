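test_that("dual-part schedule construction matches the acquisition protocol", {
  sch <- default_schedule()
  expect_equal(nrow(sch), 32)
  expect_equal(sum(sch$part == "PART1"), 24)
  expect_equal(sum(sch$part == "PART2"), 8)
  p1 <- sch[sch$part == "PART1", ]
  p2 <- sch[sch$part == "PART2", ]
  expect_identical(sum(p1$end - p1$start), 5400)   # 90 min
  expect_identical(sum(p2$end - p2$start), 4500)   # 75 min
  expect_equal(min(p1$start), 0)
  expect_equal(max(p1$end), 5400)
  expect_equal(min(p2$start), 9000)                # 150 min post injection
  expect_equal(max(p2$end), 13500)                 # 225 min
})

test_that("schedule invariants are enforced", {
  expect_error(frame_schedule(c(60, -30)), "non-positive")
  expect_error(frame_schedule(c(60, 0)), "non-positive")
  expect_error(frame_schedule(c(60, 60), c(60), part2_start = 90),
               "schedule conflict")
  one <- frame_schedule(60)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(0, 60))
})

test_that("frame mid-times are interval midpoints in minutes", {
  expect_equal(frame_midtimes(frame_schedule(15)), 0.125)
  mt <- frame_midtimes(default_schedule())
  expect_equal(mt[24], 85)            # last frame of part 1: [80, 90] min
  expect_true(all(diff(mt) > 0))
  empty <- default_schedule()[0, ]
  expect_identical(frame_midtimes(empty), numeric(0))
})

test_that("decay correction has the half-life doubling and round-trip properties", {
  dc <- decay_constants()
  expect_equal(dc$lambda * dc$half_life, log(2), tolerance = 1e-12)
  expect_equal(decay_correct(5, 30, dc, reference_time = 30), 5)
  expect_equal(decay_correct(5, dc$half_life, dc, reference_time = 0), 10)
  set.seed(11)
  for (i in 1:5) {
    v <- stats::runif(20, 0, 100)
    t <- stats::runif(20, 0, 225)
    back <- decay_correct(decay_correct(v, t, dc), t, dc, uncorrect = TRUE)
    expect_equal(back, v, tolerance = 1e-12)
  }
})

test_that("tac validates dimensions and the noise floor", {
  sch <- frame_schedule(c(60, 60, 60))
  expect_error(tac(sch, matrix(1, 2, 1)), "one row per frame")
  expect_error(tac(sch, matrix(1, 3, 2), regions = "a"),
               "one column per region")
  expect_error(tac(sch, matrix(-100, 3, 1)), "noise floor")
  expect_silent(tac(sch, matrix(-1, 3, 1)))  # small dips are data
})

test_that("session concatenation unions schedules, keeps values, preserves integrals", {
  d1 <- c(rep(15, 8), rep(60, 3), rep(120, 5), 300, rep(600, 7))
  d2 <- c(rep(600, 7), 300)
  s1 <- frame_schedule(d1)
  s2 <- frame_schedule(d2)
  s2$start <- s2$start + 9000; s2$end <- s2$end + 9000
  set.seed(3)
  t1 <- tac(s1, matrix(runif(24 * 2, 1, 10), 24, 2), c("a", "b"))
  t2 <- tac(s2, matrix(runif(8 * 2, 1, 10), 8, 2), c("a", "b"))
  cc <- concatenate_sessions(t1, t2)
  expect_equal(nrow(cc$schedule), 32)
  expect_identical(cc$values, rbind(t1$values, t2$values))
  # no frames inside the break
  expect_false(any(cc$schedule$start >= 5400 & cc$schedule$start < 9000))
  # per-part trapezoidal integrals unchanged
  int_part <- function(x, part) {
    i <- x$schedule$part == part
    mt <- frame_midtimes(x$schedule)[i]
    sum(diff(mt) * (utils::head(x$values[i, 1], -1) +
                      utils::tail(x$values[i, 1], -1)) / 2)
  }
  expect_equal(int_part(cc, "PART1"), int_part(t1, "PART1"))
  i2 <- int_part(t2, "PART1")  # t2's frames carry PART1 labels pre-merge
  expect_equal(int_part(cc, "PART2"), i2)
  # degenerate and error cases
  empty2 <- tac(s2[0, ], matrix(0, 0, 2), c("a", "b"))
  expect_identical(concatenate_sessions(t1, empty2), t1)
  expect_error(concatenate_sessions(t2, t1), "schedule conflict")
  t2b <- tac(s2, t2$values, c("a", "c"))
  expect_error(concatenate_sessions(t1, t2b), "region lists differ")
  t2c <- tac(s2, t2$values, c("a", "b"), reference_time = 5)
  expect_error(concatenate_sessions(t1, t2c), "reference times")
})
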