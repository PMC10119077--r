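# Frame, time and decay bookkeeping shared by all modelling stages.
#
# Internal convention: all model-facing times are minutes post injection;
# file formats and frame-schedule constructors carry seconds (frame tables
# are conventionally listed in seconds) and convert at the boundary.

#' Build a dual-part PET frame schedule
#'
#' Constructs the timing of a dynamic acquisition carried out in one or two
#' parts (e.g. a 90-min scan, a break outside the camera, then a 75-min
#' scan).  Frames within a part are contiguous; the gap between parts
#' contains no frames.
#'
#' @param part1_durations Frame durations of the first part, in seconds.
#' @param part2_durations Frame durations of the second part, in seconds
#'   (may be empty for a single-session schedule).
#' @param part2_start Start time of the second part in seconds post
#'   injection; must not fall inside part 1.
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `start`, `end` (seconds, half-open intervals `[start, end)`) and
#'   `part` (`"PART1"` or `"PART2"`).
#' @examples
#' # 24-frame first part + 8-frame second part starting at 150 min
#' sch <- frame_schedule(
#'   c(rep(15, 8), rep(60, 3), rep(120, 5), 300, rep(600, 7)),
#'   c(rep(600, 7), 300), part2_start = 9000)
#' nrow(sch)  # 32
#' @export
frame_schedule <- function(part1_durations, part2_durations = numeric(),
                           part2_start = NULL) {
  part1_durations <- as.numeric(part1_durations)
  part2_durations <- as.numeric(part2_durations)
  if (length(part1_durations) == 0L)
    stop("schedule needs at least one frame in part 1")
  if (any(!is.finite(part1_durations)) || any(part1_durations <= 0))
    stop("non-positive or non-finite frame duration in part 1")
  start1 <- cumsum(c(0, part1_durations))
  end1 <- start1[-1]
  start1 <- start1[-length(start1)]
  if (length(part2_durations) > 0L) {
    if (any(!is.finite(part2_durations)) || any(part2_durations <= 0))
      stop("non-positive or non-finite frame duration in part 2")
    if (is.null(part2_start)) part2_start <- max(end1)
    if (!is.finite(part2_start) || part2_start < max(end1))
      stop("schedule conflict: part2_start lies inside part 1")
    start2 <- part2_start + cumsum(c(0, part2_durations))
    end2 <- start2[-1]
    start2 <- start2[-length(start2)]
    out <- data.frame(start = c(start1, start2), end = c(end1, end2),
                      part = c(rep("PART1", length(start1)),
                               rep("PART2", length(start2))),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(start = start1, end = end1,
                      part = rep("PART1", length(start1)),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("frame_schedule", "data.frame")
  validate_frame_schedule(out)
  out
}

validate_frame_schedule <- function(x) {
  stopifnot(inherits(x, "frame_schedule"))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$end <= x$start)) stop("frame with non-positive duration")
  if (is.unsorted(x$start, strictly = TRUE)) stop("frame starts not strictly increasing")
  if (any(x$start[-1] < x$end[-nrow(x)])) stop("schedule conflict: overlapping frames")
  p <- x$part
  if (any(p == "PART2") && any(p == "PART1") &&
      min(which(p == "PART2")) < max(which(p == "PART1")))
    stop("all PART1 frames must precede PART2 frames")
  for (pp in unique(p)) {
    i <- which(p == pp)
    if (length(i) > 1 && any(abs(x$start[i][-1] - x$end[i][-length(i)]) > 1e-9))
      stop("frames within a part must be contiguous")
  }
  invisible(x)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("PET frame schedule: %d frames", nrow(x)))
  if (nrow(x)) {
    parts <- table(x$part)
    cat(sprintf(" (%s), spanning %.1f-%.1f min\n",
                paste(sprintf("%s: %d", names(parts), parts), collapse = ", "),
                min(x$start) / 60, max(x$end) / 60))
  } else cat(" (empty)\n")
  invisible(x)
}

#' Frame mid-times in minutes
#'
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of frame interval midpoints, minutes post injection.
#' @export
frame_midtimes <- function(schedule) {
  validate_frame_schedule(schedule)
  (schedule$start + schedule$end) / 2 / 60
}

#' Frame durations in minutes
#' @param schedule A [frame_schedule()].
#' @export
frame_durations <- function(schedule) {
  validate_frame_schedule(schedule)
  (schedule$end - schedule$start) / 60
}

#' Physical decay constants for a radionuclide
#'
#' @param half_life Isotope half-life in minutes.  Defaults to fluorine-18
#'   (109.771 min).
#' @return List with `half_life` (min) and `lambda` (= ln 2 / half-life,
#'   per minute), class `decay_constants`.
#' @export
decay_constants <- function(half_life = 109.771) {
  if (!is.finite(half_life) || half_life <= 0) stop("half_life must be positive")
  structure(list(half_life = half_life, lambda = log(2) / half_life),
            class = "decay_constants")
}

#' Decay-correct (or uncorrect) activity values to a reference time
#'
#' Multiplies each value by `exp(lambda * (t - reference_time))`, the
#' standard correction that re-expresses measured activity as if no decay
#' had occurred since `reference_time`.  With `uncorrect = TRUE` the
#' inverse factor is applied, recovering measured activities.
#'
#' @param values Activity values (any shape; recycled against `times`).
#' @param times Times in minutes at which the values were measured.
#' @param constants A [decay_constants()] object.
#' @param reference_time Reference time in minutes (default 0, scan start).
#' @param uncorrect Apply the inverse correction.
#' @export
decay_correct <- function(values, times, constants = decay_constants(),
                          reference_time = 0, uncorrect = FALSE) {
  if (any(!is.finite(times)) || !is.finite(reference_time))
    stop("non-finite times in decay correction")
  fac <- exp(constants$lambda * (times - reference_time))
  if (uncorrect) values / fac else values * fac
}

#' Regional time-activity curves
#'
#' Couples a frame schedule with a per-frame, per-region table of
#' decay-corrected activity concentrations.
#'
#' @param schedule A [frame_schedule()].
#' @param values Numeric matrix, `nrow(schedule)` rows by one column per
#'   region (a vector is accepted for a single region), in kBq/mL.
#' @param regions Character vector of region names.
#' @param reference_time Decay-correction reference time in minutes
#'   (0 = start of the first acquisition part).
#' @param noise_floor Most negative admissible value (frames of a noisy
#'   reconstruction can dip slightly below zero); values below it error.
#' @return Object of class `tac`.
#' @export
tac <- function(schedule, values, regions = NULL, reference_time = 0,
                noise_floor = -5) {
  validate_frame_schedule(schedule)
  values <- as.matrix(values)
  if (is.null(regions)) {
    regions <- colnames(values)
    if (is.null(regions)) regions <- paste0("region", seq_len(ncol(values)))
  }
  if (nrow(values) != nrow(schedule))
    stop("value table must have one row per frame")
  if (ncol(values) != length(regions))
    stop("value table must have one column per region")
  if (any(!is.finite(values))) stop("non-finite activity values")
  if (any(values < noise_floor))
    stop("activity below the configured noise floor")
  colnames(values) <- regions
  structure(list(schedule = schedule, values = values, regions = regions,
                 reference_time = reference_time),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curves: %d frames x %d regions (kBq/mL), ref time %g min\n",
              nrow(x$schedule), length(x$regions), x$reference_time))
  cat("  regions:", paste(utils::head(x$regions, 8), collapse = ", "),
      if (length(x$regions) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.tac <- function(x, regions = x$regions, log = "", ...) {
  mt <- frame_midtimes(x$schedule)
  v <- x$values[, regions, drop = FALSE]
  graphics::matplot(mt, v, type = "b", pch = 1, lty = 1, log = log,
                    xlab = "time (min)", ylab = "activity (kBq/mL)", ...)
  graphics::legend("topright", legend = regions, col = seq_along(regions),
                   lty = 1, bty = "n", cex = 0.7)
  invisible(x)
}

#' Concatenate two single-session TACs into one dual-part curve
#'
#' Joins an early and a late acquisition of the same subject into one
#' dynamic curve.  Both inputs must share region labels and the same
#' decay-correction reference time (the TAC-level stand-in for image
#' alignment between parts); the second must lie entirely after the first.
#'
#' @param tac1,tac2 Objects of class `tac`.  `tac2` may have an empty
#'   schedule, in which case `tac1` is returned unchanged.
#' @return A `tac` whose schedule is the union, frames of `tac1` labelled
#'   PART1 and those of `tac2` PART2; values are unchanged.
#' @export
concatenate_sessions <- function(tac1, tac2) {
  stopifnot(inherits(tac1, "tac"), inherits(tac2, "tac"))
  if (nrow(tac2$schedule) == 0L) return(tac1)
  if (!identical(tac1$regions, tac2$regions))
    stop("region lists differ between sessions")
  if (!isTRUE(all.equal(tac1$reference_time, tac2$reference_time)))
    stop("sessions are decay-corrected to different reference times")
  if (min(tac2$schedule$start) < max(tac1$schedule$end))
    stop("schedule conflict: second part overlaps the first")
  sch <- rbind(as.data.frame(tac1$schedule), as.data.frame(tac2$schedule))
  sch$part <- c(rep("PART1", nrow(tac1$schedule)),
                rep("PART2", nrow(tac2$schedule)))
  class(sch) <- c("frame_schedule", "data.frame")
  validate_frame_schedule(sch)
  tac(sch, rbind(tac1$values, tac2$values), tac1$regions,
      reference_time = tac1$reference_time)
}

# trapezoidal integral of y(x); exact for piecewise-linear y
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# cumulative trapezoidal integral, same length as x
cumtrapz <- function(x, y) {
  if (length(x) < 2) return(numeric(length(x)))
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}
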