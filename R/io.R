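# Plain-text file formats.  TSV with '#'-prefixed metadata lines for
# curves; JSON sidecars for nested results.  On-disk times are seconds
# and fractions are percent; in memory, minutes and fractions.

.read_meta <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#\\s*", "", m)
    if (grepl("=", kv)) {
      k <- trimws(sub("=.*", "", kv))
      v <- trimws(sub("^[^=]*=", "", kv))
      meta[[k]] <- v
    }
  }
  list(meta = meta, n_skip = length(meta_lines))
}

.write_meta <- function(path, meta) {
  writeLines(sprintf("# %s=%s", names(meta),
                     vapply(meta, as.character, character(1))), path)
}

#' Write regional TACs to TSV
#'
#' Format: metadata lines (`# reference_time_s=`, `# units=kBq/mL`,
#' `# part_boundary_s=`), then a header
#' `frame_start_s  frame_end_s  <region1> ...` and one row per frame.
#'
#' @param x A [tac()].
#' @param path Output file.
#' @export
write_tac_tsv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  boundary <- if (any(x$schedule$part == "PART2"))
    min(x$schedule$start[x$schedule$part == "PART2"]) else max(x$schedule$end)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# reference_time_s=%g", x$reference_time * 60),
               "# units=kBq/mL",
               sprintf("# part_boundary_s=%g", boundary)), con)
  df <- data.frame(frame_start_s = x$schedule$start,
                   frame_end_s = x$schedule$end, x$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read regional TACs from TSV
#'
#' Inverse of [write_tac_tsv()]; validates the frame table and raises
#' parse errors naming the offending content.
#'
#' @param path Input file.
#' @return A [tac()].
#' @export
read_tac_tsv <- function(path) {
  mi <- .read_meta(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = mi$n_skip,
                          check.names = FALSE)
  need <- c("frame_start_s", "frame_end_s")
  if (!all(need %in% names(df)))
    stop("TAC file ", path, " lacks required columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  units <- mi$meta[["units"]]
  if (!is.null(units) && units != "kBq/mL")
    stop("TAC file ", path, ": unsupported units '", units, "'")
  boundary <- as.numeric(mi$meta[["part_boundary_s"]] %||% Inf)
  part <- ifelse(df$frame_start_s >= boundary, "PART2", "PART1")
  sch <- data.frame(start = df$frame_start_s, end = df$frame_end_s,
                    part = part, stringsAsFactors = FALSE)
  class(sch) <- c("frame_schedule", "data.frame")
  ok <- try(validate_frame_schedule(sch), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("TAC file ", path, ": invalid frame table (",
         trimws(conditionMessage(attr(ok, "condition"))), ")")
  vals <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  ref_s <- as.numeric(mi$meta[["reference_time_s"]] %||% 0)
  tac(sch, vals, regions = colnames(vals), reference_time = ref_s / 60)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a blood dataset to a directory
#'
#' Writes `blood.tsv` (`time_s`, `cwb_kBq_mL`, optional `cp_kBq_mL` with
#' NA where plasma was not separated), `parent_fraction.tsv` and `fp.tsv`
#' (`time_s`, `fraction_percent`).
#'
#' @param x A [blood_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_blood_dir <- function(x, dir) {
  stopifnot(inherits(x, "blood_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cp <- rep(NA_real_, length(x$time_wb))
  if (!is.null(x$time_cp)) cp[match(x$time_cp, x$time_wb)] <- x$cp
  utils::write.table(
    data.frame(time_s = x$time_wb * 60, cwb_kBq_mL = x$cwb, cp_kBq_mL = cp),
    file.path(dir, "blood.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  wfrac <- function(t, v, f) utils::write.table(
    data.frame(time_s = t * 60, fraction_percent = v * 100),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$time_pf)) wfrac(x$time_pf, x$pf, "parent_fraction.tsv")
  if (!is.null(x$time_fp)) wfrac(x$time_fp, x$fp, "fp.tsv")
  invisible(dir)
}

#' Read a blood dataset written by [write_blood_dir()]
#' @param dir Directory containing `blood.tsv` (and optional fraction
#'   files).
#' @export
read_blood_dir <- function(dir) {
  b <- utils::read.table(file.path(dir, "blood.tsv"), header = TRUE, sep = "\t")
  rfrac <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.table(p, header = TRUE, sep = "\t")
  }
  pf <- rfrac("parent_fraction.tsv"); fp <- rfrac("fp.tsv")
  has_cp <- "cp_kBq_mL" %in% names(b) && any(!is.na(b$cp_kBq_mL))
  blood_dataset(
    time_wb = b$time_s / 60, cwb = b$cwb_kBq_mL,
    time_cp = if (has_cp) b$time_s[!is.na(b$cp_kBq_mL)] / 60,
    cp = if (has_cp) b$cp_kBq_mL[!is.na(b$cp_kBq_mL)],
    time_pf = if (!is.null(pf)) pf$time_s / 60,
    pf = if (!is.null(pf)) pf$fraction_percent / 100,
    time_fp = if (!is.null(fp)) fp$time_s / 60,
    fp = if (!is.null(fp)) fp$fraction_percent / 100)
}

#' Write an assembled input function to TSV
#'
#' Columns `time_s`, `aif_kBq_mL`, `cwb_kBq_mL`; metadata lines carry
#' fwb, the parent-fraction fit and the fp mode.
#'
#' @param x An `input_function`.
#' @param path Output file.
#' @param pf_fit Optional [fit_parent_fraction()] result for metadata.
#' @export
write_aif_tsv <- function(x, path, pf_fit = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sprintf("# fwb=%.6g", x$fwb),
            sprintf("# fp_mode=%s", x$fp_mode %||% "unknown"))
  if (!is.null(pf_fit))
    meta <- c(meta, sprintf("# A0=%.6g", pf_fit$A0),
              sprintf("# T_min=%.6g", pf_fit$T))
  writeLines(meta, con)
  utils::write.table(
    data.frame(time_s = x$grid * 60, aif_kBq_mL = x$aif,
               cwb_kBq_mL = x$cwb),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic study to a directory tree
#'
#' Layout: `subject<i>/<session>/tacs.tsv` plus the blood files of
#' [write_blood_dir()], with `ground_truth.json` and the effective
#' configuration at the root.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "pet_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sname in names(study$subjects)) {
    for (session in names(study$subjects[[sname]])) {
      d <- file.path(dir, sname, session)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_tac_tsv(study$subjects[[sname]][[session]]$tac,
                    file.path(d, "tacs.tsv"))
      write_blood_dir(study$subjects[[sname]][[session]]$blood, d)
    }
  }
  jsonlite::write_json(study$ground_truth, file.path(dir, "ground_truth.json"),
                       digits = NA, dataframe = "rows")
  cfg <- study$config
  jsonlite::write_json(
    list(n_subjects = cfg$n_subjects, regions = cfg$regions,
         bs_cv = cfg$bs_cv, global_cv = cfg$global_cv, ws_cv = cfg$ws_cv,
         alpha = cfg$alpha,
         blood_noise = cfg$blood_noise, seed = cfg$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#' @param dir Study directory.
#' @return List with `subjects` (per subject/session `tac` and `blood`)
#'   and `ground_truth`.
#' @export
read_study <- function(dir) {
  subjects <- list()
  for (sd in sort(list.dirs(dir, recursive = FALSE))) {
    sname <- basename(sd)
    if (!grepl("^subject", sname)) next
    sess <- list()
    for (session in c("test", "retest")) {
      d <- file.path(sd, session)
      if (!dir.exists(d)) next
      sess[[session]] <- list(tac = read_tac_tsv(file.path(d, "tacs.tsv")),
                              blood = read_blood_dir(d))
    }
    subjects[[sname]] <- sess
  }
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path))
    jsonlite::fromJSON(gt_path) else NULL
  list(subjects = subjects, ground_truth = gt)
}
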