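# End-to-end orchestration: configuration, logging, and the full
# quantification pipeline (AIF build -> invasive fits -> reference fits
# -> DVR tables -> test-retest report -> cross-method regression).

.known_models <- c("1TC", "2TC", "LOGAN", "SRTM", "LREF")

#' Pipeline run configuration
#'
#' Validates and normalizes the settings of a full pipeline run.  Unknown
#' keys are rejected.
#'
#' @param study_dir Directory holding a study written by [write_study()]
#'   (may be `NULL` when an in-memory study is passed to
#'   [run_pipeline()]).
#' @param out_dir Output directory.
#' @param models Subset of `"1TC"`, `"2TC"`, `"LOGAN"`, `"SRTM"`,
#'   `"LREF"` (case-insensitive).
#' @param ref_region Reference region name for reference models and DVRs.
#' @param fp_mode `"time-varying"` or `"late-mean"` free-fraction
#'   handling.
#' @param fp_late_threshold Minutes; late-mean threshold.
#' @param t_star Logan-type start time in minutes, or `"auto"`.
#' @param k2_prime Reference efflux rate for LREF: `NULL` (omit the
#'   term), a number (1/min), or `"srtm"` to use the median `k2 / R1`
#'   over all SRTM fits of the run (the classic two-pass refinement;
#'   requires SRTM among the models).
#' @param weights Frame weighting scheme, `"frame-decay"` or
#'   `"uniform"`.
#' @param seed Integer seed echoed into outputs (the pipeline itself is
#'   deterministic).
#' @param ... Unknown keys: rejected with an error.
#' @export
run_config <- function(study_dir = NULL, out_dir = tempfile("petkin_run_"),
                       models = c("1TC", "SRTM", "LREF"),
                       ref_region = "cerebellum_wm",
                       fp_mode = "time-varying", fp_late_threshold = 30,
                       t_star = 60, k2_prime = NULL,
                       weights = "frame-decay", seed = 1, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  models <- toupper(models)
  bad <- setdiff(models, .known_models)
  if (length(bad)) stop("unknown models: ", paste(bad, collapse = ", "))
  if (!fp_mode %in% c("time-varying", "late-mean"))
    stop("fp_mode must be 'time-varying' or 'late-mean'")
  if (!weights %in% c("frame-decay", "uniform"))
    stop("unknown weighting scheme: ", weights)
  if (identical(k2_prime, "srtm") && !"SRTM" %in% models)
    stop("k2_prime = 'srtm' requires SRTM among the models")
  if (!is.null(k2_prime) && !identical(k2_prime, "srtm") &&
      (!is.numeric(k2_prime) || k2_prime <= 0))
    stop("k2_prime must be NULL, a positive rate, or 'srtm'")
  structure(list(study_dir = study_dir, out_dir = out_dir, models = models,
                 ref_region = ref_region, fp_mode = fp_mode,
                 fp_late_threshold = fp_late_threshold, t_star = t_star,
                 k2_prime = k2_prime, weights = weights,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# polynomial rolling hash of the effective configuration, for provenance
.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.invasive_requested <- function(models) any(models %in% c("1TC", "2TC", "LOGAN"))

# build the corrected input function for one session's blood data
.session_aif <- function(blood, config, t_end) {
  fwb <- estimate_fwb(blood)
  pf_fit <- fit_parent_fraction(blood$time_pf, blood$pf)
  fp_fun <- build_fp(blood$time_fp, blood$fp, mode = config$fp_mode,
                     late_threshold = config$fp_late_threshold)
  grid <- default_aif_grid(t_end)
  list(aif = assemble_aif(blood, pf_fit, fp_fun, grid, fwb = fwb$mean),
       pf_fit = pf_fit, fwb = fwb)
}

.fit_row <- function(fit, subject, session) {
  data.frame(subject = subject, session = session, model = fit$model,
             region = fit$region,
             K1 = unname(fit$par["K1"])[1] %||% NA_real_,
             k2 = unname(fit$par["k2"])[1] %||% NA_real_,
             k3 = unname(fit$par["k3"])[1] %||% NA_real_,
             k4 = unname(fit$par["k4"])[1] %||% NA_real_,
             Vb = unname(fit$par["Vb"])[1] %||% NA_real_,
             R1 = unname(fit$par["R1"])[1] %||% NA_real_,
             vt = fit$vt %||% NA_real_, bp = fit$bp %||% NA_real_,
             dvr = fit$dvr %||% NA_real_,
             ssr = fit$gof$ssr %||% NA_real_,
             aic = fit$gof$aic %||% NA_real_,
             r2 = fit$r2 %||% NA_real_,
             flags = paste(fit$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Run the full quantification pipeline
#'
#' Executes, per subject and session: input-function construction from
#' the blood data (when any invasive model is requested), invasive
#' kinetic fits, reference-model fits, and DVR computation against the
#' configured reference region; then, across subjects: the test-retest
#' report per reference method and the per-subject linear regression of
#' reference-model DVRs against one-tissue DVRs.  All tables are written
#' to `config$out_dir` as TSV with a JSON sidecar carrying the effective
#' settings and a structured log with per-stage timing.
#'
#' @param config A [run_config()].
#' @param study Optional in-memory [simulate_study()] result or
#'   [read_study()] list; read from `config$study_dir` when `NULL`.
#' @return Invisibly, a list with `fits` (long table of all fits), `dvr`
#'   (per subject x session x region x method), `trt` (named list of
#'   [trt_report()]s), `regression` (per-subject regression table) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, study = NULL) {
  stopifnot(inherits(config, "run_config"))
  t_start <- proc.time()[["elapsed"]]
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t_start,
                   sprintf(fmt, ...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  if (is.null(study)) {
    if (is.null(config$study_dir) || !dir.exists(config$study_dir))
      stop("config error: study_dir does not exist")
    study <- read_study(config$study_dir)
  }
  subjects <- study$subjects
  if (!length(subjects)) stop("config error: study contains no subjects")
  if (.invasive_requested(config$models)) {
    has_blood <- vapply(subjects, function(s)
      all(vapply(s, function(ss) !is.null(ss$blood$time_cp), logical(1))),
      logical(1))
    if (!all(has_blood))
      stop("config error: invasive models requested but blood data are missing")
  }
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say("pipeline start: %d subjects, models %s, reference '%s'",
      length(subjects), paste(config$models, collapse = "+"),
      config$ref_region)

  # pass 1: input functions, invasive models and SRTM
  fits <- list()
  for (sname in names(subjects)) {
    for (session in names(subjects[[sname]])) {
      dat <- subjects[[sname]][[session]]
      x <- dat$tac
      if (!config$ref_region %in% x$regions)
        stop("config error: reference region '", config$ref_region,
             "' not among TAC regions")
      t_end <- max(x$schedule$end) / 60
      aif <- NULL
      if (.invasive_requested(config$models))
        aif <- .session_aif(dat$blood, config, t_end)$aif
      roi_regions <- setdiff(x$regions, config$ref_region)
      sess_fits <- list()
      for (m in setdiff(config$models, "LREF")) {
        regions_m <- if (m == "SRTM") roi_regions else x$regions
        for (r in regions_m) {
          fit <- switch(m,
            "1TC" = fit_1tc(x, aif, region = r, weights = config$weights),
            "2TC" = fit_2tc(x, aif, region = r, weights = config$weights),
            "LOGAN" = logan_vt(x, aif, region = r, t_star = config$t_star),
            "SRTM" = fit_srtm(x, region = r, ref_region = config$ref_region,
                              weights = config$weights))
          sess_fits[[length(sess_fits) + 1]] <- .fit_row(fit, sname, session)
        }
      }
      if (length(sess_fits)) {
        fits[[length(fits) + 1]] <- do.call(rbind, sess_fits)
        say("fitted %s/%s: %d fits", sname, session,
            nrow(fits[[length(fits)]]))
      }
    }
  }
  fits <- if (length(fits)) do.call(rbind, fits) else NULL

  # resolve the reference efflux rate for the reference Logan
  k2p <- config$k2_prime
  if (identical(k2p, "srtm")) {
    sr <- fits[fits$model == "SRTM", ]
    k2p <- stats::median(sr$k2 / sr$R1, na.rm = TRUE)
    say("k2' from SRTM fits: median %.4f 1/min over %d fits", k2p, nrow(sr))
  }

  # pass 2: reference Logan with the resolved k2'
  if ("LREF" %in% config$models) {
    for (sname in names(subjects)) {
      for (session in names(subjects[[sname]])) {
        x <- subjects[[sname]][[session]]$tac
        rows <- lapply(setdiff(x$regions, config$ref_region), function(r)
          .fit_row(logan_ref(x, region = r, ref_region = config$ref_region,
                             t_star = config$t_star, k2_prime = k2p),
                   sname, session))
        fits <- rbind(fits, do.call(rbind, rows))
      }
    }
    say("reference Logan fits complete")
  }

  # DVR per subject x session x region x method
  dvr_rows <- list()
  for (m in intersect(config$models, c("1TC", "2TC", "LOGAN"))) {
    sub <- fits[fits$model == m, ]
    for (key in unique(paste(sub$subject, sub$session))) {
      ss <- sub[paste(sub$subject, sub$session) == key, ]
      vt_ref <- ss$vt[ss$region == config$ref_region]
      if (!length(vt_ref) || vt_ref <= 0) next
      roi <- ss[ss$region != config$ref_region, ]
      dvr_rows[[length(dvr_rows) + 1]] <- data.frame(
        subject = roi$subject, session = roi$session, method = m,
        region = roi$region, dvr = dvr_from_vt(roi$vt, vt_ref),
        stringsAsFactors = FALSE)
    }
  }
  for (m in intersect(config$models, c("SRTM", "LREF"))) {
    sub <- fits[fits$model == m, ]
    dvr_rows[[length(dvr_rows) + 1]] <- data.frame(
      subject = sub$subject, session = sub$session, method = m,
      region = sub$region, dvr = sub$dvr, stringsAsFactors = FALSE)
  }
  dvr <- do.call(rbind, dvr_rows)
  say("DVR table: %d rows", nrow(dvr))

  # test-retest reports per method
  trt <- list()
  two_sessions <- all(vapply(subjects, function(s)
    all(c("test", "retest") %in% names(s)), logical(1)))
  if (two_sessions && length(subjects) >= 2) {
    for (m in unique(dvr$method)) {
      dm <- dvr[dvr$method == m, ]
      regions <- sort(unique(dm$region))
      mk <- function(session) {
        d <- dm[dm$session == session, ]
        out <- matrix(NA_real_, length(unique(d$subject)), length(regions),
                      dimnames = list(sort(unique(d$subject)), regions))
        for (i in seq_len(nrow(d)))
          out[d$subject[i], d$region[i]] <- d$dvr[i]
        out
      }
      trt[[m]] <- trt_report(mk("test"), mk("retest"), method = m,
                             ref_region = config$ref_region)
    }
    say("test-retest reports: %s", paste(names(trt), collapse = ", "))
  }

  # per-subject regression of reference-model DVRs on 1TC DVRs
  regression <- NULL
  if ("1TC" %in% config$models &&
      any(config$models %in% c("SRTM", "LREF"))) {
    rows <- list()
    gold <- dvr[dvr$method == "1TC", ]
    for (m in intersect(config$models, c("SRTM", "LREF"))) {
      dm <- dvr[dvr$method == m, ]
      for (key in unique(paste(gold$subject, gold$session))) {
        g <- gold[paste(gold$subject, gold$session) == key, ]
        d <- dm[paste(dm$subject, dm$session) == key, ]
        d <- d[match(g$region, d$region), ]
        if (nrow(g) < 3 || any(is.na(d$dvr))) next
        r <- tryCatch(dvr_regression(g$dvr, d$dvr),
                      error = function(e) NULL)
        if (is.null(r)) next
        rows[[length(rows) + 1]] <- data.frame(
          subject = g$subject[1], session = g$session[1], method = m,
          slope = r$slope, intercept = r$intercept, r2 = r$r2,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      regression <- do.call(rbind, rows)
      say("cross-method regressions: %d subject-sessions", nrow(regression))
    }
  }

  # outputs
  hash <- .config_hash(config)
  meta_header <- function(con) writeLines(sprintf("# config_hash=%s", hash), con)
  wtab <- function(df, name) {
    p <- file.path(config$out_dir, name)
    con <- file(p, "w"); on.exit(close(con), add = TRUE)
    meta_header(con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  wtab(fits, "fits.tsv")
  wtab(dvr, "dvr.tsv")
  if (!is.null(regression)) wtab(regression, "dvr_regression.tsv")
  for (m in names(trt)) {
    rep <- trt[[m]]
    wtab(as.data.frame(rep), sprintf("trt_%s.tsv", m))
    jsonlite::write_json(
      list(config_hash = hash, method = m, ref_region = config$ref_region,
           regional = as.data.frame(rep),
           pooled_regional = as.list(attr(rep, "pooled_regional")),
           pooled_all = as.list(attr(rep, "pooled_all"))),
      file.path(config$out_dir, sprintf("trt_%s.json", m)),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(
    list(config_hash = hash,
         settings = unclass(config)[!vapply(unclass(config), is.null,
                                            logical(1))],
         n_fits = nrow(fits), n_dvr = nrow(dvr)),
    file.path(config$out_dir, "settings.json"), auto_unbox = TRUE,
    digits = NA)
  say("done; outputs in %s (config hash %s)", config$out_dir, hash)
  writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  invisible(list(fits = fits, dvr = dvr, trt = trt, regression = regression,
                 out_dir = config$out_dir, config_hash = hash))
}
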