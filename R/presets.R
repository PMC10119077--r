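# Published region-level kinetic parameters and blood pharmacokinetics of
# [18F]F13640 in healthy volunteers, shipped as presets for the synthetic
# generator and as reference inputs for validation.

#' One-tissue-compartment region presets for [18F]F13640
#'
#' Cohort-mean one-tissue parameters per brain region (K1 in mL/(min*mL),
#' k2 in 1/min, fractional blood volume Vb), from the first-in-human
#' characterization of the tracer.  `vt` is the implied total distribution
#' volume K1/k2.  These define the synthetic generator's regional kinetics.
#'
#' @return Data frame with columns `name`, `K1`, `k2`, `Vb`, `vt`.
#' @export
region_presets <- function() {
  p <- data.frame(
    name = c("cingulate", "frontal", "occipital", "parietal",
             "temporal_sup", "temporal_inf", "amygdala", "central_grey",
             "hippocampus", "insula", "parahippocampal", "thalamus",
             "brainstem", "raphe_dorsal", "raphe_median", "cerebellum",
             "cerebellum_gm", "cerebellum_wm", "vermis", "frontal_wm",
             "corpus_callosum"),
    K1 = c(1.38, 1.33, 1.26, 1.32, 1.31, 1.19, 1.07, 1.07, 1.04, 1.18,
           1.05, 1.18, 1.03, 1.21, 1.13, 1.38, 1.38, 1.03, 1.41, 0.81,
           0.56),
    k2 = c(0.014, 0.016, 0.017, 0.016, 0.016, 0.016, 0.013, 0.016, 0.013,
           0.014, 0.014, 0.015, 0.013, 0.013, 0.012, 0.016, 0.016, 0.015,
           0.017, 0.013, 0.011),
    Vb = c(0.038, 0.033, 0.036, 0.038, 0.040, 0.029, 0.036, 0.030, 0.035,
           0.037, 0.044, 0.038, 0.033, 0.033, 0.032, 0.042, 0.041, 0.028,
           0.039, 0.020, 0.022),
    stringsAsFactors = FALSE)
  p$vt <- p$K1 / p$k2
  p
}

.preset <- function(name) {
  p <- region_presets()
  i <- match(name, p$name)
  if (any(is.na(i))) stop("unknown region preset: ",
                          paste(name[is.na(i)], collapse = ", "))
  p[i, , drop = FALSE]
}

#' Published blood pharmacokinetic summary for [18F]F13640
#'
#' Per-subject plasma parent fractions and free plasma fractions at the
#' five metabolite/free-fraction sampling times (2, 10, 30, 90, 205 min)
#' and the per-subject mean plasma-to-whole-blood ratios, for the four
#' volunteers with arterial sampling.  Fractions are dimensionless (not
#' percent).  One parent-fraction value (subject 2, 90 min) was not
#' interpretable and is `NA`.
#'
#' @return List with `times` (minutes), matrices `parent_fraction` and
#'   `free_fraction` (subjects x times), vector `fwb` (per-subject means),
#'   and `parent_fraction_mean` (cohort means used for the published
#'   one-exponential metabolite model).
#' @export
f13640_blood_reference <- function() {
  times <- c(2, 10, 30, 90, 205)
  pf <- rbind(
    s2 = c(0.995, 0.961, 0.954, NA, 0.967),
    s5 = c(0.995, 0.979, 0.978, 0.967, 0.956),
    s7 = c(0.989, 0.975, 0.958, 0.949, 0.947),
    s8 = c(0.995, 0.980, 0.956, 0.945, 0.943))
  fp <- rbind(
    s2 = c(0.0042, 0.0072, 0.0110, 0.0123, 0.0194),
    s5 = c(0.0052, 0.0079, 0.0088, 0.0287, 0.0166),
    s7 = c(0.0038, 0.0088, 0.0108, 0.0156, 0.0162),
    s8 = c(0.0059, 0.0089, 0.0151, 0.0194, 0.0124))
  colnames(pf) <- colnames(fp) <- paste0("t", times)
  list(times = times,
       parent_fraction = pf,
       free_fraction = fp,
       fwb = c(s2 = 1.84, s5 = 1.78, s7 = 1.77, s8 = 1.77),
       parent_fraction_mean = c(0.9940, 0.9740, 0.9620, 0.9540, 0.9530))
}
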