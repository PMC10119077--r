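---
title: "Kinetic quantification of slowly clearing PET radiotracers: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic quantification of slowly clearing PET radiotracers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`petkin` implements the complete region-level quantification chain for
dynamic brain PET with very slowly clearing radioligands, of which the
5-HT1A agonist tracer [18F]F13640 is the motivating example: tissue
efflux rates around 0.011–0.017 min⁻¹ mean the tissue curve is still
rising after an hour, quantification needs acquisitions extending to
~225 min (acquired in two parts with a break), and late-time graphical
methods operate close to the edge of their asymptotic validity. This
vignette documents the models, the numerical conventions, the
synthetic-data generator that the validation rests on, and the known
limitations.

## Time, frames and decay

All model-facing quantities use minutes post injection; file formats
carry seconds (the convention in which frame tables are printed) and
convert at the boundary. Frames are half-open intervals `[start, end)`
validated to be contiguous within an acquisition part; the default
schedule is 24 frames over 0–90 min (8×15 s, 3×60 s, 5×120 s, 1×300 s,
7×600 s) and, after a one-hour break outside the scanner, 8 frames over
150–225 min (7×600 s, 1×300 s). Both parts are assumed decay-corrected
to the same reference time (the start of the first part);
`concatenate_sessions()` enforces shared region labels and reference
time, which is the TAC-level stand-in for image-domain alignment —
image registration, motion correction and reconstruction are out of
scope. The fluorine-18 half-life is fixed at 109.771 min (the standard
physical constant, configurable through `decay_constants()`).

## The arterial input function

The input function is assembled multiplicatively,

$$AIF(t) = PPf(t)\; f_{wb}\; C_{wb}(t)\; f_p(t),$$

from four independently estimated pieces:

* `fwb` — the plasma-to-whole-blood activity ratio, the mean of the
  per-sample ratios `Cp/Cwb` over all paired draws (sample SD
  reported). Pre-appearance draws where both activities are exactly
  zero are uninformative and skipped.
* `PPf(t)` — the plasma parent (unmetabolized) fraction, modelled as
  `1 − A0·(1 − exp(−ln 2 · t/T))`: a monotone decline from 1 to the
  plateau `1 − A0` with half-rise time `T` min. Fitted by unweighted
  least squares with a multi-start grid (`T ∈ {1, 5, 10, 30, 60}` min,
  `A0 ∈ {0.01, 0.05, 0.2}`, bounds `0 ≤ A0 ≤ 1`, `0.1 ≤ T ≤ 500`)
  because the objective is very flat when the plateau is shallow. If
  `A0` collapses to zero, `T` is unidentifiable and the fit is flagged.
* `fp(t)` — the free (non-protein-bound) plasma fraction, around 1–2%
  for this tracer class and not constant over time. Default mode is
  linear interpolation through the measured samples with constant
  extrapolation (`time-varying`); the alternative `late-mean` mode uses
  the mean of samples at or after 30 min, reflecting that early fp
  assays of slowly equilibrating tracers are unreliable. Fractions are
  dimensionless in memory; percent appears only on disk, which prevents
  silent 100× scale errors in the AIF.
* `Cwb(t)` — piecewise-linear interpolation of the whole-blood samples,
  with a linear rise from (0, 0) to the first sample and a
  single-exponential tail fitted to the last three samples; evaluation
  more than 30 min past the last sample raises an error rather than
  extrapolating silently.

## Invasive models

The measured PET signal is modelled with a vascular term,
`PET(t) = Vb·Cwb(t) + (1 − Vb)·C_T(t)`.

**One- and two-tissue compartment models.** For the 1TC model
`C_T = K1 · AIF ⊗ e^{−k2 t}`; the 2TC model adds a serial bound
compartment (rates k3, k4) and is evaluated as the sum of two
exponential convolutions via the macro-rate eigendecomposition.
Convolutions with the piecewise-linear input are computed in closed
form per linear segment, and per-frame time-averages are obtained
exactly from the identity `∫₀ᵗ E = (∫₀ᵗ f − E(t))/k` for
`E = f ⊗ e^{−kt}`, so the forward model carries no quadrature error
(the test suite verifies 0.1% agreement against a dense-grid numeric
convolution oracle). Fitting is weighted least squares. For the 1TC
model the problem is linear in `(1 − Vb)K1` and `Vb` once `k2` is
fixed, so a log-spaced global grid search over `k2` with an exact
linear subfit, refined by 1-D minimization, finds the optimum without
multi-start heuristics. The 2TC fit optimizes (k2, k3, k4) by
multi-start bounded quasi-Newton search with the two linear parameters
profiled out; the start list includes the nested one-tissue solution
(so the 2TC fit can never be worse than the 1TC fit on the same data),
and finite-difference steps are scaled to parameter magnitude, without
which convergence stalls at the percent level for rates of order
10⁻² min⁻¹. Estimates pinned at a rate bound — the hallmark of
unidentifiable k3/k4 for near-1TC kinetics — are flagged rather than
silently reported. Bounds: K1 ∈ [0, 10] mL/(min·mL),
k2 ∈ [10⁻⁴, 1] min⁻¹, k3, k4 ∈ [0, 1] min⁻¹, Vb ∈ [0, 0.2].

**Frame weights.** Default `w_j = Δt_j · exp(−2λ t_j)` (duration times
squared decay factor at the frame mid-time), the standard
count-statistics surrogate, normalized to mean one; uniform weights are
available. With relative weights, rescaling all activities shifts every
model's AIC equally, leaving model ordering invariant.

**Logan graphical analysis.** Ordinary least squares of
`∫₀^T C_T / C_T(T)` on `∫₀^T AIF / C_T(T)` over frames with mid-time
beyond `t*` (default 60 min, configurable; an automatic selector
accepting the earliest window with relative deviations below 10% is
provided but off by default). For a 1TC system this relation is exactly
linear with slope Vt at all times, so the estimate is limited only by
integration accuracy. Two numerical choices matter for this tracer
class: tissue integrals treat frame values as frame averages (increment
= value × duration), and the inter-part acquisition gap is bridged by
integrating a cubic spline through the mid-time points — the tissue
curve of a slowly clearing tracer peaks *inside* the 60-min break, and
a straight-chord bridge clips that peak enough to bias Vt by several
percent. No blood-volume term is applied (standard practice); with
realistic Vb in the data the Logan Vt is accordingly a few percent low,
and under frame noise the estimator carries its well-known additional
negative bias, both demonstrated in the test suite.

**Model comparison.** `AIC = n·ln(SSR/n) + 2k`, the least-squares form;
a perfect fit (SSR = 0) yields −∞ with a guard in the user-facing
function.

## Reference-tissue models

**SRTM** is fitted with basis functions: for each washout rate `k2a` on
a 200-point log-spaced grid over [10⁻³, 1] min⁻¹ the model
`C_T = R1·Cref + (k2 − R1·k2a)·Cref ⊗ e^{−k2a t}` is linear in its two
coefficients, which are solved exactly under the frame weights; the
grid minimum is refined by 1-D search and `BP = k2/k2a − 1`,
`DVR = BP + 1`. The model is evaluated at frame mid-times with the
reference curve taken as piecewise linear through the origin and the
reference TAC's mid-time points. Mid-time (node-consistent) evaluation
was chosen over frame-averaging the interpolant because it makes the
basic identity exact — an ROI identical to the reference region returns
R1 = 1, BP = 0 to machine precision — whereas frame-averaging the
mid-time interpolant injects a spurious ~1% bias into every fit.

**Reference Logan** regresses `∫₀^T C_T / C_T` on
`[∫₀^T C_ref + C_ref/k2′] / C_T` past `t*`; the slope is DVR and
`BP = DVR − 1`. By default the `C_ref/k2′` term is omitted: for very
slow kinetics and a late `t*` the term is nearly constant and is mostly
absorbed by the intercept. *Mostly* is doing real work here: at these
efflux rates the omission still biases DVR by up to roughly −4% for the
slowest regions, so `k2_prime` can be supplied as a number or — in the
pipeline — as `"srtm"`, which uses the median `k2/R1` over the run's
SRTM fits (the classic two-pass refinement) and restores sub-percent
accuracy, as the end-to-end validation shows. The median is used
because individual `k2/R1` estimates are occasionally wild when a
region's SRTM fit is weakly identified.

## Test–retest statistics

Reproducibility and reliability follow the two-session design: bias is
the per-subject percent change `(DVR_retest − DVR_test)/DVR_test × 100`
(regional summaries average per-subject biases, never biases of means),
variability (VAR) is the sample SD of those biases, and reliability is
the one-way ICC `(BSMSS − WSMSS)/(BSMSS + WSMSS)` with
`BSMSS = 2·Σ(subject mean − grand mean)²/(n−1)` and
`WSMSS = Σ(value − subject mean)²/n`. Negative ICCs are reported as
computed, and an all-identical input (denominator zero) raises a typed
condition from `icc()` while the report functions record `NA`. Under a
two-level Gaussian model the estimator converges to
σ²b/(σ²b + σ²w); at n = 8 subjects a single estimate has a sampling SD
above 0.1 and a mild downward bias at high ICC, which is why the
validation averages many simulated cohorts. Study-level summaries are
emitted under both defensible aggregations — mean of regional
statistics, and statistics recomputed on pooled subject×region values —
explicitly labelled.

## The synthetic-study generator

The generator emulates the statistical structure of the real
acquisition so that estimators can be validated against known truth:

* **Blood side.** The whole-blood bolus is a delayed tri-exponential
  `A1·e^{−l1 u} + A2·e^{−l2 u} − (A1+A2)·e^{−l3 u}` (`u = t − 0.5` min),
  continuous at appearance, peaking ≈ 21 kBq/mL near 1.4 min with a
  slow terminal phase — shape-plausible values, since no numeric bolus
  parameterization is published for this tracer. Metabolite and free
  fractions default to the published cohort means (A0 = 0.046,
  T = 9.06 min; fp from 0.48% to 1.9% across 2–205 min; fwb = 1.79).
  Samples follow the dense arterial schedule (every 5 s in minute one,
  every 15 s in minute two, every 30 s in minute three, then ten late
  draws: 28 samples, 18 with plasma separation; an optional
  pre-injection draw makes 29) with multiplicative Gaussian noise
  (default 2%) on activities; fraction assays are modelled noise-free.
* **Tissue side.** Regional TACs follow the 1TC operational equation
  with the published regional presets (`region_presets()`), plus
  Gaussian frame noise `SD_j = α·sqrt(value_j/(Δt_j·e^{−λ t_j}))`
  (count-rate scaling: short and late frames are noisier). The default
  α = 0.05 yields roughly 1–1.5% relative noise on late 10-min frames,
  typical of large-region TACs.
* **Cohort structure.** Between-subject variation of each region's Vt
  is a shared global log-normal factor (CV 0.19 — reproducing the ~20%
  regional Vt spread of the published cohort; it cancels in DVR) times
  a region-specific factor (CV 0.05 — sized so between-subject DVR
  spread lands near the published ~7%); sessions are perturbed
  region-wise with CV 0.012. All variation is placed on Vt via k2 with
  K1 held fixed, because reference-model outcomes depend on Vt ratios.
  Identical configuration and seed give bit-identical studies.

What the generator does **not** emulate: image-domain effects (partial
volume, motion, scanner resolution), dispersion/delay of the arterial
line, metabolite assay noise, violations of the 1TC assumption, or
inter-regional correlation beyond the global Vt factor. Passing tests
therefore demonstrate estimator correctness and statistical behaviour
under the stated model, not robustness to those real-data effects.

## Pipeline

`run_pipeline()` executes, per subject and session: input-function
construction (when an invasive model is requested and blood data are
present — requesting one without blood fails validation before any
fitting), invasive fits, SRTM fits; then resolves `k2′` if requested
and runs the reference Logan in a second pass; then DVR tables against
the configured reference region, per-method test–retest reports, and
per-subject regressions of reference-model DVRs on the one-tissue gold
standard. All outputs are TSV with a JSON settings sidecar, stamped
with a hash of the effective configuration, alongside a timing log.
Configuration may come from R (`run_config()`) or YAML
(`read_run_config()`); unknown keys are rejected.

## Known limitations

* **SRTM under blood-volume contamination.** SRTM has no vascular term.
  With realistic fractional blood volumes (2–4.4%) and these very slow
  kinetics, the basis fit absorbs the blood signal by drifting to small
  `k2a`, inflating DVR by up to about five percent for the slowest
  high-Vb regions even on noise-free data — the end-to-end validation
  computes this directly, and it mirrors the weaker gold-standard
  agreement and reliability reported for SRTM with this tracer class.
  The reference Logan with the `"srtm"` k2′ refinement is the
  recommended non-invasive estimator.
* **Logan estimators.** Noise-induced negative bias (no correction such
  as total least squares is implemented) and the documented few-percent
  negative offset when blood volume is present.
* **Very-long-lived parameter regime.** With k2 ~ 0.012 min⁻¹ even a
  225-min acquisition yields limited washout information; 1TC K1 and Vb
  are precise, but Vt estimates inherit the input-function tail and
  free-fraction assumptions (the choice of fp mode changes K1 and Vt
  materially, which is why both modes are exposed).
* **Identifiability of the 2TC model.** For near-1TC data k3/k4 are
  unidentifiable; fits are flagged when rates pin at bounds, and AIC
  comparison should be read with that flag in view.
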