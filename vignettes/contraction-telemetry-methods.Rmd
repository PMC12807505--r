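---
title: "Methods: contraction-peak phenotyping and heteroscedastic knockout contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contraction-peak phenotyping and heteroscedastic knockout contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

partolab quantifies uterine contractility during mouse parturition from
intrauterine-pressure telemetry, and estimates how tissue-specific loss of
mechanosensitive PIEZO channels (in the uterus, in dorsal-root-ganglion
sensory neurons, or both) weakens contractions. This vignette is the
package's own account of the analysis: the models, every tunable parameter
with its default and rationale, what the synthetic-data generator does and
does not emulate, the numerical choices, and known limitations.

## The analysis chain

1. **Ingest and resample.** Pressure traces (mmHg, timestamps in seconds
   since lights-on, ZT0) are resampled to exactly 1 Hz by bin averaging over
   half-open one-second bins `[t, t + 1)`. Averaging rather than decimation
   is used because it is anti-aliasing and preserves the mean of a constant
   signal exactly; every input sample is counted exactly once. Empty bins
   (telemetry dropouts) are linearly interpolated to keep the grid uniform,
   flagged, and excluded from peak statistics.
2. **Detect contraction peaks.** A contraction is a strict local maximum
   with absolute height at least 40 mmHg and topographic prominence at least
   20 mmHg. Prominence is the peak height minus the higher of its two bases,
   each base being the minimum sample between the peak and the nearest
   strictly higher sample on that side (or the trace edge when none exists).
3. **Window and summarize.** Windows are referenced to labor onset, defined
   as the appearance of the first pup (annotated to 1-minute accuracy):
   pre-labor, the 2-hour post-onset window, and beyond 2 hours, all
   half-open on the right so they partition the recording. The per-animal
   outcome `P_i` is the arithmetic mean of peak heights in the 2-hour
   post-onset window; inter-pup interval is the mean gap between successive
   deliveries; onset is dichotomized at ZT3.
4. **Group tests.** Fisher's exact 2x2 test (probability-mass rule, full
   hypergeometric enumeration), Mann-Whitney (exact permutation distribution
   by dynamic programming for combined n <= 20 without ties; otherwise
   normal approximation with tie and continuity correction), Kruskal-Wallis
   with tie correction. These are implemented from first principles because
   small-sample exactness is the point at cohort sizes of 6-9 animals; the
   base R implementations serve as independent cross-checks in the test
   suite.
5. **Knockout contrast.** The linear model
   `P_i = b0 + b_DRG D_DRG_i + b_Uterus D_Uterus_i + e_i` with
   `e_i ~ N(0, sigma^2_{g_i})`, one error variance per treatment group:
   viral (intrathecal AAV) knockouts are inherently more variable than
   germline Cre lines, so homoscedastic OLS would be inefficient. The
   estimator is feasible generalized least squares,
   `bhat = (X' O^-1 X)^-1 X' O^-1 P` with `O = diag(sigma^2_{g_i})`,
   iterating between coefficient and variance updates. Knockout effects are
   tested one-sided (H0: `b >= 0` vs H1: `b < 0`) with
   `t = bhat / se(bhat)` against a t distribution with `n - p` degrees of
   freedom, `p = 3` mean-model coefficients.
6. **Mechanoresponse classification.** Patch-clamp sweeps are low-pass
   filtered at 500 Hz (-3 dB) with an 8-pole Bessel filter; the baseline is
   the mean current in the window from 35 ms to 5 ms before stimulus onset;
   the peak amplitude is the largest absolute baseline-subtracted excursion
   during the mechanical stimulus (probe ramp plus 125-ms hold); a sweep is
   a mechanoresponse only if that amplitude strictly exceeds five times the
   baseline SD.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `min_height` | 40 | mmHg | detection threshold for contraction peaks; absolute sample value, not baseline-subtracted (baselines run near 5 mmHg, small against 40) |
| `min_prominence` | 20 | mmHg | suppresses shoulders and noise riding on larger contractions |
| analysis window | onset to onset + 2 h | — | the knockout effect is specific to early labor; pre-labor and late windows are comparable across groups |
| `zt_boundary` | 3 | h ZT | onset dichotomy; onset exactly at ZT3 counts as "before" (strict `>`), exposed as a config switch |
| GLS `tol`, `max_iter` | 1e-8, 100 | relative, count | feasible iteration stops when the largest relative coefficient change drops below `tol` |
| `var_correction` | `"leverage"` | — | per-group variance denominator `sum(1 - h_ii)`; see below |
| `one_step` | `FALSE` | — | non-iterated feasible GLS as a sensitivity variant |
| filter `cutoff`, `poles` | 500, 8 | Hz, count | the standard recording-rig anti-alias chain for mechanically activated currents |
| response rule | strict `> 5 x SD` | — | a deflection of exactly five SDs is not a response |

## The synthetic-data generator

The generator produces cohorts with the statistical structure the pipeline
assumes, fully seeded (every animal draws from private substreams, so
byte-identical files follow from an identical config and seed).

* **Traces.** Baseline pressure (5 mmHg) plus Gaussian sensor noise
  (SD 1.5 mmHg) plus Gaussian contraction transients (width parameter 15 s:
  smooth, unimodal, and isolated transients have prominence equal to their
  amplitude). Transient centres follow an inhomogeneous Poisson process: a
  sparse pre-labor rate (3/h) switching at labor onset to a group-dependent
  rate, 30/26/22/18 per hour for control, uterus-, DRG- and combined
  knockout. These are contractions every 2-3 minutes, the physiological
  range for mouse labor; they also keep neighbouring transients far enough
  apart that their Gaussian tails do not inflate each other's detected
  heights. Centres closer than three widths (45 s) are thinned so
  ground-truth peaks stay resolvable at 1 Hz.
* **Amplitudes.** Normal per group, truncated below at zero. Defaults embed
  the additive knockout structure the GLS model assumes: control mean
  150 mmHg with effects -16.01 (uterus) and -47.11 mmHg (DRG), per-transient
  SDs 8/10/12/14 mmHg. The study does not report absolute per-group peak
  means, only the detection threshold and the effect sizes, so the absolute
  scale is a package choice: it is set high enough that every group mean
  clears the 40 mmHg detection criterion by more than three per-transient
  SDs. That matters: if a group's amplitude distribution straddled the
  detection threshold, the missing low peaks would bias that group's mean
  upward and corrupt effect recovery.
* **Labor schedules.** Onset ZT per group (means 1.5/2.0/3.0/3.2 h, SDs
  0.6-1.2 h: all controls before ZT3, roughly half of the severe knockouts
  after, matching the reported phenotype), clamped so the recording always
  contains a pre-labor stretch and the full 2-hour window. Litter size
  uniform on 5-9; inter-pup gaps Gamma with group-specific mean/SD
  (10/13/11/25 min means: combined knockouts labor much more slowly),
  rounded to whole minutes like the video annotations. The Gamma family
  keeps gaps positive and degenerates to the exact mean when the SD is set
  to zero.
* **Sweeps.** Gaussian current noise around a holding current; responsive
  sweeps add an inward deflection rising linearly over the probe ramp
  (1 um/ms), held for 125 ms, relaxing exponentially (5 ms) afterwards.

**What the generator does not emulate.** Real traces contain baseline drift,
movement artefacts, non-Gaussian amplitude distributions, serially
correlated contractions, and — importantly — per-animal biological
variability in contraction strength. In the generator, an animal's mean peak
pressure varies only through its finite number of per-transient draws, so
animal-level variances are far smaller than in real cohorts. The GLS
calibration and recovery studies therefore inject animal-level noise
directly (group SDs 10/25/30/35 mmHg at the summary level) rather than
relying on trace-level simulation. Passing tests demonstrate correctness of
the algorithms under the stated generative assumptions, not robustness to
every artefact of real telemetry.

## Numerical choices

* **Plateaus** collapse to one peak at the plateau midpoint (floor
  division); edge samples are never peaks. Ties in prominence bases need no
  extra rule: the minimum over the interval is the definition.
* **Window boundaries** are half-open on the right everywhere, so a peak
  exactly 2 h after onset belongs to the later window and the three windows
  partition the trace.
* **Fisher's probability-mass rule** sums hypergeometric probabilities no
  greater than the observed table's within relative tolerance 1e-12; this
  reproduces the published 0.0294 for the onset-delay table.
* **Bessel realization.** The analog prototype is the degree-8 reverse
  Bessel polynomial (roots via `polyroot`); its -3 dB frequency is located
  numerically and the poles rescaled so that, after the bilinear transform
  with cutoff pre-warping, the digital magnitude response crosses 1/sqrt(2)
  exactly at the requested cutoff (measured gain 0.7066 at 500 Hz). The
  filter is applied causally as second-order sections for numerical
  stability, with state initialized at the DC level of the first sample so a
  constant sweep passes unchanged. The baseline SD in the 5x-SD rule is
  computed on the filtered trace, from the same window as the baseline mean
  (a raw-trace option is exposed).
* **Degenerate inputs** are carried, not crashed on: animals with no peaks
  or a single pup get explicit missing statistics; degenerate Fisher margins
  give p = 1 with a note; a group whose residual spread collapses to zero
  makes the variance inestimable and errors.

## Variance estimation and calibration of the one-sided test

The model specifies group variances but not how to estimate them. The
package iterates feasible GLS to convergence and estimates each group's
variance as the sum of squared residuals divided by `sum(1 - h_ii)` over the
group's observations, where `h_ii` is the GLS hat diagonal — the standard
leverage correction that makes the estimator near-unbiased in small groups.
The naive denominator `n_g` (option `var_correction = "none"`) underestimates
variances and, in 20000-replicate null simulations at the study design
(8/7/6/8 animals, group SDs 10/25/30/35), pushes the one-sided test's type-I
error to 0.089 at nominal 0.05; the leverage correction brings it to 0.077
(DRG) and 0.069 (uterus).

The residual excess is structural, not an estimator defect: the t reference
with `n - p = 26` degrees of freedom treats the four estimated group
variances as known. With groups of 6-8 observations their sampling noise is
material, and the DRG contrast — which leans on the smallest, noisiest
groups — is the more affected. A Satterthwaite-type effective-df correction
would repair this, but the stated inferential procedure fixes df at `n - p`,
so the package follows it and documents the consequence instead: at these
group sizes the one-sided GLS p-values are mildly anti-conservative (true
size roughly 0.07-0.08 at nominal 0.05). Users needing strict size control
at this scale should interpret p-values near 0.05 cautiously or increase
group sizes. The one-step variant (weights from OLS residuals, no iteration)
is slightly better calibrated (0.071/0.064) and is exposed for sensitivity
analysis; the iterated fit remains the default because it is the standard
feasible estimator and the more efficient one.

## Problem sizes in the test suite

Simulation-backed tests use sizes chosen to keep Monte-Carlo error well
below the asserted margins: 1000 random traces (length up to 500) against
the brute-force peak oracle; 500 replicates for GLS effect recovery at the
8/7/6/8 design; 2000 replicates for each type-I calibration; 200 replicate
cohorts of 4 animals per group (4-hour, 1 Hz recordings) for full-pipeline
effect recovery; 1000 synthetic null sweeps for the classifier
false-positive rate.

## Known limitations

* Peak heights are absolute pressures; if a recording had a large baseline
  offset, the 40 mmHg criterion would need re-referencing.
* The GLS model is fixed-effects with a diagonal covariance; no
  repeated-measures or mixed-effects structure, no REML.
* The one-sided test's size at small n is discussed above; no
  multiple-testing machinery is included beyond reporting raw p-values.
* The mechanoresponse module classifies single sweeps; it does not fit
  pressure-response curves or correct for series resistance.
* Whether the 5x-SD rule should use the filtered or raw baseline SD is
  ambiguous in the field; filtered is the default here (the filter is
  specified as applied before analysis), with a switch for the raw variant.
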