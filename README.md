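# partolab

Quantitative phenotyping of uterine contractions during mouse parturition
from intrauterine-pressure telemetry, with a heteroscedastic
generalized-least-squares model for tissue-specific knockout effects and a
rule-based classifier for mechanically activated patch-clamp currents.

Mechanosensitive PIEZO channels in the uterus and in dorsal-root-ganglion
(DRG) sensory neurons both contribute to labor: deleting them weakens
contractions and prolongs delivery. Testing that quantitatively requires
turning multi-hour pressure recordings from freely moving animals into
per-animal contraction statistics, and comparing small, unequally variable
treatment groups (germline Cre vs intrathecal-AAV knockouts). partolab
implements that analysis chain for telemetry data exported as delimited
text, plus a fully seeded synthetic-cohort generator so every stage is
testable against known ground truth. It is written for physiologists and
biostatisticians analyzing parturition telemetry or similar episodic
pressure signals.

## What it computes

* **Contraction peaks.** Traces are resampled to 1 Hz (bin averaging);
  peaks are strict local maxima with height >= 40 mmHg and topographic
  prominence >= 20 mmHg; peaks are windowed relative to labor onset (first
  pup), with the 2-hour post-onset window as the primary analysis window.
* **Labor statistics.** Per-animal mean peak pressure P_i, mean inter-pup
  interval, onset-after-ZT3 classification; exact Fisher 2x2, exact
  small-sample Mann-Whitney, and tie-corrected Kruskal-Wallis tests,
  implemented from first principles and cross-checked against base R.
* **Knockout contrast.** The linear model

      P_i = b0 + b_DRG * D_DRG_i + b_Uterus * D_Uterus_i + e_i,
      e_i ~ N(0, sigma^2_g(i))

  with one error variance per treatment group, estimated by iterative
  feasible GLS, `bhat = (X' O^-1 X)^-1 X' O^-1 P`; knockout coefficients are
  tested one-sided (H1: b < 0) against t with n - p df.
* **Mechanoresponses.** Patch-clamp sweeps are filtered at 500 Hz (-3 dB,
  8-pole Bessel), baselined on the 35-to-5 ms pre-stimulus window, and
  classified as responses only when the baseline-subtracted peak amplitude
  strictly exceeds 5x the baseline SD.

## Worked example

Simulate a four-arm cohort (control, uterus-specific, DRG-specific and
combined knockout; 8/7/6/8 animals) with knockout effects of -16.01 and
-47.11 mmHg embedded in the contraction amplitudes, run the pipeline, and
fit the contrast:

```r
library(partolab)
cfg <- cohort_config(seed = 20251)                  # 8/7/6/8 animals
art <- run_pipeline(run_config(cohort = cfg, outdir = "results/run"))
print(art$gls_fit)
```

```
Heteroscedastic GLS fit (n = 29, df = 26, converged in 7 iterations)
          estimate     se      t p_one_sided
intercept   156.01 0.2192 711.79   1.000e+00
d_drg       -47.77 0.5385 -88.70   4.169e-34
d_uterus    -16.52 0.2770 -59.66   1.192e-29
```

The estimates recover the embedded effects: contraction peaks average
~156 mmHg in controls, and deleting PIEZO channels in DRG neurons or the
uterus lowers mean peak pressure by ~48 and ~17 mmHg respectively (one-sided
p-values test H1: effect < 0). The very small standard errors are a property
of the generator — synthetic animals vary only through per-contraction
noise; see the methods vignette for what the generator does and does not
emulate. The onset-delay association uses Fisher's exact test:

```r
fisher_exact_2x2(matrix(c(9, 0, 4, 5), 2, byrow = TRUE))$p_value
#> [1] 0.02941176
```

The numbered scripts under `analysis/` run the same workflow as a narrative
sequence (simulate -> detect peaks -> labor statistics -> GLS contrast ->
ephys classification), writing their tables under `results/`.

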