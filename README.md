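# drstrend

Longitudinal analysis of tumor perfusion and angiogenesis under
chemotherapy, built for preclinical studies that follow the same tumors
week by week with endoscopic diffuse reflectance spectroscopy (DRS) and
repeated biopsies. The package implements the complete analysis chain for
a three-arm design — maximum-tolerated-dose (MTD), metronomic (MET) and
saline control (CG) — together with a synthetic cohort generator with
known ground truth, so every stage is testable without animal data.

## What it computes

**Spectral inversion.** Raw spectra are calibrated against dark and
5%-reflectance-standard measurements,
`R(λ) = 0.05 · (I_sample − I_dark)/(I_ref − I_dark)`,
screened for artifacts (saturation, low signal, poor model fit), averaged
per tumor-visit and inverted through a reflectance forward model. With
μa(λ) = ln(10)·(tHb/64500)·[StO2·ε_HbO2(λ) + (1−StO2)·ε_Hb(λ)] and
μs′(λ) = a·(λ/630)^(−b), bounded least squares over θ = (tHb, StO2, a, b)
on 450–650 nm yields total hemoglobin, oxygen saturation and the derived
HbO2 = StO2·tHb, HbO = (1−StO2)·tHb. The forward map can be an analytic
surrogate or a tabulated lookup table (LUT) interpolated in
(log μa, μs′).

**Relative expression.** Ct triplicates are aggregated (outliers beyond a
0.5-cycle range dropped), per-gene amplification efficiencies E are
estimated from standard-curve slopes (E = 10^(−1/slope)), and expression
is quantified by the efficiency-corrected ratio
`E_target^ΔCt_target / E_ref^ΔCt_ref` with Gapdh as reference and the
control arm at week 1 as calibrator.

**Trend inference.** Each metric is modeled by a penalized-spline
generalized additive model with a treatment-by-time interaction: one
cubic B-spline smooth per arm (k = 6, second-order difference penalty)
plus arm intercepts, smoothing parameters selected by REML. Pairwise arm
comparisons compute the difference of fitted trends d̂(x) on a fine week
grid with a 95% *simultaneous* confidence band d̂ ± m*·SE, where m* is the
level-quantile of the maximum standardized deviation over the grid under
posterior simulation of the coefficients (10,000 draws; σ² integrated
out, smoothing-parameter uncertainty propagated into the covariance).
Week intervals where the band excludes zero are reported as significant.

**Cohort summaries.** Weekly tumor-score proportions on the nine-category
scale (missing visits excluded from denominators), per-tumor score
trajectories, and microvessel density (MVD, percent marker-positive area
over tissue area) from three-class label masks, compared across arms by
Kruskal–Wallis.

## Worked example: the analysis workflow

The numbered drivers under `analysis/` run the whole study on the
synthetic cohort (arm sizes CG = 14, MET = 20, MTD = 27, six weekly
visits) and write tables under `results/study/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_invert_spectra.R
...
Rscript analysis/07_report.R
```

Output from a run with the committed configuration (seed 1234):

```
simulated 1098 raw spectra for 61 tumors (3.8% corrupted)
inverted 366/366 tumor-visits; median |StO2 error| 0.0021, median tHb rel. error 1.08%
estimated efficiencies: Gapdh=1.999, Hif1a=1.903, Vegf=1.944
MTD week-1 Vegf mean relative expression: 0.503 (n=27)
StO2   smooth EDF: CG=1.00 MET=3.99 MTD=3.87
...
Vegf   CG-MTD   positive difference, weeks 1.0-6.0
MVD medians: CG=24.87% MET=23.99% MTD=7.88%; Kruskal-Wallis H=46.1, p=9.53e-11
```

Reading this: the inversion recovers the generator's true perfusion
values to ~0.2% StO2 under 1% spectral noise; the MTD arm's Vegf level at
week 1 is half the control calibrator (the suppression the generator
encodes); the control smooths stay linear (EDF 1) while treated arms need
~4 effective degrees of freedom; the difference bands flag the MTD arm's
Vegf suppression across the study and the masks give the MTD arm a
three-fold lower vessel density.

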