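---
title: "Models and methods behind drstrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind drstrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drstrend)
```

drstrend analyzes longitudinal preclinical chemotherapy studies in which
the same colorectal tumors are followed over six weekly endoscopies with
diffuse reflectance spectroscopy (DRS), repeated biopsies for qPCR,
endoscopic size scoring, and terminal immunohistochemistry. This
vignette explains each model, the tunable parameters and their defaults,
what the synthetic generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The spectral forward model and its inversion

Tissue absorption in the visible range is modeled as a hemoglobin
mixture,

$$\mu_a(\lambda) = \ln(10)\,\frac{tHb}{64500}\,
\bigl[\mathrm{StO_2}\,\varepsilon_{HbO_2}(\lambda) +
(1-\mathrm{StO_2})\,\varepsilon_{Hb}(\lambda)\bigr],$$

with total hemoglobin $tHb$ in g/L, a molar mass of 64,500 g/mol, and
molar extinction spectra $\varepsilon$ in L mol$^{-1}$cm$^{-1}$.
Reduced scattering follows the usual power law
$\mu_s'(\lambda) = a(\lambda/630\,\mathrm{nm})^{-b}$. The packaged
extinction table (`inst/extdata/hb_extinction_synthetic.csv`) is a
*synthetic* smooth emulation of oxy-/deoxyhemoglobin spectra — it
carries the Q-band doublet near 542/577 nm, the single deoxy band near
555 nm, their isosbestic crossings and the steep red-region contrast,
which is the structure that makes StO$_2$ spectrally identifiable, but
its magnitudes are not laboratory measurements. All optics validation is
round-trip (forward then invert against the same table), so the
qualitative shape is what matters; a measured table can be dropped in by
path.

Probe-specific lookup tables built from phantom measurements are not
available here, so the forward reflectance is a stated closed form,

$$R(\mu_a, \mu_s') = \frac{\mu_s'}{\mu_s' + k_1\mu_a}\,
e^{-k_2\,\mu_a\,d},$$

with $k_1 = 1$, $k_2 = 2$, $d = 0.029$ cm (the scale of the probe's
source–detector separation). The albedo-like first factor captures the
competition between scattering-driven return and absorption; the
Beer–Lambert factor represents absorption along a fixed effective photon
path, which both breaks the $\mu_a/\mu_s'$ ratio degeneracy (making the
absolute scale of $tHb$ and $a$ identifiable) and keeps the surface
strictly decreasing in $\mu_a$ and strictly increasing in $\mu_s'$
everywhere. An attenuation term of the form
$\exp(-k_2\sqrt{\mu_a\mu_s'}\,d)$ was considered and rejected: at low
absorption the albedo factor saturates at 1 while the square-root term
keeps falling, so reflectance would *decrease* with scattering — a
physically wrong monotonicity that also breaks LUT validation. The
surrogate is pluggable wherever a forward model is accepted, and
`build_lut()` tabulates any monotone surrogate on a
log-$\mu_a \times \mu_s'$ grid ($[0.01, 50] \times [1, 50]$ cm$^{-1}$,
$80\times60$ nodes by default) with bilinear interpolation in
$(\log\mu_a, \mu_s')$.

Inversion is bounded least squares over $(tHb, \mathrm{StO_2}, a, b)$ on
the 450–650 nm fit window (covering the Soret shoulder and the Q-bands),
multi-started from a fixed $2\times3\times2$ grid of initializations to
avoid local minima. Bounds default to $tHb \in [0.01, 100]$ g/L,
$\mathrm{StO_2} \in [0,1]$, $a \in [1,50]$ cm$^{-1}$, $b \in [0,4]$.
Spectra are screened before inversion — detector saturation, or median
calibrated reflectance below 0.005 — and after it, when the fit RMSE
exceeds 0.01; replicate spectra surviving screening are averaged per
tumor-visit before the fit. These thresholds are configuration defaults:
the original instrument's exact rejection rules are not published, so
they are set where they cleanly separate the generator's three
corruption archetypes from clean spectra. Perfusion metrics are
summarized per tumor as fold changes against that tumor's week-1 value
(tumors missing week 1 are excluded and logged); normalizing to the
group baseline instead is available by configuration.

## Relative expression

Technical Ct triplicates are averaged after an outlier rule: if the
replicate range exceeds 0.5 cycles, the single value farthest from the
median is dropped and the record flagged. The 0.5-cycle bound is a lab
convention, not a published constant. RNA quality filtering keeps
samples with 260/280 absorbance in $[1.8, 2.0]$, inclusive on both ends.
Amplification efficiencies come from standard-curve slopes,
$E = 10^{-1/\text{slope}}$, and expression ratios use the
efficiency-corrected form

$$\mathrm{ratio} = \frac{E_{t}^{\Delta Ct_t}}{E_{ref}^{\Delta Ct_{ref}}},
\qquad \Delta Ct = Ct_{\text{calibrator}} - Ct_{\text{sample}},$$

with Gapdh as the reference gene and the control arm at week 1 as
calibrator. The calibrator Ct is the *arithmetic mean* over the
calibrator samples per gene (mean versus median was open; mean is the
default and configurable), applied per sample rather than pairwise, so
the calibrator stratum maps to a mean ratio of 1 by construction. When
every efficiency equals 2 the ratio reduces exactly to
$2^{-\Delta\Delta Ct}$, which the test suite verifies against an
independent oracle.

## The trend model

Fold changes and expression ratios are continuous, positive and modeled
on their own scale with Gaussian errors and identity link (a log-scale
option exists in configuration). For metric value $y_{ij}$ of tumor $i$
in arm $g$ at week $x$:

$$y = \alpha_g + f_g(x) + \varepsilon, \qquad
\varepsilon \sim N(0, \sigma^2),$$

with one smooth $f_g$ per arm — a treatment-by-time interaction. Each
$f_g$ uses $k = 6$ cubic B-splines on equally spaced knots extending
beyond the week domain, sum-to-zero constrained over the arm's observed
weeks (absorbed by reparameterization so the arm intercept stays
identifiable), with a second-order difference penalty
$\lambda_g\,\beta^\top D_2^\top D_2\,\beta$. Two consequences of this
layout are load-bearing and tested: straight lines in week lie exactly
in the penalty null space (they are never shrunk, and the
$\lambda\to\infty$ limit equals per-arm ordinary least squares lines),
and $k = 6$ saturates six weekly visits so the smooth can interpolate
the weekly means when the data demand it. $k$ is configurable; the
identifiable maximum is the number of distinct weeks plus two. Equally
spaced knots matter here: with stacked boundary knots the
coefficient-difference penalty no longer annihilates straight lines,
which silently breaks both properties.

Smoothing parameters are selected by REML (coordinate descent over a
40-point log-spaced grid on $[10^{-4}, 10^6]$ with golden-section
refinement, tolerance $10^{-8}$); GCV is available as an option. REML is
the default because its smoothing estimates are markedly less variable:
in the package's own null-coverage experiments GCV's occasional
undersmoothing cost 2–3 percentage points of band coverage.
All observations within an arm are treated as exchangeable — no
per-tumor random effects — which mirrors the interaction model this
workflow is built around; the consequences are discussed under
limitations.

## Simultaneous inference on differences of smooths

For arms $A, B$ the difference $d(x) = \alpha_A + f_A(x) - \alpha_B -
f_B(x)$ (intercepts included by default, because comparisons are between
full arm trends; a smooth-only flag exists) is evaluated on a 200-point
grid with $\hat d = L\hat\beta$ and pointwise
$SE = \sqrt{\operatorname{diag}(L V L^\top)}$. The 95% simultaneous band
is $\hat d \pm m^* SE$, where $m^*$ is the empirical 0.95-quantile of
$\max_x |L(\beta^* - \hat\beta)|/SE$ over 10,000 posterior draws
$\beta^*$. Three calibration details matter, all verified by simulation:

* **Covariance.** $V = \hat\sigma^2 (X^\top X + \sum_g \lambda_g
  S_g)^{-1}$ is the Bayesian covariance of the penalized fit, *plus* a
  smoothing-parameter-uncertainty term $J\,\Omega\,J^\top$ with
  $J = \partial\hat\beta/\partial\log\lambda$ and $\Omega$ the inverse
  curvature of the REML criterion at its optimum.
* **Scale uncertainty.** Posterior draws are scaled by
  $\sqrt{\nu/\chi^2_\nu}$ with $\nu = n - \operatorname{tr}(A)$,
  integrating $\sigma^2$ out of the band.
* **Degenerate points.** Grid points with $SE$ below $10^{-12}$ (e.g. a
  self-difference) are masked from the maximization.

Without the first two corrections the null band covered the zero
function in about 93% of replicates instead of 95%; with them the
acceptance runs land at 95–96%. By construction $m^*$ never falls below
the pointwise normal quantile 1.96, and on a one-point grid it reduces
to it. Significant windows are contiguous grid runs where the band
excludes zero, with endpoints refined by linear interpolation of the
bounding curve's zero crossing; single-cell excursions are flagged
short. The three pairwise comparisons per metric are reported without
additional multiplicity correction — the simultaneity is across time
within a comparison, which is the protection this design relies on.

## The synthetic cohort generator

The generator emulates the study design: arms CG (n = 14), MET (n = 20),
MTD (n = 27), six weekly visits. Arm-level trend templates are
piecewise-cubic interpolants through (week, level) anchors on the
fold-change scale: CG flat at 1; MET StO$_2$ rising to 1.08 at week 4;
MTD to 1.05 at week 3; HbO$_2$ analogues at 1.15/1.10; MTD Vegf starting
at 0.5 in week 1 and recovering toward 1. Per-tumor heterogeneity is an
additive Gaussian offset on the fold-change scale (`subject_sd`, default
0.04) shared across that tumor's weeks; observation noise is
`noise_sd_value` (default 0.06). The combined ~7% dispersion was chosen
once as the level at which 8–15% arm effects are resolvable at these arm
sizes — the regime the emulated study operates in — and is not revisited.
Spectra are re-embedded in instrument units (lamp shape ×
reflectance / 0.05 + dark) with 1% multiplicative noise and corrupted
with probability `artifact_rate` by one of three archetypes (saturation,
near-dark, baseline shift), each recorded in ground truth. Ct tables
follow $Ct = Ct_{cal} - \log_E(\text{level})$ with triplicate noise
(0.1 cycles), a group-independent housekeeping gene, and standard curves
with slope $-1/\log_{10}E$. Scores are drawn on the nine-category scale
around arm-specific mean trends; masks are three-class label images with
arm positive fractions 25/24/8%. Missingness is completely at random
(`missing_rate`, default 0.05) — the emulated study reports missing
visits but no mechanism. Biopsy weeks default to the study's schedule
(control and metronomic arms at weeks 1, 4, 6; MTD weekly).

What the generator does *not* emulate: mechanistic tumor growth or
pharmacokinetics, image texture, spatial vessel structure, informative
missingness, and week-dependent error variance after per-tumor
normalization. Passing tests on this generator therefore demonstrates
correctness of the estimators and calibration of the intervals under
the stated sampling model, not robustness to every feature of real
endoscopic data.

## Calibration experiments and their scope

The two headline validation quantities are computed by
`scripts/acceptance.R`: whole-function null coverage of the simultaneous
difference band (500 replicate two-arm cohorts with identical truth,
n = 20/arm) and average across-the-function coverage of the pointwise
interval around a curved truth (500 single-arm replicates). Both use
exchangeable Gaussian noise at the generator's observation-noise default
with the between-tumor offset switched off. That choice is deliberate:
coverage at the nominal level is a property of the method *under its
sampling assumptions*, and the trend model deliberately carries no
per-tumor random effects. With `subject_sd` at its cohort default the
same experiment shows substantial undercoverage (the shared offsets make
errors within a tumor correlated, so the model underestimates the
variance of arm-level functionals) — which is exactly why the generator
exposes the offset as a separate dial: it marks the boundary of what the
exchangeable model can claim. Analyses of cohorts with strong per-tumor
level differences should treat the bands as anti-conservative; a
random-intercept extension is out of scope here.

Problem sizes throughout (500 coverage replicates, 200 detection
replicates, a $4\times4\times3\times3$ round-trip grid, 10,000 band
draws) are the package's validation defaults and complete in a few
minutes on one CPU.

## Numerical choices and degenerate inputs

Penalized systems are solved by QR of the penalty-augmented design
(never by forming $X^\top X + \lambda S$ explicitly), which keeps the
$\lambda \to \infty$ limit accurate to ~$10^{-12}$ where naive Cholesky
loses six digits. Efficiency estimation refuses non-negative
standard-curve slopes; calibration refuses non-positive
reference-minus-dark denominators, naming the offending wavelength;
`compute_mvd` errors on masks without tissue; score tallies emit empty
cells with denominator 0 rather than dividing by zero; duplicate
(tumor, week) score rows are an error naming the duplicate. Ties in the
triplicate outlier rule resolve to the first farthest value
(`which.max`), a deterministic tie-break. Seeds propagate from a single
global seed through stage-name hashing (`derive_seed`), so any stage can
be rerun in isolation with identical results; reruns of the full
pipeline are verified hash-identical.

## Known limitations

The surrogate forward model is qualitatively, not instrumentally,
correct — absolute perfusion values from real probes require the
instrument's own LUT (pluggable). The synthetic extinction table is not
laboratory data. The exchangeable-error trend model undercovers when
between-tumor heterogeneity is strong (see above). Fold-change
normalization pins week 1 at exactly 1, so inference near the baseline
week reflects the model's homoscedasticity assumption more than the
data. MVD compares ROI-level values as independent observations by
default (per-sample aggregation is a flag), and no across-metric joint
inference is attempted.
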