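---
title: "Quantitative K-trans mapping of blood-brain-barrier leakage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative K-trans mapping of blood-brain-barrier leakage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktransmap)
```

# The problem

Dynamic contrast-enhanced (DCE) MRI measures the leakage of a gadolinium
contrast agent across a disrupted blood-brain barrier (BBB), summarized per
voxel by the volume transfer coefficient $K^{trans}$ (min$^{-1}$). In small
animals a surface transceiver coil buys the signal-to-noise needed for high
spatiotemporal resolution, but at a price: the transmit field — and with it
the flip angle — varies several-fold across the brain, so signal intensity is
no longer a surrogate for contrast concentration. `ktransmap` implements the
full quantitative chain that makes surface-coil DCE quantitative:

1. **Flip-angle (B1) calibration** from a dual-TR spoiled-gradient-echo
   (SPGR/FLASH) pre-scan pair,
2. **M0 calibration** from a long-TR pre-scan,
3. **dynamic R1 inversion** of the T1-weighted series,
4. **AIF scaling** of a population-average arterial input function against a
   no-leakage reference region,
5. **extended Kety model fitting** with per-voxel selection between an
   irreversible and a reversible leakage model by a nested-model F-test.

Because no in-vivo data ship with the package, a digital rat-brain-like
phantom with fully known ground truth (`simulate_dataset()`) serves as the
test substrate for every stage.

# Signal model

The steady-state SPGR magnitude is

$$ S = M_0 \sin\alpha \,\frac{1 - E_1}{1 - \cos\alpha\, E_1},
   \qquad E_1 = e^{-TR \cdot R_1}, $$

with the echo-time decay factor treated as exactly 1: the sequence uses a
minimum-TE (2 ms) single echo and a low contrast dose, so transverse decay is
negligible and TE is carried as metadata only. Flip angles are degrees at
every interface and radians internally.

`invert_r1()` solves this equation for $R_1$ in closed form. Voxels whose
normalized signal is inconsistent with the model (saturation factor outside
$(0,1)$, as happens under noise) are *flagged* `NA`, never clamped — silent
clamping would bias the downstream $\Delta R_1$ curves. The inversion uses a
cancellation-minimizing rearrangement ($1-\cos\alpha = 2\sin^2(\alpha/2)$);
its accuracy is then limited purely by conditioning. At deep saturation the
forward map loses information: at $TR \cdot R_1 = 15$ the signal sits within
$3\times10^{-7}$ of full recovery and even infinitely precise inversion of a
double-precision signal errs by $\sim 3\times10^{-9}$ relative (amplification
$\approx \varepsilon\, e^{TR R_1}/(TR \cdot R_1)$). For the regimes that
matter here ($TR \cdot R_1 \le 6$) the round trip is exact to $10^{-12}$.

# Calibration

**Flip angle.** The ratio of SPGR magnitudes at TR = 200 ms and 64 ms depends
strongly on $\alpha$ and only weakly on T1; since brain-tissue T1 is narrowly
distributed (roughly 1.5–2.1 s at 7 T), a single assumed T1 (default 1.8 s)
suffices. The ratio is strictly monotone in $\alpha$ (grid-verified at
startup), so `estimate_alpha_raw()` inverts it by per-voxel bisection on
$[1^\circ, 89^\circ]$ to $10^{-9}$ degrees — tight enough that bisection
error is invisible next to every other error source. The "weak" T1
dependence is weak but real: a voxel with true T1 = 1.5 s inverted under the
1.8 s assumption reads 27.48° instead of 30°.

**Smoothing.** The transmit field varies smoothly with depth, while the
T1-induced errors of the raw map are local (tissue-dependent). The default
`smooth_alpha()` therefore fits a per-slice 2-D polynomial surface (order 3)
by iteratively reweighted least squares with Tukey bisquare weights: voxels
whose raw angle deviates locally — elevated-T1 edema, blood, CSF — are
downweighted against the majority surface instead of bending it. Gaussian
normalized-convolution smoothing is available as an alternative and as the
automatic fallback for rank-deficient or data-starved slices. Output is
clipped to $[1^\circ, 89^\circ]$ with a message.

**M0.** Two estimators are provided:

* `estimate_m0()` — the long-TR estimator $M_0 = M_{3000}/\sin\alpha$. At
  TR = 3 s and T1 = 1.8 s the residual saturation factor
  $(1-E_1)/(1-\cos\alpha E_1) \approx 0.97$ is *not* 1, so this estimator
  underestimates M0 by a known, exposed factor
  (`m0_saturation_factor()`).
* `estimate_m0_corrected()` (the default in `calibrate()` and the pipeline)
  — solves (M0, baseline R1) jointly from the 64 ms/3000 ms pair: at known
  $\alpha$ their ratio is strictly decreasing in R1, so a second bisection
  yields R1 and then M0 exactly. We made this the default after quantifying
  the alternative: the uncorrected bias factor varies with depth and T1, and
  distorts $\Delta R_1$ by a factor of 1.04–1.10 that differs between the
  reference region and the lesion, which propagates into a 5–20% regional
  $K^{trans}$ error. The corrected path removes this entirely while using
  only the same three pre-scans; the plain estimator remains available
  (`m0_method = "long_tr"`) for fidelity comparisons.

# Dynamic R1 and the AIF

`compute_r1_series()` inverts every frame, averages the pre-injection frames
(those earlier than both the injection time and the baseline duration;
15 frames under the default 2-min baseline at 8 s resolution) into a baseline
R1, and subtracts to give $\Delta R_1(t)$, which is proportional to tissue
contrast concentration. Fitting is done directly in $\Delta R_1$ units
without relaxivity conversion — tissue and plasma curves share units, so
$K^{trans}$ is unaffected as long as relaxivity is spatially uniform.

The arterial input function is a population-average *shape* scaled to the
individual: assuming the contralesional caudate-putamen has no leakage and a
plasma volume fraction $v_p^{ref}$ (default 1%), its tissue curve equals
$v_p^{ref}\, C_p(t)$, so averaging both curves over a late window (default
3–9 min post injection, half-open, trapezoidal time-averaging) gives the
scale factor $k = \overline{\Delta R_1^{ref}} / (v_p^{ref}\,
\overline{C_p^{tmpl}})$. Scaling is exactly invariant to the template's
overall level. The shipped template is a configurable bi-exponential
(defaults: 16 s linear rise, amplitudes 4.0 and 1.5 s$^{-1}$, decay rates
0.007 and 4×10$^{-4}$ s$^{-1}$ — a fast distribution phase with ~100 s
half-life and a slow renal elimination phase of ~29 min, typical
small-molecule gadolinium kinetics in the rat). All kinetic-recovery tests
use the phantom's own ground-truth AIF, so their validity does not depend on
the realism of the template shape. A venous curve from a single
sagittal-sinus voxel (`extract_vif()`) cross-checks the scaling; its Pearson
correlation with the scaled AIF is reported as QC.

At curve SNR 20 the scale factor estimated from the ~400-voxel reference
region recovers the true AIF to a few percent RMSE; this is the one stage
whose accuracy rests on ROI averaging, and it degrades with smaller
reference regions.

# Kinetic models and selection

The extended Kety model in $\Delta R_1$ units:

$$ \Delta R_1^{tissue}(t) = v_p\, C_p(t) + K^{trans} \int_0^t C_p(\tau)\,
   e^{-k_{ep}(t-\tau)}\, d\tau. $$

Rates are min$^{-1}$ at the interface and s$^{-1}$ internally. The
convolution uses the recursive trapezoid identity
$I_i = E_i I_{i-1} + \tfrac{\Delta t}{2}(E_i C_{p,i-1} + C_{p,i})$,
algebraically identical to full-grid trapezoid integration of the sampled
integrand but $O(n)$ and overflow-safe. On the 8 s grid the discretization
error is $(k_{ep}\Delta t)^2/12$ relative — below 0.1% for $k_{ep}$ up to
about 0.8 min$^{-1}$, comfortably covering BBB leakage rates (tumor-grade
rates would need a faster grid).

* **Model 2 (irreversible, $k_{ep}=0$)** is linear in $(v_p, K^{trans})$
  with regressors $C_p$ and $\int C_p$; `fit_model2()` computes the exact
  least-squares minimizer from the normal equations (2×2, well conditioned
  after the monotone-regressor check; rank-deficient designs are flagged).
* **Model 3 (reversible)** is fitted by variable projection: for each
  candidate $k_{ep}$ the conditionally linear pair is solved in closed form;
  the $k_{ep}$ profile is searched on a 50-point log grid over
  $[10^{-3}, 10]$ min$^{-1}$ plus the exact $k_{ep}=0$ candidate, then
  refined by 14 rounds of bracketed 5-point subdivision between the grid
  neighbors of the minimum (final bracket $\sim 2\times10^{-5}$ relative).
  Including $k_{ep}=0$ — evaluated through the *same* arithmetic path as
  model 2 — guarantees $SSE_3 \le SSE_2$ exactly, so the F-statistic is
  never negative by construction.

Estimates are unconstrained (negative values are retained and reported);
model selection, not a positivity constraint, is the noise-control mechanism.

**Selection.** Models 2 and 3 differ by one parameter, giving

$$ F = \frac{SSE_2 - SSE_3}{SSE_3 / (N-3)}, \qquad df = (1,\, N-3), $$

with $N$ = 90 frames. The denominator degrees of freedom are configurable;
$(N-3)$ counts the three parameters of the richer model. A voxel switches to
model 3 only when $F > F_0$ with $F_0 = 10$ — deliberately conservative
versus the ~3.95 nominal 5% critical value of $F_{1,87}$, because the
maximization over $k_{ep}$ inflates the statistic's null distribution. Ties
at exactly $F_0$ keep the simpler model. Degenerate cases: $SSE_3 = 0$ with
$SSE_2 > 0$ gives $F = \infty$ (model 3); two perfect fits tie at $F = 0$
(model 2). The final maps stitch model-3 parameters inside the selection
mask and model-2 parameters elsewhere, with $k_{ep} = 0$ outside the mask.

Monte-Carlo operating characteristics at curve SNR 20 (peak clean signal /
noise SD), 90 frames, 500–1000 replicates per condition: $K^{trans}$ bias
below 0.1% and RMSE 1–2% for truth in 0.005–0.05 min$^{-1}$; false model-3
selection below 1%; detection of strong reversible leakage
($K^{trans} = 0.05$, $k_{ep} = 0.5$ min$^{-1}$) at 100%. Fitting model 2
everywhere *underestimates* $K^{trans}$ several-fold where reversible flux
is strong; fitting model 3 everywhere inflates the $K^{trans}$ variance by a
factor ~4 on irreversible voxels — both effects motivate the selection
scheme, and both are asserted in the test suite.

# The digital phantom

`default_tbi_spec()` builds a five-slice 64×64 phantom (in-plane downscaled
from the 128×128 acquisition matrix to keep simulation fast; pass
`grid = c(128, 128, 5)` for full size) with an elliptical brain and six
labeled regions:

| region | T1 (s) | $K^{trans}$ (min$^{-1}$) | $v_p$ | $k_{ep}$ (min$^{-1}$) |
|---|---|---|---|---|
| focal lesion | 2.1 | 0.05 | 0.02 | 0.5 |
| perifocal rim | 1.9 | 0.01 | 0.01 | 0 |
| remote tissue | 1.8 | 0 | 0 | 0 |
| reference (caudate-putamen) | 1.7 | 0 | 0.01 | 0 |
| sagittal sinus (1 voxel/slice) | 1.5 | 0 | 1 | 0 |

Magnitudes are plausible for mild-to-moderate cortical impact: a dorsal
focal lesion with strong *reversible* leakage (contrast accumulates enough
to back-flux), a weakly leaking irreversible rim, and intact tissue. The
remote region carries $v_p = 0$ so that, noiselessly, its dynamic frames are
exactly constant — a convenient null; the reference region keeps the
vascularized no-leakage configuration ($v_p = 0.01$) that the AIF scaling
assumes. T1 values span the measured brain range of 1.5–2.1 s.

The surface coil is modeled as a linear depth profile of the transmit angle
across the brain, 45° dorsal to 15° ventral (extended linearly outside,
clipped to $[1^\circ, 89^\circ]$), with an exponentially decaying receive
sensitivity normalized to 1 at the coil surface; a `"flat"` profile (uniform
30°, unit sensitivity) is the control configuration. Noise is `"none"`,
`"gaussian"` (additive, linear-theory; background voxels may go negative) or
`"rician"` (magnitude of two independent Gaussian channels), seeded and
bit-reproducible; the level is set by `sigma` in scanner units or `snr` =
mean noiseless baseline brain signal / sigma. Curve-level Monte-Carlo
simulations (`simulate_tissue_curves()`) define SNR as peak clean tissue
curve / noise SD instead.

What the phantom deliberately does *not* emulate: anatomically realistic
geometry, motion, scanner drift, bolus dispersion or delay, partial-volume
mixing at region boundaries, spatially varying relaxivity, slice-profile and
B0 effects, and within-region parameter texture. Tests passing on the
phantom therefore validate the *estimation chain* — calibration, inversion,
scaling, fitting, selection — under known physics, not robustness to every
in-vivo confound.

# Numerical choices and degenerate inputs

* Bisection tolerances: $10^{-9}$ deg (flip angle), $10^{-12}$ s$^{-1}$
  (corrected M0); both far below every physical error source.
* The trapezoid rule is used consistently for forward simulation, fitting
  regressors, and AIF window means, so noiseless fits are exact in the span
  of the discretized model.
* Invalid voxels (failed inversion, rank-deficient design, unattainable
  ratio) carry `NA` flags and are skipped downstream; they never raise
  global failures.
* Erosion for ROI summaries removes voxels whose in-plane 4-neighborhood
  leaves their label — one iteration strips exactly the 1-voxel rim, the
  documented guard against brain-boundary hyperintensities.
* Dice on two empty masks is defined as 1 (messaged). The selection-mask
  Dice reported by the QC stage compares the voxels assigned model 2 (resp.
  model 3) in the final map against all fitted voxels; any other mask pair
  can be passed explicitly to `dice_coefficient()`.
* Problem sizes used by the shipped validation: 64×64×5 phantom (~8800
  brain voxels), 90 frames, 500–1000 Monte-Carlo replicates per condition —
  the full suite runs in well under two minutes on one core, and all
  problem sizes scale up via configuration.

# Known limitations

* $K^{trans}$ is in $\Delta R_1$-ratio units; comparability with
  concentration-based analyses rests on relaxivity cancelling between
  tissue and plasma.
* The AIF template shape is user input; only its scale is estimated. No
  dispersion/delay correction is applied.
* Water-exchange effects, Patlak/Logan graphical variants, and a
  vascular-only model tier are out of scope.
* The F-threshold $F_0 = 10$ is calibrated for 90 frames; shorter series
  change the null distribution and may warrant re-tuning.
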