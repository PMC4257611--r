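# ktransmap

Quantitative mapping of blood–brain-barrier (BBB) leakage from dynamic
contrast-enhanced (DCE) MRI acquired with a surface transceiver coil.

After traumatic brain injury, contrast agent leaks across the disrupted BBB;
the volume transfer coefficient **K^trans (min⁻¹)** quantifies that leakage
per voxel and can be followed longitudinally, unlike terminal histology.
Surface coils provide the SNR needed for high-resolution dynamic imaging of
the rodent brain but make the flip angle — and therefore signal intensity —
strongly depth-dependent. `ktransmap` implements the full calibrated chain
that makes such data quantitative, and is aimed at preclinical imaging
groups processing multi-slice 2D FLASH DCE protocols (three-TR pre-scan +
fast dynamic series).

## Method

Per voxel, with S the spoiled-gradient-echo (SPGR) magnitude:

- **Signal model** — S = M₀ sin α (1−E₁)/(1−cos α E₁), E₁ = e^(−TR·R₁);
  closed-form inversion for R₁, with flagged (never clamped) failures.
- **Calibration** — flip angle α from the monotone M_200ms/M_64ms ratio by
  bisection at an assumed tissue T1 (1.8 s), smoothed by a robust per-slice
  polynomial surface; M₀ from the pre-scans, either jointly with baseline R₁
  from the 64/3000 ms pair (default, exact) or as M_3000/sin α (the
  long-TR estimator with its documented saturation bias).
- **Dynamic ΔR₁** — per-frame inversion minus the pre-injection baseline
  average; ΔR₁ is proportional to tissue contrast concentration.
- **AIF** — a population bi-exponential template scaled so that a
  no-leakage reference region (contralesional caudate-putamen, plasma
  volume 1%) obeys ΔR₁ = 0.01·Cp over the 3–9 min post-injection window;
  a single-voxel sagittal-sinus venous curve cross-checks the scaling.
- **Kinetics** — extended Kety model
  ΔR₁(t) = v_p Cp(t) + K^trans ∫₀ᵗ Cp(τ) e^(−k_ep(t−τ)) dτ, fitted per voxel
  as the irreversible **model 2** (k_ep = 0; exact linear least squares) and
  the reversible **model 3** (variable projection over a log-grid of k_ep
  with bracketed refinement; the k_ep = 0 candidate guarantees nesting).
- **Selection** — F = (SSE₂−SSE₃)/(SSE₃/(N−3)), df (1, N−3); model 3 is
  taken only where F > F₀ = 10. The final K^trans map stitches the selected
  model per voxel.

A seeded digital rat-brain phantom (`simulate_dataset()`) with known
regional ground truth, surface-coil transmit/receive profiles and
Gaussian/Rician noise validates every stage; see the methods vignette
(`vignettes/ktrans-mapping.Rmd`) for assumptions and design decisions.

## Worked example

```r
library(ktransmap)

# a noisy phantom: 64x64x5, 90 frames at 8 s, Rician noise at SNR 20
ph <- simulate_dataset(default_tbi_spec(noise = list(model = "rician", snr = 20),
                                        seed = 42))
res <- run_pipeline(ph$prescans, ph$dynamic, ph$masks$brain,
                    ph$masks$reference, ph$truth$aif, ph$spec$acq,
                    sinus_voxel = ph$sinus_voxel,
                    labels = ph$truth$region_labels)
print(res)
#> <ktrans_maps> 8760 voxels fit (n=90 frames, F0=10); model 3 selected in 436 (5.0%)
#>   AIF/VIF correlation: 0.9991

roi_summary(res$maps$ktrans_final, ph$truth$region_labels, erode = 1,
            level_names = c("remote", "focal", "perifocal",
                            "reference_cpu", "sinus"))
#>          region    n          mean          sem
#> 1        remote 6275  1.471140e-04 1.968958e-04
#> 2         focal  275  5.239185e-02 3.143770e-04
#> 3     perifocal  485  1.043909e-02 2.348472e-05
#> 4 reference_cpu  270 -8.322639e-07 2.965182e-05
```

The fitted means recover the regional ground truth (focal 0.05, perifocal
0.01, remote/reference 0 min⁻¹) to a few percent at this noise level; the
focal lesion — simulated with strong reversible leakage — is the region
where model 3 is selected (100% of its voxels, i.e. 5% of the brain), and
fitting it with the irreversible model alone would underestimate its
K^trans several-fold. `write_pipeline_outputs(res, "out/")` writes the maps
as NIfTI plus the scaled AIF, ROI table and a JSON manifest.

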