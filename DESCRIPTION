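Package: ktransmap
Title: Quantitative K-trans Mapping of Blood-Brain-Barrier Leakage from
    DCE-MRI with Surface-Coil Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise pharmacokinetic mapping of blood-brain-barrier (BBB)
    leakage from dynamic contrast-enhanced (DCE) MRI acquired with a surface
    transceiver coil. Implements dual-TR spoiled-gradient-echo (SPGR/FLASH)
    flip-angle (B1) mapping and long-TR M0 calibration, closed-form dynamic
    R1 inversion, scaling of a population arterial input function against a
    no-leakage reference region, and extended Kety model fitting with
    irreversible and reversible leakage variants selected per voxel by a
    nested-model F-statistic. Ships a digital rat-brain-like phantom
    generator with known ground truth for validation, NIfTI-1 input/output,
    QC metrics (Dice overlap, AIF/VIF agreement, ROI summaries), and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
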