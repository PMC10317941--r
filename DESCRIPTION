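Package: sirtdose
Title: Voxel-Level Dosimetry and Simulation-Therapy Agreement Analysis for
    Yttrium-90 Radioembolization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-based internal dosimetry for selective internal radiation
    therapy (SIRT) of liver malignancies with yttrium-90 microspheres.
    Converts pre-therapy Tc-99m-MAA and post-therapy Y-90 bremsstrahlung
    SPECT count maps into absorbed-dose maps by activity self-calibration
    and the local deposition method, derives tumoral and non-tumoral liver
    volumes of interest with a small-lesion filter, computes mean absorbed
    dose, cumulative dose-volume-histogram metrics (Dx, Vx) and
    tumour-to-normal ratios, and runs the full simulation-versus-therapy
    agreement protocol (rank tests, Pearson correlation with strength
    categories, linear regression, relative differences, Bland-Altman
    limits, volume stratification, voxel-wise joint histograms). Includes a
    seeded synthetic phantom generator producing paired count maps with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
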