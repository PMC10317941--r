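# sirtdose

Voxel-level dosimetry and simulation–therapy agreement analysis for
yttrium-90 radioembolization (SIRT) of liver malignancies.

In SIRT, a pre-therapy ⁹⁹ᵐTc-MAA SPECT/CT ("simulation") is used as a
surrogate for the ⁹⁰Y microsphere distribution actually delivered, which is
verified afterwards on ⁹⁰Y bremsstrahlung SPECT/CT ("therapy"). `sirtdose`
answers the theragnostic question — how well does simulation dosimetry
predict therapy dosimetry? — with a complete, tested pipeline:

* **Image/mask model** — axis-aligned 3-D grids, NIfTI I/O, trilinear /
  nearest-neighbour resampling to the simulation reference grid, VOI
  algebra (tumoral liver TL = union of lesions, non-tumoral target NTLt,
  non-tumoral whole liver NTLw) with the 4-ml small-lesion exclusion.
* **Dosimetry** — activity self-calibration
  `A_v = c_v / Σ c_liver · A_net` (both arms calibrated to the same net
  ⁹⁰Y activity, injected minus residual) and the local deposition method:
  `D_v = A_v · (T½/ln 2) · E / (ρ · V_voxel)` with T½ = 64.1 h,
  E = 0.93 MeV, ρ = 1.05 g/cm³. The kernel's closed form is
  ≈ 49.61 Gy·kg/GBq, so the mean dose over any region is
  `49.61 · A_net / mass` for *any* spatial distribution.
* **Dose metrics** — mean absorbed dose (MAD), exact step-function DVH,
  Dx (minimum dose to the hottest x% of the volume, no interpolation), Vx
  (% of volume receiving ≥ x Gy), and the tumour-to-normal ratio
  `TNR = (A_TL/M_TL) / (A_NTL/M_NTL)`, in absolute Gy and normalized
  Gy/GBq.
* **Agreement statistics** — Mann–Whitney U, Pearson r with strength
  categories, OLS regression in both orientations, per-case relative
  differences with zero-denominator flagging, Bland–Altman bias and 95%
  limits, Kruskal–Wallis covariate tests, 200-ml tumoral-volume
  stratification, voxel-wise joint histograms, and publication-shaped
  cohort tables.
* **Synthetic phantoms** — a seeded generator of paired simulation/therapy
  cases (ellipsoidal liver, spherical lesions, lognormal uptake
  heterogeneity, Gaussian PSF, Poisson counts, controlled tumour
  overestimation bias) with exact ground truth for recovery testing.

## Worked example

```r
library(sirtdose)

cases  <- generate_cohort(6, seed = 1, bias_T_mean = 1.26)  # paired phantoms
cohort <- run_cohort(cases)

m <- cohort$tables$metrics
m[m$metric == "MAD", c("voi", "sim_mean", "ther_mean", "wilcoxon_p",
                       "pearson_r", "r_category", "rel_diff_mean")]
#>     voi sim_mean ther_mean wilcoxon_p pearson_r  r_category rel_diff_mean
#> 1    TL     66.5      51.8      0.310     0.943 very strong         29.64
#> 7  NTLt     23.9      25.3      0.485     0.991 very strong         -5.85
#> 14 NTLw     23.2      24.9      0.485     0.988 very strong         -7.51

t <- cohort$tables$tnr
t[t$stratum == "all", c("reference", "sim_mean", "ther_mean",
                        "pearson_r", "ba_bias", "ba_lower", "ba_upper")]
#>   reference sim_mean ther_mean pearson_r ba_bias ba_lower ba_upper
#> 1      ntlt     3.01      2.10     0.973  -0.913    -2.66    0.831
#> 2      ntlw     3.16      2.14     0.974  -1.016    -3.08    1.042
```

Reading the output: the simulation arm carries a deliberate tumour dose
bias of 1.26, and the pipeline recovers it — tumour mean absorbed dose
(Gy/GBq) is overestimated by ~30% in this small cohort while non-tumoral
liver is mildly underestimated (the self-calibration budget is fixed, so
tumour excess comes at the expense of normal tissue); correlations are
very strong everywhere but weakest for tumour; simulation TNR (3.0)
overestimates therapy TNR (2.1), giving a negative Bland–Altman bias.
`write_tables(cohort, "tables/")` exports the four cohort tables as CSV.

A thin command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sirtdose.R", package="sirtdose"))')" \
    simulate --n 5 --seed 1 --out cases/
Rscript "$(Rscript -e 'cat(system.file("cli/sirtdose.R", package="sirtdose"))')" \
    run --manifest cases/manifest.csv --out results/
```

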