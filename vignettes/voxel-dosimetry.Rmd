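---
title: "Voxel-level dosimetry and simulation-therapy agreement for Y-90 SIRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-level dosimetry and simulation-therapy agreement for Y-90 SIRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Selective internal radiation therapy (SIRT) treats liver malignancies by
infusing yttrium-90-loaded microspheres through the hepatic arteries. The
treatment is planned with a pre-therapy surrogate: technetium-99m-labelled
macroaggregated albumin (Tc-99m-MAA) is injected in the same way, imaged by
SPECT/CT, and read as a prediction of where the microspheres will lodge
("simulation"). After the infusion the actual microsphere distribution is
imaged by Y-90 bremsstrahlung SPECT/CT ("therapy"). The theragnostic
question is how well simulation dosimetry predicts therapy dosimetry — per
volume of interest and per dose-distribution metric.

`sirtdose` implements the full comparison pipeline at the voxel level:
activity self-calibration, local-deposition dose maps, per-VOI dose
metrics, and the cohort agreement statistics, plus a synthetic phantom
generator that produces paired count maps with known ground truth so every
stage can be validated end to end.

## Dose model

The dosimetry rests on four standard assumptions: microspheres are trapped
permanently (physical decay only, no biological clearance); there is no
activity shunt outside the liver; each voxel's decay energy is absorbed in
that voxel (local deposition method, LDM — no cross-voxel kernel); and the
constants are the Y-90 half-life $T_{1/2} = 64.1$ h, mean energy per decay
$E = 0.93$ MeV, and liver density $\rho = 1.05$ g/cm$^3$.

**Self-calibration.** SPECT counts are proportional to activity but the
constant is scanner-dependent. With a known net administered activity
$A_{net}$ (injected minus vial residual; the lung-shunt correction is off
by default under the no-shunt assumption, both toggles are exposed), the
activity in voxel $v$ is

$$A_v = \frac{c_v}{\sum_{u \in \mathrm{liver}} c_u}\, A_{net},$$

with zero activity assigned outside the calibration region (the whole
liver by default; configurable to the full field of view). Both arms are
calibrated to the *same* Y-90 $A_{net}$: the MAA image is used purely as a
spatial distribution surrogate, so "simulation dosimetry" is Y-90
dosimetry evaluated on the MAA distribution. No Tc-99m decay data enter
anywhere.

**Local deposition.** The time-integrated activity under permanent
trapping is $\tilde A_v = A_v T_{1/2}/\ln 2$, and the voxel dose is

$$D_v = \frac{\tilde A_v \, E}{\rho \, V_{voxel}}.$$

A useful closed-form corollary: per GBq of net activity the deposited
energy is $(T_{1/2}/\ln 2)\, E \approx 49.61$ Gy·kg/GBq, so the mean dose
over any region of mass $M$ receiving activity $A$ is $49.61\,A/M$ Gy
*regardless of the spatial distribution* — an identity the test suite
checks to $10^{-9}$ relative on random distributions, and a convenient
hand check (1 MBq confined to a 1 cm$^3$ voxel gives 47.24 Gy).

## Volumes of interest and metrics

Three VOIs are derived from the liver, targeted-lobe and lesion contours
(all assumed co-registered and resampled to the simulation grid; masks are
resampled nearest-neighbour, continuous maps trilinearly): tumoral liver
`TL` (union of retained lesions), non-tumoral target `NTLt` (lobe
$\cap$ liver $\setminus$ TL) and non-tumoral whole liver `NTLw` (liver
$\setminus$ TL). Lesions under 4 ml (about a 2-cm sphere) are excluded —
they are unreliable on SPECT because of partial-volume effects and
registration sensitivity; the threshold is strict (< 4 ml dropped, 4.0 ml
kept). Lobe contours drawn on CT may spill outside the liver contour, so
`NTLt` intersects with the liver first; this is a configurable choice.

Per VOI and arm the package reports the mean absorbed dose (MAD), the
exact cumulative DVH, and

* $D_x$ — the minimum dose received by the hottest $x\%$ of the volume,
  evaluated on the unbinned step DVH as the $\lceil xN/100\rceil$-th
  largest voxel dose (no interpolation; an interpolated variant exists for
  plot parity only). $D_{50}, D_{70}, D_{95}$ are reported for all VOIs.
* $V_x$ — the percentage of the volume receiving at least $x$ Gy;
  $V_{120}, V_{205}$ for tumour (tumoricidal thresholds), $V_{20}, V_{50},
  V_{90}$ for non-tumoral liver (toxicity thresholds).
* TNR $= (A_{TL}/M_{TL})/(A_{NTL}/M_{NTL})$, computed against both `NTLt`
  and `NTLw`. TNR is invariant to global rescaling of the activity map, so
  the simulation TNR needs no Y-90 calibration.

Dose metrics are reported in absolute Gy and normalized Gy/GBq of net
activity; $V_x$ thresholds are absolute Gy. The step-DVH estimator was
chosen because it matches the printed definitions literally and is exactly
testable against a sorted-voxel oracle; with the cohort data unavailable,
fidelity to any published interpolation variant cannot be checked, so
testability decided.

## Agreement protocol

Per metric and VOI the cohort tables report mean ± SD for both arms, a
two-sided unpaired Mann–Whitney U test at $\alpha = 0.05$ (the protocol
names the unpaired rank-sum test even though the data are paired; a
signed-rank variant is available behind `paired = TRUE`), Pearson's $r$
with the conventional strength bands on $|r|$ ([0, 0.3) very weak up to
[0.9, 1] very strong, half-open), OLS regression, the per-case relative
difference $100(\mathrm{sim}-\mathrm{ther})/\mathrm{ther}$ (undefined when
the therapy value is zero; such metrics are flagged rather than silently
averaged), Bland–Altman bias with 1.96 SD limits oriented therapy minus
simulation (negative bias = simulation overestimates), Kruskal–Wallis
tests for discrete covariates, a tumoral-volume stratification at 200 ml
(inclusive on the small side), and voxel-wise joint histograms with OLS
lines on the raw voxel pairs.

Regression orientation deserves a note: therapy-on-simulation is the
planning direction and is reported as primary, but under simulation
overestimation its slope falls below one while the
simulation-on-therapy slope exceeds one; both orientations are reported
(`slope_ther_on_sim`, `slope_sim_on_ther`) because the overestimation
direction is conventionally quoted as "slope greater than unity". No
multiple-testing correction is applied, matching the protocol. Rank tests
use exact enumeration for small tie-free samples and the tie- and
continuity-corrected normal approximation otherwise, via `wilcox.test` and
`kruskal.test`; the test suite cross-checks them against brute-force
enumeration and the textbook rank formula.

## The synthetic phantom

No patient data accompany this package, so validation runs on a generator
that emulates the *statistical structure* of a retrospective glass-
microsphere cohort:

* geometry: ellipsoidal liver (default semi-axes 100/80/55 mm, about
  1.84 l) on a 64³ grid at 4 mm, split by a sagittal plane into a treated
  and an untreated lobe (right lobe about two thirds), with spherical
  lesions inside the treated lobe;
* uptake: mean-corrected multiplicative lognormal heterogeneity
  ($\mu = -\sigma^2/2$ so expectations are unbiased), $\sigma_n = 0.3$ in
  normal tissue, $\sigma_t = 0.5$ in tumour, and an expected
  tumour-to-normal specific-uptake ratio `tnr_true`;
* imaging: isotropic Gaussian PSF (default FWHM 12 mm, typical of SPECT;
  the therapy arm can be given a wider PSF to mimic bremsstrahlung's
  poorer resolution) applied to expected counts, then Poisson sampling at
  an expected total of $3\times 10^6$ counts;
* discordance: the simulation arm multiplies the latent uptake by a
  voxel-wise mean-corrected lognormal field ($\tau_t = 0.4$ in tumour
  $> \tau_n = 0.15$ elsewhere) and a tumour uptake bias.

**Why the bias is parameterized post-calibration.** Self-calibration fixes
the summed liver activity, so multiplying tumour counts by a raw factor
$b$ yields an observed tumour dose bias $b/(1+s(b-1))$ that depends on the
tumour's count share $s$ — and PSF spill-out attenuates it further. The
generator therefore treats `bias_T` as the *observable*: it solves the
(linear) forward model, blur included, for the pre-calibration tumour
factor that makes the expected calibrated tumour dose ratio equal
`bias_T` regardless of tumour burden and resolution. At `bias_T = 1.26`
the pipeline recovers a +26% tumour overestimation; without blur the
solution reduces to $f = b(1-s)/(1-bs)$.

**Cohort distributions.** `generate_cohort()` draws per case: injected
activity lognormal around 2.6 GBq, liver scale lognormal (volume spread
roughly 0.9–3.5 l), tumoral volume lognormal around 180 ml spanning both
volume strata, expected TNR lognormal around 2.3, one dominant lesion
(sometimes two or three, the smallest of which may fall under the 4-ml
filter), treated lobe right in 75% of cases, and a per-case tumour bias
drawn as a mean-corrected lognormal around `bias_T_mean` (sdlog 0.18).
The case-level bias scatter represents catheter-position and flow
differences between the two injections — the accepted dominant mechanism
for simulation-therapy discordance — and is what makes tumour agreement
weaker than non-tumoral agreement at the cohort level: voxel-scale
discordance alone averages out over 100-ml VOIs. The sdlog of 0.18 and
the volume/TNR spreads were calibrated once so that the generated cohorts
reproduce the published agreement structure (tumour Pearson r about 0.9,
non-tumoral about 0.95–0.98, wide per-case relative-difference ranges); a
joint cap on tumour volume (≤ 35% of the liver) and uptake share
(bias × share ≤ 0.6) encodes the observed large-tumour/low-TNR
anticorrelation and keeps the requested bias physically achievable.

**What the phantom does not emulate**: SPECT projection/reconstruction
(no OSEM, attenuation, scatter or reconstruction artefacts beyond the
Gaussian PSF), breathing motion, necrotic cores, registration error, or
anatomy beyond an ellipsoid-and-spheres geometry. Passing tests therefore
demonstrate the correctness of the dosimetry and statistics machinery and
the qualitative reproducibility of the published agreement pattern under
controlled discordance — not clinical performance on real images.

## Numerical choices and degenerate inputs

* Negative voxels (reconstruction ringing) are clamped to zero at load;
  non-finite voxels are an error. Masks binarize at 0.5.
* Resampling uses voxel-centre world coordinates on axis-aligned grids;
  reference voxels outside the input extent become zero/FALSE; disjoint
  extents are an error; resampling onto the same grid is an exact
  identity short-circuit.
* Zero total counts in the calibration region, an empty liver mask, an
  empty VOI for a metric, residual ≥ injected activity: errors. A zero
  NTL activity makes TNR undefined (`NA`), reported as missing. A zero
  therapy denominator makes that case's relative difference undefined and
  flags the metric.
* Cohort runs isolate failures: a corrupt case is logged and skipped; the
  run aborts only if fewer than two cases survive. All randomness flows
  through one integer seed per case; regenerating with the same seed is
  bit-identical.
* Problem sizes: the validation cohorts use 30 cases at 64³ (4 mm) — the
  scale at which the cohort statistics stabilize — and unit tests use 32³
  (8 mm) phantoms of the same field of view.

## A worked run

```{r, eval = FALSE}
library(sirtdose)
cases <- generate_cohort(30, seed = 1, bias_T_mean = 1.26)
cohort <- run_cohort(cases)
print(cohort)
write_tables(cohort, "tables/")
```

`scripts/acceptance.R` executes this end to end (plus the worked-example
arithmetic and the physics identities) and writes the headline numbers as
JSON; see the README for how to run it.

## Known limitations

Axis-aligned grids only (no oblique direction cosines); NIfTI I/O only;
constant tissue density (no CT-derived density maps); no partial-volume,
scatter or motion correction; no dose-point-kernel or Monte-Carlo
transport (LDM only); no radiobiological conversions (EQD2/BED); the
rigid registration itself is assumed done upstream.
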