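---
title: "Chemometric analysis of drop-coating deposition Raman spectra of glycated albumin"
author: "glycoDCDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric analysis of DCDR spectra of glycated albumin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoDCDR)
```

## The measurement problem

Glycated albumin is serum albumin that has reacted non-enzymatically with
glucose; its fraction of total albumin tracks average glycemia over the
preceding two to three weeks, complementing HbA1c. Drop-coating deposition
Raman (DCDR) spectroscopy measures protein Raman spectra off the annular
ring that a microliter droplet leaves when it dries: capillary flow carries
the solute to the pinned contact line (the coffee-ring effect), giving two
to three orders of magnitude of pre-concentration and strong, solution-free
spectra from microliter samples.

Glycation barely perturbs the albumin Raman signature — the modified
arginine, lysine and cysteine side chains contribute little scattering — so
the analysis is chemometric throughout: multivariate decomposition finds
the small but consistent spectral differences, a calibration model converts
spectra to concentrations, and figures of merit establish whether the
precision is clinically useful. `glycoDCDR` implements that entire chain,
together with a synthetic-data generator that emulates the study design so
every step is testable end to end.

## Data model

Spectral datasets are `SpectraSet` objects — `SummarizedExperiment`s with
one `intensity` assay (wavenumber channels x spectra), the common strictly
increasing wavenumber axis in `rowData`, and per-spectrum metadata (sample,
analyte class, concentration in uM, ring location, replicate, optional map
grid coordinates) in `colData`. The calibration design is 6 two-fold
dilutions per analyte — albumin 23.4-750 uM, glycated albumin 7.8-250 uM —
with 3 ring locations x 5 replicate spectra per sample: 90 spectra per
class, 180 in all, plus a 10 x 10 map grid (80 x 80 um at 8 um pitch) over
the ring of one glycated sample.

## The synthetic-spectrum generator

Pure-component spectra are sums of pseudo-Voigt bands
(`eta = 0.7` Lorentzian fraction, FWHM 12 cm^-1, typical of protein Raman
lines) at the 22 fingerprint-region band positions of drop-coated albumin,
normalized to unit maximum. Relative amplitudes are a design choice — the
band table fixes positions, not intensities — set so the principal peaks
dominate: 1.00 at 1002 cm^-1 (Phe), 0.85 amide-I, 0.80 CH2 deformation,
0.45/0.40 for the 850/828 tyrosine doublet, 0.35 for the CH deformation
pair, 0.30 at 1031, 0.20 for the remaining minor bands.

Glycation is modeled by three perturbations scaled by one effect size
`epsilon` (default 0.3):

* a new shoulder at 792 cm^-1 with amplitude `epsilon` times the 828 band,
* a tyrosine-doublet ratio shift, 828 scaled by `1 - 0.3 epsilon` and 850
  by `1 + 0.3 epsilon` (the doublet reports tyrosine hydrogen bonding),
* an amide-I center shift of `+6 epsilon` cm^-1 toward the beta-sheet
  position, reflecting the alpha-to-beta conversion of heavily glycated
  albumin.

A simulated spectrum is
`baseline + f * s * c * pure + noise`, with `s` the signal per uM, `c` the
concentration, `f` a lognormal per-location deposition factor shared by a
location's replicates, a fixed positive quadratic background of about 20%
of the 250 uM peak (quartz/fluorescence), and heteroscedastic Gaussian
noise of standard deviation `sqrt(sigma_read^2 + sigma_0^2 * clean)`
(read noise 2 counts, shot scale 0.5). Map pixels additionally carry the
asymmetric radial deposition profile of the ring — a plateau of 1.0 over
pixels 4-7, a gradual inner rise (0.40, 0.65, 0.85) and a steep outer fall
(0.80, 0.45, 0.10), the signature of complete desiccation at the pinned
outer contact line — plus a small angular jitter (s.d. 0.02).

Default calibration: `signalPerUM = 80` (a 20000-count phenylalanine peak
at 250 uM, consistent with 10-s acquisitions on the pre-concentrated ring;
per-point SNR at 1002 cm^-1 about 130 at the top standard) and
`locationSd = 0.02` (2% deposition reproducibility at constant radial
distance, the same order as the angular variation observed across the
ring). Under these conditions the two classes separate perfectly in the
score space (below) while the permutation controls stay near chance —
the qualitative regime the method is designed for.

What the generator deliberately does not emulate: spot-to-spot background
shape drift, wavenumber miscalibration, deposit morphology differences
between samples, or any matrix effect. Consequently the quantitative
figures of merit come out cleaner than real ring deposits would give
(relative errors of a few percent rather than tens of percent), and a
passing test suite demonstrates correctness of the algorithms under the
stated noise model, not instrument-grade performance. One structural
consequence is documented under *Known limitations*.

## Classification

`fitPCA()` performs column-mean-centered singular value decomposition with
no variance scaling (relative band intensity is the signal; scaling
channels would inflate noise regions). Loadings follow the sign convention
that each component's largest-magnitude element is positive; explained
fractions are squared singular values over their total. Discrimination
uses logistic regression on scores 2-4: the first component tracks overall
signal amplitude (here >99% of variance) and carries little class
information, while the glycation contrast concentrates in the next
components. The logistic plane is fitted by iteratively reweighted least
squares on internally standardized scores with a small ridge penalty
(`lambda = 1e-3`), which keeps the optimum finite and reproducible even
under perfect separation; coefficients are reported on the raw score
scale, and the decision rule calls a spectrum glycated when
`w0 + w . s > 0` (exact ties go to albumin).

Two permutation controls guard against chance correlation. Random mode
permutes the class labels over all 180 spectra and refits the plane (PCA
is label-free and is computed once). Measurement-order mode emulates the
drift control: acquisition is sample-blocked — each sample's 15 spectra
are measured together, the 12 samples interleaved in random order — and
the first half of the order is labeled one class, the second half the
other. Order-correlated labels respect the within-sample correlation
structure, which is why this control sits measurably above chance
(about 58%) without approaching the real-label accuracy.

## Quantification

`fitPLS()` is single-response NIPALS partial least squares on mean-centered
spectra and concentrations (no channel autoscaling, no baseline
correction — backgrounds are left to the multivariate model rather than
risking subtraction artifacts). Each latent variable extracts the weight
`w = X'y/|X'y|`, scores `t = Xw`, loadings `p = X't/t't`, `q = y't/t't`,
then deflates; the regression vector is `b = W(P'W)^{-1} q`. At full rank
NIPALS reproduces the least-squares fit, which the tests verify against an
SVD pseudoinverse oracle.

Accuracy and precision are estimated by leave-one-sample-out
cross-validation: each of the 6 glycated samples is predicted by a model
trained on the other 5 (75 spectra), so no spectrum is ever predicted by a
model that saw its sample. The latent-variable count is chosen inside each
training fold by leave-one-group-out RMSECV over 1..8 with a parsimony
rule (smallest count within 2% of the minimum) — the left-out sample never
influences the choice. Negative predictions are reported as-is; clipping
would bias the detection-limit statistics.

## Figures of merit

For N predictions with references `c_i` and predictions `chat_i`:

* REP (relative error of prediction):
  `(100/N) sum |c_i - chat_i| / c_i`. The root-mean-square variant is
  available via `computeREP(..., method = "rms")`; the mean-absolute form
  is the default because it reproduces the characteristic drop when the
  below-LOD sample is excluded.
* RSD: per concentration `c_k`, `100 * sd_k / c_k` with the sample (n-1)
  standard deviation of that group's predictions; the average is the mean
  over the distinct concentrations. The denominator is the reference
  concentration, not the mean prediction — the choice that makes the RSD
  exactly one third at the 3-sigma detection limit.
* Calibration line: ordinary least squares of predicted on reference, with
  `s_y/x = sqrt(sum r^2 / (N-2))` and Pearson r.
* LOD, calibration-plot form: `3 s_y/x / slope` (IUPAC 3-sigma). By
  construction the prediction standard deviation in concentration units,
  relative to this LOD, is exactly 33.3% — an identity the acceptance
  suite checks analytically.
* LOD, precision-profile form: the per-concentration RSD values are fitted
  with `RSD(c) = A exp(-B c) + C` (A, B > 0, C >= 0; the floor C captures
  the concentration-independent precision plateau) by bounded
  Levenberg-Marquardt from five data-driven starts, and the fit is solved
  for the 100/3 % crossing, `c = log(A / (100/3 - C)) / B`. A profile
  already below 33.3% at zero concentration reports an LOD of 0 with a
  flag; a flat (zero-residual) profile is represented as a vanishing decay
  on a floor, since A and B are then unidentifiable.

`meritReport()` assembles everything and can recompute REP and the average
RSD after excluding concentration groups whose reference lies below the
calibration-plot LOD (computed on the full set first).

## 2D mapping

`predictMap()` applies a PLS model — trained on the five calibration
samples other than the mapped one — to the 100 grid spectra and arranges
predictions with the radial direction along X (pixel 1 innermost) and the
angular approximation along Y. `radialProfile()` (per-column means)
recovers the asymmetric ring shape; `angularCV()` (per-column sd/mean,
zero-mean columns flagged rather than fatal) quantifies angular
reproducibility, of order a few percent at the defaults; and
`centerBandMean()` averages the plateau columns 5-6, which should
reproduce the reference concentration of the mapped sample.

## Numerical choices and degenerate inputs

* IRLS converges at a maximum coefficient change of 1e-8 (at most 200
  iterations) with step-halving on the penalized likelihood; the
  overflow-safe `log(1+e^x)` is used throughout.
* PCA of a constant dataset returns canonical axes with zero explained
  variance instead of failing; logistic on all-zero scores degenerates to
  the intercept and predicts the majority class.
* The cosmic-ray filter replaces points whose deviation from the 5-point
  running median exceeds 100 times the local robust scale. Two details
  matter on peaked spectra: points on a locally monotone flank are their
  own window median, so the running MAD is floored at half the global MAD
  of the *positive* deviations; and genuine band tips reach modified
  z-scores near 50 at ring-deposit SNR, so the threshold sits at 100,
  far below the 10^3-10^5 scored by real single-pixel spikes.
* The display-only baseline remover is the iterative modified polynomial
  fit (order 5, clip to the pointwise minimum of spectrum and fit, relative
  tolerance 1e-4, at most 100 iterations, warning on non-convergence). It
  is never applied in the quantitative path.
* CSV output writes intensities with 17 significant digits so a write/read
  cycle is bit-exact.
* Every generator entry point draws from one seeded stream (the config
  seed), restoring the caller's RNG state afterwards; map generation
  offsets the seed so calibration and map draws are independent.

## Problem sizes

The test suite and the acceptance script run the full study design (180 +
100 spectra, 601 channels); seed sweeps use 10-20 replicates per property
and 100-200 permutations per control study, sizes at which every check
completes in seconds on a single core while keeping Monte Carlo error well
inside the asserted margins.

## Known limitations

* The generator's clean signal spans only the two pure-component
  directions plus a fixed background. Real ring deposits carry
  higher-dimensional between-spectrum structure (background drift, deposit
  morphology), which is what makes real low-concentration precision much
  worse than simulated precision. One measurable consequence: in this
  generator the within-concentration RSD profile stays at the percent
  level across the whole range and never approaches the 33.3% crossing, so
  the precision-profile LOD extrapolates to zero and does not agree with
  the calibration-plot LOD. The two estimators agree on real-scale data
  where absolute prediction error is roughly constant in concentration
  units; reproducing that regime in this generator would require
  between-spectrum variability large enough to displace the glycation
  contrast from score components 2-4 and destroy the classification it is
  also required to support. The estimators themselves are exact and are
  verified against closed-form cases.
* Training-set accuracy is the reported classification figure; grouped
  held-out evaluation is available (and used for the null-effect tests)
  but is not the headline number.
* The exponential precision-profile model is a smoothing device for the
  33.3% extrapolation, not a physical noise model.
* Vendor binary formats, wavelength calibration and instrument control are
  out of scope; spectra enter as wide CSV plus a metadata sidecar.
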