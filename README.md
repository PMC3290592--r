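# glycoDCDR

Chemometric analysis of drop-coating deposition Raman (DCDR) spectra of
human serum albumin and glycated albumin.

Glycated albumin — albumin non-enzymatically modified by glucose — is a
medium-term glycemic marker. DCDR measures protein Raman spectra off the
analyte-rich annular ring left by a dried microliter droplet (the
coffee-ring effect concentrates the solute 2–3 orders of magnitude at the
pinned contact line). Because glycation changes the albumin Raman signature
only subtly, the analysis is multivariate throughout. This package
implements the full chain on a `SummarizedExperiment`-based spectral
container:

* **Simulation** of the study design: pseudo-Voigt band-model spectra of
  the two analytes (22 fingerprint bands; glycation modeled as a 792 cm⁻¹
  shoulder, an 828/850 tyrosine-doublet ratio shift and an amide-I shift,
  all scaled by one effect size ε), 6 two-fold dilutions per analyte
  × 3 ring locations × 5 replicates (180 spectra), plus a 10×10 map grid
  over the ring with its asymmetric radial deposition profile.
* **Classification**: mean-centered PCA (SVD); ridge-penalized logistic
  regression (IRLS, λ = 10⁻³ on standardized scores) on score components
  2–4, giving a separation plane `w₀ + w·s = 0`; random-label and
  measurement-order permutation controls.
* **Quantification**: single-response NIPALS PLS
  (`b = W(PᵀW)⁻¹q`, mean-centering only), leave-one-sample-out
  cross-validation with the latent-variable count chosen by nested
  leave-one-group-out RMSECV and a 2% parsimony rule.
* **Figures of merit**: REP = (100/N) Σ|cᵢ−ĉᵢ|/cᵢ; per-concentration
  RSDₖ = 100·σₖ/cₖ and their average; the predicted-on-reference
  calibration line; LOD = 3·s_y/x/slope (IUPAC 3σ); and the
  precision-profile LOD from fitting RSD(c) = A·e^(−Bc) + C and solving
  for the 33.3 % crossing.
* **2D mapping**: per-pixel concentration prediction over the ring,
  radial profiles, angular coefficients of variation, ring-center means.

## Worked example

```r
library(glycoDCDR)

cfg <- simulationConfig(seed = 7L)          # study-design defaults
ds  <- simulateDiscriminationSet(cfg)       # 90 albumin + 90 glycated
ds
#> SpectraSet with 180 spectra x 601 wavenumber channels
#>   axis: 600.0-1800.0 cm-1 (median step 2.00)
#>   analytes: albumin:90, glycated_albumin:90

pca    <- fitPCA(ds, nComponents = 4L)
round(100 * sum(pca@explainedVarFrac), 2)   # variance in 4 components
#> [1] 99.99

scores <- projectScores(pca, ds)
model  <- fitLogistic(scores)               # ridge logistic on scores 2-4
classifyScores(model, scores)$accuracy      # training accuracy
#> [1] 1

# random-label control: the same pipeline on permuted labels sits at chance
ctrl <- permutationControl(ds, "random", nRepeats = 200L, seed = 8L)
round(100 * ctrl$mean, 1)
#> [1] 54.2

# leave-one-sample-out PLS quantification of the glycated series
gly    <- ds[, spectraMeta(ds)$analyte == "glycated_albumin"]
preds  <- losoCrossValidate(gly)
meritReport(preds, excludeBelowLOD = TRUE)
#> MeritReport: REP 1.82% (excl. below-LOD: 1.82%)
#>   average RSD 1.54% (excl.: 1.54%)
#>   LOD: calibration plot 5.63 uM; precision profile 0 uM

# 2D map of one glycated sample, predicted by a model trained on the rest
mapset <- simulateMapGrid(cfg, "glycated_albumin", concentration = 31.25)
train  <- gly[, spectraMeta(gly)$concentration_uM != 31.25]
grid   <- predictMap(fitPLS(train, nLV = selectNumLV(train)), mapset)
round(radialProfile(grid), 1)     # ring shape: steep outer, gradual inner
#>  [1] 12.1 19.9 26.1 30.7 30.6 31.1 31.0 24.4 13.6  2.7
round(angularCV(grid)$mean, 3)    # angular reproducibility
#> [1] 0.021
round(centerBandMean(grid), 2)    # plateau average vs 31.25 uM reference
#> [1] 30.85
```

Reading the numbers: the classifier separates the two classes perfectly on
score components 2–4 while the permuted-label control stays near the 50 %
coin-flip level, so the separation reflects class structure, not
overfitting. The cross-validated predictions track the references to
within a few percent; the calibration-plot LOD of 5.6 µM sits well below
the lowest physiological glycated-albumin levels (~50 µM). The radial
profile reproduces the ring's asymmetric deposition (steeper outer flank),
the angular variation is ~2 %, and the ring-center average recovers the
reference concentration within ~1 %.

## File formats

Spectra travel as wide CSV (first column `wavenumber_cm-1`, one column per
spectrum) with a metadata sidecar CSV keyed by `spectrum_id`
(`sample_id`, `analyte`, `concentration_uM`, `location_id`,
`replicate_id`, optional `grid_x`/`grid_y`, `measurement_order`); see
`readSpectraSet()` / `writeSpectraSet()`. Round-trips are bit-exact.

## Documentation

The methods vignette (`vignettes/glycoDCDR-methods.Rmd`) describes the
generator's band model and noise structure, the chemometric models and
their assumptions, every tunable parameter with units and defaults, the
numerical choices, and known limitations of the synthetic study.
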