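# Shared fixtures: everything is generated in code at test time.

# default study-design config with a fixed seed
studyConfig <- function(seed = 1L, ...) simulationConfig(seed = seed, ...)

# config with all randomness switched off (noise, location variability)
noiselessConfig <- function(seed = 1L, ...)
    simulationConfig(seed = seed, noiseFloor = 0, shotScale = 0,
                     locationSd = 0, ...)

# tiny deterministic 3-spectrum set on a short axis
toySpectraSet <- function() {
    wn <- seq(600, 700, by = 10)
    mat <- cbind(a = seq_along(wn), b = rev(seq_along(wn)),
                 c = rep(2, length(wn)))
    SpectraSet(mat, wn, data.frame(
        spectrum_id = c("a", "b", "c"), sample_id = c("s1", "s1", "s2"),
        analyte = "albumin", concentration_uM = c(10, 10, 20),
        location_id = c(1L, 2L, 1L), replicate_id = 1L))
}

# deterministic mean baseline of a config on its axis
meanBaseline <- function(cfg) {
    u <- (simulationAxis(cfg) - 1200) / 600
    cfg@baselineCoef[1] + cfg@baselineCoef[2] * u + cfg@baselineCoef[3] * u^2
}

# held-out classification accuracy: train the PCA-score logistic pipeline on
# a subset of samples, evaluate on the rest
heldOutAccuracy <- function(x, trainSamples, nComponents = 4L,
                            selected = c(2L, 3L, 4L), lambda = 1e-3) {
    meta <- spectraMeta(x)
    tr <- x[, meta$sample_id %in% trainSamples]
    te <- x[, !meta$sample_id %in% trainSamples]
    pca <- fitPCA(tr, nComponents)
    fit <- fitLogistic(projectScores(pca, tr), selected, lambda)
    classifyScores(fit, projectScores(pca, te))$accuracy
}
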