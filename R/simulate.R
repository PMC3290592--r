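# Band positions and assignments of the drop-coated albumin spectrum, with
# relative amplitudes chosen so the principal peaks (amide-I 1655, CH2 1447,
# Phe 1002, Tyr doublet 850/828) dominate the rendered spectrum.
.albuminBands <- data.frame(
    center = c(1655, 1616, 1605, 1584, 1447, 1335, 1319, 1208, 1172, 1157,
               1125, 1102, 1089, 1031, 1002, 960, 940, 899, 850, 828, 667,
               643),
    rel_amplitude = c(0.85, 0.20, 0.20, 0.20, 0.80, 0.35, 0.35, 0.20, 0.20,
                      0.20, 0.20, 0.20, 0.20, 0.30, 1.00, 0.20, 0.20, 0.20,
                      0.45, 0.40, 0.20, 0.20),
    assignment = c("Amide-I", "Tyr", "Phe", "Phe", "delta(CH2)", "delta(CH)",
                   "delta(CH)", "Tyr+Phe", "Tyr", "nu(CN)", "nu(CN)",
                   "nu(CN)", "nu(CN)", "Phe", "Phe", "nu(CC)",
                   "nu(CCN)sym, nu(CC)", "nu(CC)", "Tyr", "Tyr", "nu(CS)",
                   "Tyr"),
    stringsAsFactors = FALSE)

#' Default band model for albumin or glycated albumin
#'
#' The albumin model carries the 22 fingerprint-region bands of drop-coated
#' serum albumin with default pseudo-Voigt widths. The glycated model applies
#' three perturbations scaled by the effect size `epsilon`: a new band at
#' 792 cm^-1 (amplitude `epsilon` times the 828 cm^-1 band, the shoulder that
#' grows on the tyrosine doublet), a tyrosine-doublet intensity-ratio shift
#' (828 scaled by `1 - 0.3 epsilon`, 850 by `1 + 0.3 epsilon`), and an
#' amide-I center shift of `+6 epsilon` cm^-1 toward the beta-sheet position.
#'
#' @param analyte `"albumin"` or `"glycated_albumin"`.
#' @param epsilon glycation effect size in \[0, 1\]; at 0 the two models are
#'   identical.
#' @param fwhm band full width at half maximum (cm^-1), default 12.
#' @param eta Lorentzian fraction of the pseudo-Voigt, default 0.7.
#' @return a [BandModel-class].
#' @examples
#' defaultBandModel("glycated_albumin", epsilon = 0.3)
#' @export
defaultBandModel <- function(analyte = c("albumin", "glycated_albumin"),
                             epsilon = 0.3, fwhm = 12, eta = 0.7) {
    analyte <- match.arg(analyte)
    if (epsilon < 0 || epsilon > 1)
        stop("epsilon must be in [0, 1]", call. = FALSE)
    bands <- .albuminBands
    bands$fwhm <- fwhm
    if (analyte == "glycated_albumin" && epsilon > 0) {
        i828 <- which(bands$center == 828)
        i850 <- which(bands$center == 850)
        iAm1 <- which(bands$center == 1655)
        newBand <- data.frame(center = 792, rel_amplitude =
            epsilon * bands$rel_amplitude[i828],
            assignment = "glycation shoulder", fwhm = fwhm,
            stringsAsFactors = FALSE)
        bands$rel_amplitude[i828] <- bands$rel_amplitude[i828] *
            (1 - 0.3 * epsilon)
        bands$rel_amplitude[i850] <- bands$rel_amplitude[i850] *
            (1 + 0.3 * epsilon)
        bands$center[iAm1] <- bands$center[iAm1] + 6 * epsilon
        bands <- rbind(bands, newBand[, colnames(bands)])
    }
    new("BandModel", bands = bands, eta = eta)
}

#' Render the pure-component spectrum of a band model
#'
#' Sum over bands of `rel_amplitude * (eta * Lorentzian + (1 - eta) *
#' Gaussian)` with the band's center and FWHM, normalized so the global
#' maximum equals 1.
#'
#' @param model a [BandModel-class].
#' @param axis numeric wavenumber axis (cm^-1).
#' @return nonnegative numeric vector on `axis` with maximum exactly 1.
#' @export
renderPureSpectrum <- function(model, axis) {
    stopifnot(is(model, "BandModel"))
    axis <- as.numeric(axis)
    eta <- model@eta
    y <- numeric(length(axis))
    for (i in seq_len(nrow(model@bands))) {
        b <- model@bands[i, ]
        hw <- b$fwhm / 2
        d <- axis - b$center
        lor <- hw^2 / (d^2 + hw^2)
        gau <- exp(-log(2) * (d / hw)^2)
        y <- y + b$rel_amplitude * (eta * lor + (1 - eta) * gau)
    }
    y / max(y)
}

#' Construct a SimulationConfig
#'
#' Defaults emulate the study conditions: fingerprint axis 600-1800 cm^-1 at
#' 2 cm^-1 spacing, glycation effect 0.3, 80 counts of peak signal per uM
#' (10-s acquisitions off the analyte-rich pre-concentrated ring give a
#' 1002 cm^-1 peak of 20000 counts at 250 uM), a positive quadratic
#' background of roughly 20% of the 250 uM peak signal, read noise 2 counts,
#' shot-noise scale 0.5, and 2% lognormal location-to-location deposition
#' variability at constant radial distance from the ring center.
#'
#' @param axisMin,axisMax,axisStep wavenumber axis (cm^-1).
#' @param glycationEffect effect size epsilon in \[0, 1\].
#' @param signalPerUM peak-signal counts per uM.
#' @param baselineCoef length-3 coefficients (constant, linear, quadratic) of
#'   the background polynomial in the scaled axis `(wn - 1200)/600`; the
#'   default scales with `signalPerUM` to stay near 20% of the 250 uM peak.
#' @param noiseFloor read-noise s.d. (counts).
#' @param shotScale shot-noise scale (dimensionless).
#' @param locationSd log-scale s.d. of the per-location deposition factor.
#' @param seed integer random seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(axisMin = 600, axisMax = 1800, axisStep = 2,
                             glycationEffect = 0.3, signalPerUM = 80,
                             baselineCoef = signalPerUM * c(37.5, -10, 15),
                             noiseFloor = 2, shotScale = 0.5,
                             locationSd = 0.02, seed = 1L) {
    new("SimulationConfig", axisMin = axisMin, axisMax = axisMax,
        axisStep = axisStep, glycationEffect = glycationEffect,
        signalPerUM = signalPerUM, baselineCoef = baselineCoef,
        noiseFloor = noiseFloor, shotScale = shotScale,
        locationSd = locationSd, seed = as.integer(seed))
}

#' @rdname simulationConfig
#' @param cfg a [SimulationConfig-class].
#' @return `simulationAxis` returns the numeric wavenumber axis of `cfg`.
#' @export
simulationAxis <- function(cfg)
    seq(cfg@axisMin, cfg@axisMax, by = cfg@axisStep)

.baselineOn <- function(cfg, axis) {
    u <- (axis - 1200) / 600
    cfg@baselineCoef[1] + cfg@baselineCoef[2] * u + cfg@baselineCoef[3] * u^2
}

#' Default concentration series of the calibration design
#'
#' Six two-fold dilutions per analyte: glycated albumin 250 down to 7.8 uM,
#' albumin 750 down to 23.4 uM.
#'
#' @param analyte `"albumin"` or `"glycated_albumin"`.
#' @return numeric vector of 6 concentrations (uM), descending.
#' @export
defaultConcentrations <- function(analyte = c("albumin",
                                              "glycated_albumin")) {
    analyte <- match.arg(analyte)
    if (analyte == "albumin") 750 / 2^(0:5) else 250 / 2^(0:5)
}

# evaluate an expression under a temporary RNG seed, restoring global state
.withSeed <- function(seed, code) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code
}

# noisy spectrum on the current RNG stream (vector only; no metadata);
# u is the scaled axis (wn - 1200)/600 of the baseline polynomial
.simulateIntensity <- function(cfg, pure, concentration, locationFactor, u) {
    baseline <- cfg@baselineCoef[1] + cfg@baselineCoef[2] * u +
        cfg@baselineCoef[3] * u^2
    clean <- baseline +
        locationFactor * cfg@signalPerUM * concentration * pure
    sd <- sqrt(cfg@noiseFloor^2 + cfg@shotScale^2 * pmax(clean, 0))
    clean + stats::rnorm(length(clean), 0, sd)
}

#' Simulate one DCDR spectrum
#'
#' The clean signal is `baseline(wn) + locationFactor * signalPerUM *
#' concentration * pure(wn)`; heteroscedastic Gaussian noise with s.d.
#' `sqrt(noiseFloor^2 + shotScale^2 * max(clean, 0))` is added. Draws come
#' from the current RNG stream, so results are deterministic given the RNG
#' state (use `set.seed()` or the dataset-level simulators, which seed from
#' the config).
#'
#' @param cfg a [SimulationConfig-class].
#' @param analyte `"albumin"` or `"glycated_albumin"`.
#' @param concentration analyte concentration (uM, > 0).
#' @param locationFactor multiplicative deposition factor of the probed spot.
#' @return a single-spectrum [SpectraSet-class].
#' @export
simulateSpectrum <- function(cfg, analyte = c("albumin", "glycated_albumin"),
                             concentration, locationFactor = 1) {
    analyte <- match.arg(analyte)
    if (concentration <= 0)
        stop("concentration must be positive", call. = FALSE)
    axis <- simulationAxis(cfg)
    pure <- renderPureSpectrum(
        defaultBandModel(analyte, cfg@glycationEffect), axis)
    y <- .simulateIntensity(cfg, pure, concentration, locationFactor,
                            (axis - 1200) / 600)
    SpectraSet(matrix(y, ncol = 1), axis,
        data.frame(spectrum_id = "sim1", sample_id = "sim",
                   analyte = analyte, concentration_uM = concentration,
                   location_id = 1L, replicate_id = 1L))
}

# core generator shared by the calibration and two-class simulators;
# draws on the current RNG stream
.simulateClassSpectra <- function(cfg, analyte, concentrations, nLocations,
                                  nReplicates, axis, pure, u) {
    cols <- list(); meta <- list(); k <- 0L
    for (ci in seq_along(concentrations)) {
        conc <- concentrations[ci]
        sampleId <- sprintf("%s_c%02d", substr(analyte, 1, 3), ci)
        locFactors <- exp(stats::rnorm(nLocations, 0, cfg@locationSd))
        for (loc in seq_len(nLocations)) {
            for (rep in seq_len(nReplicates)) {
                k <- k + 1L
                cols[[k]] <- .simulateIntensity(cfg, pure, conc,
                                                locFactors[loc], u)
                meta[[k]] <- data.frame(
                    spectrum_id = sprintf("%s_l%d_r%d", sampleId, loc, rep),
                    sample_id = sampleId, analyte = analyte,
                    concentration_uM = conc, location_id = loc,
                    replicate_id = rep, stringsAsFactors = FALSE)
            }
        }
    }
    list(mat = do.call(cbind, cols), meta = do.call(rbind, meta))
}

#' Simulate a single-analyte calibration dataset
#'
#' One sample per concentration; each sample is probed at `nLocations` ring
#' locations whose lognormal deposition factors (log-scale s.d.
#' `cfg@locationSd`) are shared by that location's `nReplicates` replicate
#' spectra — 15 spectra per sample under the defaults.
#'
#' @param cfg a [SimulationConfig-class]; seeds the generator.
#' @param analyte `"albumin"` or `"glycated_albumin"`.
#' @param concentrations concentrations (uM), default the analyte's two-fold
#'   dilution series.
#' @param nLocations,nReplicates replicate structure (defaults 3 and 5).
#' @return a [SpectraSet-class] with fully populated metadata.
#' @export
simulateCalibrationSet <- function(cfg,
        analyte = c("albumin", "glycated_albumin"),
        concentrations = defaultConcentrations(analyte),
        nLocations = 3L, nReplicates = 5L) {
    analyte <- match.arg(analyte)
    if (length(concentrations) == 0L)
        stop("concentrations must be nonempty", call. = FALSE)
    axis <- simulationAxis(cfg)
    pure <- renderPureSpectrum(
        defaultBandModel(analyte, cfg@glycationEffect), axis)
    res <- .withSeed(cfg@seed,
        .simulateClassSpectra(cfg, analyte, concentrations, nLocations,
                              nReplicates, axis, pure, (axis - 1200) / 600))
    SpectraSet(res$mat, axis, res$meta)
}

#' Simulate the full two-class discrimination dataset
#'
#' Generates both calibration series (90 + 90 spectra under the defaults)
#' from one seeded stream and assigns a sample-blocked random measurement
#' order: the 12 samples are acquired in a random interleaved sequence with
#' each sample's 15 spectra contiguous, mimicking acquisition "in an
#' arbitrary manner" between the two analytes. The order is recorded in the
#' `measurement_order` metadata column.
#'
#' @inheritParams simulateCalibrationSet
#' @param albuminConcentrations,glycatedConcentrations concentration series
#'   (uM) of the two classes.
#' @return a [SpectraSet-class] with 180 spectra under the defaults.
#' @export
simulateDiscriminationSet <- function(cfg,
        albuminConcentrations = defaultConcentrations("albumin"),
        glycatedConcentrations = defaultConcentrations("glycated_albumin"),
        nLocations = 3L, nReplicates = 5L) {
    axis <- simulationAxis(cfg)
    u <- (axis - 1200) / 600
    pureAlb <- renderPureSpectrum(
        defaultBandModel("albumin", cfg@glycationEffect), axis)
    pureGly <- renderPureSpectrum(
        defaultBandModel("glycated_albumin", cfg@glycationEffect), axis)
    res <- .withSeed(cfg@seed, {
        a <- .simulateClassSpectra(cfg, "albumin", albuminConcentrations,
                                   nLocations, nReplicates, axis, pureAlb, u)
        g <- .simulateClassSpectra(cfg, "glycated_albumin",
                                   glycatedConcentrations, nLocations,
                                   nReplicates, axis, pureGly, u)
        meta <- rbind(a$meta, g$meta)
        samples <- unique(meta$sample_id)
        blockOrder <- sample(samples)
        pos <- order(match(meta$sample_id, blockOrder))
        ord <- integer(nrow(meta)); ord[pos] <- seq_len(nrow(meta))
        meta$measurement_order <- ord
        list(mat = cbind(a$mat, g$mat), meta = meta)
    })
    SpectraSet(res$mat, axis, res$meta)
}

#' Radial deposition profile of the drop-coated ring
#'
#' Relative analyte deposition across the ring's radial pixels: a plateau of
#' 1.0 at the analyte-rich center (pixels 4-7), a gradual inner rise (pixels
#' 1-3: 0.40, 0.65, 0.85) and a steeper outer fall (pixels 8-10: 0.80, 0.45,
#' 0.10), reproducing the asymmetry of complete desiccation at the pinned
#' outer contact line.
#'
#' @param x integer pixel index/indices in `1..nx`.
#' @param nx number of radial pixels (default 10).
#' @return relative deposition factor(s) in \[0, 1\].
#' @export
ringProfile <- function(x, nx = 10L) {
    if (nx != 10L)
        stop("parameter error: the ring profile is defined for nx = 10",
             call. = FALSE)
    if (any(x < 1L | x > nx))
        stop("parameter error: pixel index outside 1..", nx, call. = FALSE)
    prof <- c(0.40, 0.65, 0.85, 1.0, 1.0, 1.0, 1.0, 0.80, 0.45, 0.10)
    prof[x]
}

#' Simulate a 2D Raman map over the annular ring
#'
#' An `nx` x `ny` grid (80 x 80 um at the default 8 um pitch) with the
#' X-axis radial (pixel 1 innermost) and the Y-axis approximating the
#' angular direction. The effective concentration at pixel (x, y) is
#' `concentration * ringProfile(x) * (1 + jitter)` with small Gaussian
#' angular jitter (s.d. `angularJitterSd`), and spectra carry the usual
#' baseline and noise.
#'
#' @inheritParams simulateCalibrationSet
#' @param concentration reference analyte concentration of the mapped sample
#'   (uM).
#' @param nx,ny grid dimensions (>= 2); the radial profile requires
#'   `nx = 10`.
#' @param angularJitterSd s.d. of the relative angular jitter, default 0.02.
#' @param pitch_um inter-point distance, default 8 um.
#' @return a [SpectraSet-class] of `nx * ny` spectra with `grid_x`,
#'   `grid_y` metadata.
#' @export
simulateMapGrid <- function(cfg,
        analyte = c("albumin", "glycated_albumin"), concentration,
        nx = 10L, ny = 10L, angularJitterSd = 0.02, pitch_um = 8) {
    analyte <- match.arg(analyte)
    if (nx < 2L || ny < 2L) stop("nx and ny must be >= 2", call. = FALSE)
    axis <- simulationAxis(cfg)
    pure <- renderPureSpectrum(
        defaultBandModel(analyte, cfg@glycationEffect), axis)
    u <- (axis - 1200) / 600
    mapSeed <- as.integer((as.numeric(cfg@seed) + 104729) %%
                          .Machine$integer.max)
    res <- .withSeed(mapSeed, {
        cols <- list(); meta <- list(); k <- 0L
        for (gx in seq_len(nx)) {
            for (gy in seq_len(ny)) {
                k <- k + 1L
                eff <- concentration * ringProfile(gx, nx) *
                    (1 + stats::rnorm(1, 0, angularJitterSd))
                cols[[k]] <- .simulateIntensity(cfg, pure, max(eff, 1e-12),
                                                1, u)
                meta[[k]] <- data.frame(
                    spectrum_id = sprintf("map_x%02d_y%02d", gx, gy),
                    sample_id = "map", analyte = analyte,
                    concentration_uM = concentration,
                    location_id = NA_integer_, replicate_id = NA_integer_,
                    grid_x = gx, grid_y = gy, stringsAsFactors = FALSE)
            }
        }
        list(mat = do.call(cbind, cols), meta = do.call(rbind, meta))
    })
    out <- SpectraSet(res$mat, axis, res$meta)
    S4Vectors::metadata(out)$pitch_um <- pitch_um
    out
}
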