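test_that("write/read round-trips matrix to full precision and meta exactly", {
    cfg <- studyConfig(seed = 11L)
    ds <- simulateCalibrationSet(cfg, "glycated_albumin")
    sp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
    writeSpectraSet(ds, sp, mp)
    back <- readSpectraSet(sp, mp)
    expect_identical(intensityMatrix(back), intensityMatrix(ds))
    expect_identical(wavenumbers(back), wavenumbers(ds))
    m0 <- spectraMeta(ds); m1 <- spectraMeta(back)
    expect_identical(m1$sample_id, m0$sample_id)
    expect_identical(m1$concentration_uM, m0$concentration_uM)
    expect_identical(m1$location_id, m0$location_id)
    expect_identical(m1$replicate_id, m0$replicate_id)
})

test_that("map grid coordinates survive the round trip", {
    cfg <- studyConfig(seed = 12L)
    mp0 <- simulateMapGrid(cfg, "glycated_albumin", 31.25, nx = 10, ny = 4)
    sp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
    writeSpectraSet(mp0, sp, mp)
    back <- readSpectraSet(sp, mp)
    expect_identical(spectraMeta(back)$grid_x, spectraMeta(mp0)$grid_x)
    expect_identical(spectraMeta(back)$grid_y, spectraMeta(mp0)$grid_y)
    expect_identical(intensityMatrix(back), intensityMatrix(mp0))
})

test_that("an empty dataset writes valid files and round-trips", {
    wn <- seq(600, 1800, 2)
    empty <- SpectraSet(matrix(numeric(0), nrow = length(wn), ncol = 0), wn,
                        data.frame(spectrum_id = character(0)))
    sp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
    writeSpectraSet(empty, sp, mp)
    back <- readSpectraSet(sp, mp)
    expect_equal(ncol(back), 0L)
    expect_identical(wavenumbers(back), wn)
})

test_that("reader rejects inconsistent metadata and malformed axes", {
    ds <- toySpectraSet()
    sp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
    writeSpectraSet(ds, sp, mp)
    # metadata referencing a spectrum column that does not exist
    meta <- utils::read.csv(mp)
    meta$spectrum_id[2] <- "ghost"
    mp2 <- tempfile(fileext = ".csv")
    utils::write.csv(meta, mp2, row.names = FALSE)
    expect_error(readSpectraSet(sp, mp2), "consistency error")
    # decreasing wavenumber axis is refused, not silently re-sorted
    sp2 <- tempfile(fileext = ".csv")
    lines <- readLines(sp)
    writeLines(c(lines[1], rev(lines[-1])), sp2)
    expect_error(readSpectraSet(sp2, mp), "strictly increasing")
})

test_that("resampling is the identity on the native grid and exact on ramps", {
    ds <- toySpectraSet()
    same <- resampleSpectra(ds, wavenumbers(ds))
    expect_equal(intensityMatrix(same), intensityMatrix(ds),
                 ignore_attr = TRUE)
    # linear ramp evaluated at midpoints is the midpoint average
    wn <- wavenumbers(ds)
    mid <- head(wn, -1) + diff(wn) / 2
    res <- resampleSpectra(ds, mid)
    ramp <- intensityMatrix(ds)[, "a"]
    expect_equal(unname(intensityMatrix(res)[, 1]),
                 (head(ramp, -1) + tail(ramp, -1)) / 2)
    # a grid reaching past the axis is a coverage error
    expect_error(resampleSpectra(ds, c(wn, max(wn) + 1)), "coverage error")
})

test_that("cosmic-ray filter removes spikes and leaves clean points alone", {
    set.seed(3)
    cfg <- studyConfig(seed = 3L)
    clean <- simulateSpectrum(cfg, "albumin", 100)
    y <- intensityMatrix(clean)[, 1]
    spiked <- y
    i <- 331L  # ~1260 cm-1, away from sharp band maxima
    spiked[i] <- 50 * max(y)
    sset <- SpectraSet(cbind(s = spiked), wavenumbers(clean),
                       data.frame(spectrum_id = "s"))
    out <- intensityMatrix(removeCosmicRays(sset))[, 1]
    expect_lt(abs(out[i] - y[i]) / max(y), 0.01)
    expect_identical(out[-i], spiked[-i])  # neighbors bit-identical
    # a spike-free spectrum passes through unchanged
    cset <- SpectraSet(cbind(s = y), wavenumbers(clean),
                       data.frame(spectrum_id = "s"))
    expect_identical(intensityMatrix(removeCosmicRays(cset))[, 1], y)
})

test_that("two adjacent spikes are both replaced, matching a loop oracle", {
    set.seed(4)
    y <- intensityMatrix(
        simulateSpectrum(studyConfig(seed = 4L), "albumin", 100))[, 1]
    spiked <- y
    spiked[340:341] <- spiked[340:341] + 40 * max(y)  # quiet ~1280 cm-1
    # oracle: explicit windowed running-median modified-z filter
    oracle <- function(v, w = 5L, z = 100) {
        n <- length(v); half <- w %/% 2L; out <- v
        med <- vapply(seq_len(n), function(i) {
            idx <- max(1L, i - half):min(n, i + half)
            stats::median(v[idx])
        }, numeric(1))
        dev <- abs(v - med)
        mad <- vapply(seq_len(n), function(i) {
            idx <- max(1L, i - half):min(n, i + half)
            stats::median(dev[idx])
        }, numeric(1)) * 1.4826
        floorScale <- 1e-12 * max(abs(v), 1)
        gmad <- if (any(dev > 0)) stats::median(dev[dev > 0]) * 1.4826 else 0
        scale <- pmax(mad, gmad / 2, floorScale)
        zz <- 0.6745 * dev / scale
        bad <- zz > z & dev > floorScale
        out[bad] <- med[bad]
        out
    }
    sset <- SpectraSet(cbind(s = spiked), seq_along(spiked),
                       data.frame(spectrum_id = "s"))
    got <- intensityMatrix(removeCosmicRays(sset, window = 5L))[, 1]
    expect_lt(max(abs(got[340:341] - y[340:341])) / max(y), 0.02)
    expect_equal(got, oracle(spiked), tolerance = 1e-12)
    # idempotency
    again <- removeCosmicRays(removeCosmicRays(sset))
    expect_identical(intensityMatrix(again),
                     intensityMatrix(removeCosmicRays(sset)))
    expect_error(removeCosmicRays(sset, window = 4L), "odd")
})

test_that("display baseline removal recovers peaks over polynomial baselines", {
    wn <- seq(600, 1800, 2)
    u <- (wn - 1200) / 600
    # pure polynomial of the fitted order vanishes
    poly5 <- 100 + 50 * u + 30 * u^2 - 20 * u^3 + 10 * u^4 + 5 * u^5
    ps <- SpectraSet(cbind(s = poly5), wn, data.frame(spectrum_id = "s"))
    out <- intensityMatrix(removeBaseline(ps, polyOrder = 5L))[, 1]
    expect_lt(max(abs(out)), 1e-6 * max(poly5))
    # isolated peaks on a zero baseline survive within 1% of height
    bandPos <- c(800, 1002, 1448, 1656)   # on the 2 cm-1 grid
    bands <- new("BandModel", bands = data.frame(
        center = bandPos, fwhm = 12,
        rel_amplitude = c(0.5, 1, 0.8, 0.85), assignment = "x"), eta = 0.7)
    peaks <- 1000 * renderPureSpectrum(bands, wn)
    pk <- SpectraSet(cbind(s = peaks), wn, data.frame(spectrum_id = "s"))
    outp <- intensityMatrix(removeBaseline(pk))[, 1]
    centers <- match(bandPos, wn)
    expect_lt(max(abs(outp[centers] - peaks[centers]) / peaks[centers]), 0.01)
    # peaks on a cubic baseline, fitted with order 5: heights within 5%
    cubic <- 300 + 100 * u - 50 * u^2 + 40 * u^3
    mix <- SpectraSet(cbind(s = peaks + cubic), wn,
                      data.frame(spectrum_id = "s"))
    outm <- intensityMatrix(removeBaseline(mix, polyOrder = 5L))[, 1]
    expect_lt(max(abs(outm[centers] - peaks[centers]) / peaks[centers]), 0.05)
    # flagged as display-only, and never exceeds the input by more than tol
    expect_true(all(spectraMeta(removeBaseline(pk))$display_only))
    expect_true(all(outm <= peaks + cubic + 1e-6 * max(peaks)))
})

test_that("replicate averaging reduces groups correctly and is linear", {
    wn <- seq(600, 700, 10)
    two <- SpectraSet(cbind(a = rep(0, 11), b = rep(2, 11)), wn,
        data.frame(spectrum_id = c("a", "b"), sample_id = "s",
                   location_id = c(1L, 2L), replicate_id = 1L))
    avg <- averageReplicates(two, "sample_id")
    expect_equal(unname(intensityMatrix(avg)[, 1]), rep(1, 11))
    expect_equal(spectraMeta(avg)$n_averaged, 2L)
    # five identical spectra average to themselves
    five <- SpectraSet(matrix(3, 11, 5), wn,
        data.frame(spectrum_id = letters[1:5], sample_id = "s",
                   location_id = 1L, replicate_id = 1:5))
    expect_equal(unname(intensityMatrix(
        averageReplicates(five, "sample_id"))[, 1]), rep(3, 11))
    # study design collapses to one spectrum per sample
    ds <- simulateDiscriminationSet(studyConfig(seed = 5L))
    expect_equal(ncol(averageReplicates(ds, "sample_id")), 12L)
    # averaging commutes with linear resampling
    grid <- seq(605, 695, 10)
    a1 <- resampleSpectra(averageReplicates(two, "sample_id"), grid)
    a2 <- averageReplicates(resampleSpectra(two, grid), "sample_id")
    expect_equal(unname(intensityMatrix(a1)), unname(intensityMatrix(a2)))
})

test_that("SpectraSet validity enforces axis ordering and metadata uniqueness", {
    wn <- seq(600, 700, 10)
    expect_error(SpectraSet(matrix(1, 11, 1), rev(wn),
                            data.frame(spectrum_id = "a")),
                 "strictly increasing")
    expect_error(SpectraSet(matrix(NA_real_, 11, 1), wn,
                            data.frame(spectrum_id = "a")), "missing")
    expect_error(SpectraSet(matrix(1, 11, 2), wn,
        data.frame(spectrum_id = c("a", "b"), sample_id = "s",
                   location_id = 1L, replicate_id = 1L)), "unique")
})
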