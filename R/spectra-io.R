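.metaCols <- c("spectrum_id", "sample_id", "analyte", "concentration_uM",
               "location_id", "replicate_id", "grid_x", "grid_y",
               "measurement_order")

#' Read a SpectraSet from wide-CSV spectra and a metadata sidecar
#'
#' The spectra file is a wide CSV whose first column is `wavenumber_cm-1`
#' (strictly increasing) and whose remaining columns are one spectrum each,
#' named by spectrum id. The metadata file has one row per spectrum, keyed by
#' `spectrum_id`. Spectra are re-ordered to the metadata-row order.
#'
#' @param spectraPath path to the wide spectra CSV.
#' @param metaPath path to the metadata CSV.
#' @return a [SpectraSet-class].
#' @seealso [writeSpectraSet()] for the inverse.
#' @export
readSpectraSet <- function(spectraPath, metaPath) {
    sp <- utils::read.csv(spectraPath, check.names = FALSE,
                          colClasses = "numeric")
    if (ncol(sp) < 1L || colnames(sp)[1] != "wavenumber_cm-1")
        stop("spectra file must start with a 'wavenumber_cm-1' column",
             call. = FALSE)
    wn <- sp[[1]]
    if (anyNA(wn) || (length(wn) > 1L && any(diff(wn) <= 0)))
        stop("format error: wavenumber column must be strictly increasing ",
             "(refusing to re-sort silently)", call. = FALSE)
    meta <- utils::read.csv(metaPath, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = c(spectrum_id = "character"))
    if (!"spectrum_id" %in% colnames(meta))
        stop("metadata file must contain a spectrum_id column", call. = FALSE)
    missing <- setdiff(meta$spectrum_id, colnames(sp)[-1])
    if (length(missing))
        stop("consistency error: metadata references spectra absent from the ",
             "spectra file: ", paste(missing, collapse = ", "), call. = FALSE)
    extra <- setdiff(colnames(sp)[-1], meta$spectrum_id)
    if (length(extra))
        stop("consistency error: spectra columns without metadata: ",
             paste(extra, collapse = ", "), call. = FALSE)
    mat <- as.matrix(sp[, meta$spectrum_id, drop = FALSE])
    SpectraSet(mat, wn, meta)
}

#' Write a SpectraSet to wide-CSV spectra + metadata files
#'
#' Intensities are written with 17 significant digits so that
#' `readSpectraSet(writeSpectraSet(x))` reproduces the matrix to full double
#' precision and the metadata exactly.
#'
#' @param x a [SpectraSet-class].
#' @param spectraPath,metaPath output file paths.
#' @return invisibly, the two paths.
#' @export
writeSpectraSet <- function(x, spectraPath, metaPath) {
    stopifnot(is(x, "SpectraSet"))
    meta <- spectraMeta(x)
    if (!"spectrum_id" %in% colnames(meta))
        meta$spectrum_id <- if (!is.null(colnames(x))) colnames(x) else
            sprintf("s%03d", seq_len(ncol(x)))
    meta <- meta[, c("spectrum_id", setdiff(colnames(meta), "spectrum_id")),
                 drop = FALSE]
    mat <- intensityMatrix(x)
    num <- cbind(`wavenumber_cm-1` = wavenumbers(x), mat)
    chr <- matrix(sprintf("%.17g", num), nrow = nrow(num))
    header <- c("wavenumber_cm-1", meta$spectrum_id)
    lines <- c(paste(header, collapse = ","),
               if (nrow(chr)) apply(chr, 1L, paste, collapse = ","))
    tryCatch(writeLines(lines, spectraPath),
             error = function(e) stop("I/O error writing ", spectraPath, ": ",
                                      conditionMessage(e), call. = FALSE))
    utils::write.csv(meta, metaPath, row.names = FALSE, quote = FALSE,
                     na = "")
    invisible(c(spectra = spectraPath, meta = metaPath))
}

#' Resample spectra onto a common wavenumber grid
#'
#' Linear interpolation of each spectrum onto `grid`; extrapolation is
#' refused — every input spectrum's axis must cover the whole grid.
#'
#' @param spectra a [SpectraSet-class] or a list of them (possibly on
#'   different axes).
#' @param grid strictly increasing target axis (cm^-1).
#' @return a [SpectraSet-class] on `grid`, metadata concatenated in input
#'   order.
#' @export
resampleSpectra <- function(spectra, grid) {
    if (is(spectra, "SpectraSet")) spectra <- list(spectra)
    grid <- as.numeric(grid)
    if (length(grid) > 1L && any(diff(grid) <= 0))
        stop("grid must be strictly increasing", call. = FALSE)
    mats <- list(); metas <- list()
    for (i in seq_along(spectra)) {
        s <- spectra[[i]]
        wn <- wavenumbers(s)
        if (min(grid) < min(wn) || max(grid) > max(wn))
            stop(sprintf(
                "coverage error: spectrum axis [%g, %g] does not cover grid [%g, %g]",
                min(wn), max(wn), min(grid), max(grid)), call. = FALSE)
        m <- intensityMatrix(s)
        mats[[i]] <- apply(m, 2L, function(y)
            stats::approx(wn, y, xout = grid, method = "linear")$y)
        metas[[i]] <- spectraMeta(s)
    }
    allCols <- unique(unlist(lapply(metas, colnames)))
    metas <- lapply(metas, function(d) {
        for (cc in setdiff(allCols, colnames(d))) d[[cc]] <- NA
        d[, allCols, drop = FALSE]
    })
    SpectraSet(do.call(cbind, mats), grid, do.call(rbind, metas))
}

#' Remove cosmic-ray spikes with a running-median modified-z filter
#'
#' For each spectrum, points whose deviation from the running median exceeds
#' `zThreshold` times the local robust scale are replaced by the running
#' median; all other points are returned bit-identical. The local scale is
#' the running median absolute deviation floored at half the spectrum-wide
#' MAD, so that locally quiet stretches cannot produce spurious detections.
#' The filter is idempotent on its own output.
#'
#' The default threshold of 100 cleanly separates single-pixel cosmic spikes
#' (modified z-scores of 10^3-10^5: a spike deviates by many multiples of
#' the local intensity while the scale stays at the noise level) from the
#' sharpest genuine band tips, whose curvature reaches z of about 50 at the
#' signal-to-noise ratios of ring deposits. On steep band flanks the window
#' is locally monotone, the center point is its own running median, and both
#' the local and an untrimmed global MAD collapse to zero - hence the
#' positive-deviation floor.
#'
#' @param x a [SpectraSet-class].
#' @param window odd integer window length in points (>= 3).
#' @param zThreshold modified-z-score detection threshold (dimensionless).
#' @return a [SpectraSet-class] with spikes replaced.
#' @export
removeCosmicRays <- function(x, window = 5L, zThreshold = 100) {
    stopifnot(is(x, "SpectraSet"))
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L)
        stop("parameter error: window must be an odd integer >= 3",
             call. = FALSE)
    mat <- intensityMatrix(x)
    out <- apply(mat, 2L, .despikeVector, window = window,
                 zThreshold = zThreshold)
    dimnames(out) <- dimnames(mat)
    y <- x
    SummarizedExperiment::assay(y, "intensity") <- out
    y
}

.despikeVector <- function(y, window, zThreshold) {
    n <- length(y)
    if (n < window) return(y)
    med <- stats::runmed(y, window, endrule = "median")
    dev <- abs(y - med)
    # local robust scale: running MAD floored at half the global MAD of the
    # positive deviations (points sitting at their own window median - most
    # of a locally monotone flank - contribute exact zeros that would
    # otherwise collapse both scales), plus a numerical floor for exactly
    # constant spectra
    localMad <- stats::runmed(dev, window, endrule = "median") * 1.4826
    pos <- dev[dev > 0]
    globalMad <- if (length(pos)) stats::median(pos) * 1.4826 else 0
    floorScale <- 1e-12 * max(abs(y), 1)
    scale <- pmax(localMad, globalMad / 2, floorScale)
    z <- 0.6745 * dev / scale
    spike <- z > zThreshold & dev > floorScale
    y[spike] <- med[spike]
    y
}

#' Display-only baseline removal (iterative modified polynomial fit)
#'
#' Iteratively fits a polynomial of order `polyOrder` to each spectrum and
#' clips the working intensities to `min(intensity, fit)`; at convergence
#' (relative change < `tol`, else `maxIter` with a warning) the converged
#' polynomial is subtracted. Intended for visualisation only — the
#' quantitative pipeline operates on raw intensities — so the result is
#' flagged `display_only` in the metadata.
#'
#' @param x a [SpectraSet-class].
#' @param polyOrder polynomial order (>= 1), default 5.
#' @param maxIter maximum clip-and-refit iterations.
#' @param tol convergence tolerance: maximum change of the working curve
#'   relative to the spectrum's intensity range.
#' @return baseline-subtracted [SpectraSet-class] with a `display_only`
#'   metadata column set to `TRUE`.
#' @references Lieber & Mahadevan-Jansen (2003) Appl Spectrosc 57:1363-1367.
#' @export
removeBaseline <- function(x, polyOrder = 5L, maxIter = 100L, tol = 1e-4) {
    stopifnot(is(x, "SpectraSet"))
    if (polyOrder < 1L) stop("polyOrder must be >= 1", call. = FALSE)
    wn <- wavenumbers(x)
    mat <- intensityMatrix(x)
    basis <- stats::poly(wn, degree = polyOrder)
    out <- mat
    for (j in seq_len(ncol(mat))) {
        y0 <- mat[, j]
        scale <- max(diff(range(y0)), max(abs(y0)), .Machine$double.eps)
        work <- y0
        converged <- FALSE
        for (it in seq_len(maxIter)) {
            fit <- stats::lm.fit(cbind(1, basis), work)$fitted.values
            newWork <- pmin(work, fit)
            if (max(abs(newWork - work)) / scale < tol) {
                work <- newWork
                converged <- TRUE
                break
            }
            work <- newWork
        }
        if (!converged)
            warning("baseline fit did not converge in ", maxIter,
                    " iterations for spectrum ", j,
                    "; returning last iterate", call. = FALSE)
        baseline <- stats::lm.fit(cbind(1, basis), work)$fitted.values
        out[, j] <- y0 - baseline
    }
    y <- x
    SummarizedExperiment::assay(y, "intensity") <- out
    colData(y)$display_only <- TRUE
    y
}

#' Average replicate spectra within metadata groups
#'
#' @param x a [SpectraSet-class].
#' @param groupKeys nonempty character vector of metadata columns defining the
#'   groups (e.g. `"sample_id"`).
#' @return a [SpectraSet-class] with one mean spectrum per group; metadata
#'   keeps the grouping keys plus `n_averaged`, and any metadata column
#'   constant within a group.
#' @export
averageReplicates <- function(x, groupKeys) {
    stopifnot(is(x, "SpectraSet"))
    if (length(groupKeys) == 0L)
        stop("groupKeys must be nonempty", call. = FALSE)
    meta <- spectraMeta(x)
    if (!all(groupKeys %in% colnames(meta)))
        stop("unknown grouping columns: ",
             paste(setdiff(groupKeys, colnames(meta)), collapse = ", "),
             call. = FALSE)
    key <- interaction(meta[, groupKeys, drop = FALSE], drop = TRUE,
                       lex.order = TRUE)
    mat <- intensityMatrix(x)
    groups <- split(seq_len(ncol(mat)), key)
    avg <- vapply(groups, function(idx) rowMeans(mat[, idx, drop = FALSE]),
                  numeric(nrow(mat)))
    outMeta <- do.call(rbind, lapply(groups, function(idx) {
        d <- meta[idx, , drop = FALSE]
        keep <- vapply(d, function(col) length(unique(col)) == 1L,
                       logical(1))
        row <- d[1L, keep | colnames(d) %in% groupKeys, drop = FALSE]
        row$n_averaged <- length(idx)
        row
    }))
    rownames(outMeta) <- NULL
    outMeta$spectrum_id <- names(groups)
    SpectraSet(avg, wavenumbers(x), outMeta)
}
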