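#' Average relative error of prediction (REP)
#'
#' `REP = (100/N) * sum(|c_i - chat_i| / c_i)` over all N predictions
#' (mean absolute relative error, %). An RMS variant
#' `100 * sqrt((1/N) * sum(((c_i - chat_i)/c_i)^2))` is available via
#' `method = "rms"`.
#'
#' @param predictions a [PredictionSet-class] with positive references.
#' @param method `"mean_abs"` (default) or `"rms"`.
#' @return REP in percent.
#' @export
computeREP <- function(predictions, method = c("mean_abs", "rms")) {
    method <- match.arg(method)
    e <- predictionEntries(predictions)
    if (nrow(e) == 0L) stop("input error: empty prediction set",
                            call. = FALSE)
    if (any(e$reference_uM <= 0))
        stop("input error: reference concentrations must be positive",
             call. = FALSE)
    rel <- (e$reference_uM - e$predicted_uM) / e$reference_uM
    if (method == "mean_abs") 100 * mean(abs(rel)) else
        100 * sqrt(mean(rel^2))
}

#' Per-concentration and average relative standard deviation (RSD)
#'
#' For each distinct reference concentration c_k, `sigma_ck` is the sample
#' (n-1) standard deviation of its predictions and `RSD_k = 100 *
#' sigma_ck / c_k`; the average is `(100/N_conc) * sum(sigma_ck / c_k)`.
#' Dividing by the reference (not the mean prediction) is what makes the
#' RSD exactly 33.3% at the IUPAC 3-sigma calibration LOD.
#'
#' @param predictions a [PredictionSet-class]; every concentration group
#'   needs at least 2 predictions.
#' @return list with `perConcentration` (`data.frame`: `concentration_uM`,
#'   `n`, `sd_uM`, `rsd_pct`) and `average` (%).
#' @export
computeRSD <- function(predictions) {
    e <- predictionEntries(predictions)
    if (nrow(e) == 0L) stop("input error: empty prediction set",
                            call. = FALSE)
    groups <- split(e$predicted_uM, e$reference_uM)
    small <- names(groups)[vapply(groups, length, integer(1)) < 2L]
    if (length(small))
        stop("input error: concentration group(s) with fewer than 2 ",
             "predictions: ", paste(small, collapse = ", "), " uM",
             call. = FALSE)
    ck <- as.numeric(names(groups))
    sdv <- vapply(groups, stats::sd, numeric(1))
    per <- data.frame(concentration_uM = ck,
                      n = vapply(groups, length, integer(1)),
                      sd_uM = sdv, rsd_pct = 100 * sdv / ck,
                      row.names = NULL)
    per <- per[order(per$concentration_uM), ]
    list(perConcentration = per, average = mean(per$rsd_pct))
}

#' Best-fit calibration line of predicted on reference concentration
#'
#' Ordinary least squares with the predicted concentration as response,
#' `s_y/x = sqrt(sum(residuals^2) / (N - 2))` and r the Pearson correlation
#' of (reference, predicted).
#'
#' @param predictions a [PredictionSet-class] with >= 3 points and >= 2
#'   distinct references.
#' @return a [CalibrationLine-class].
#' @export
calibrationLine <- function(predictions) {
    e <- predictionEntries(predictions)
    if (nrow(e) < 3L) stop("at least 3 points required", call. = FALSE)
    if (length(unique(e$reference_uM)) < 2L)
        stop("degenerate design: all reference concentrations equal",
             call. = FALSE)
    fit <- stats::lm(predicted_uM ~ reference_uM, data = e)
    co <- stats::coef(fit)
    syx <- sqrt(sum(stats::residuals(fit)^2) / (nrow(e) - 2L))
    new("CalibrationLine", slope = unname(co[2L]),
        intercept = unname(co[1L]), syx = syx,
        r = stats::cor(e$reference_uM, e$predicted_uM),
        n = nrow(e))
}

#' Calibration-plot limit of detection (IUPAC 3-sigma)
#'
#' `LOD = 3 * s_y/x / slope`: three times the residual standard deviation of
#' the predicted-vs-reference best-fit line, expressed in concentration units
#' through the slope.
#'
#' @param line a [CalibrationLine-class] with positive slope.
#' @return LOD in uM.
#' @export
lodCalibration <- function(line) {
    stopifnot(is(line, "CalibrationLine"))
    if (line@slope <= 0)
        stop("invalid calibration: slope must be positive", call. = FALSE)
    3 * line@syx / line@slope
}

#' Fit an exponential precision profile RSD(c) = A exp(-B c) + C
#'
#' Bounded Levenberg-Marquardt nonlinear least squares (A, B > 0, C >= 0)
#' from 5 data-driven starts, keeping the lowest-residual converged fit.
#' The floor C captures the concentration-independent precision plateau.
#'
#' @param concentration_uM distinct concentrations c_k (uM), >= 3 points.
#' @param rsd_pct per-concentration RSD_k (%).
#' @return a [PrecisionProfile-class].
#' @export
fitPrecisionProfile <- function(concentration_uM, rsd_pct) {
    c_k <- as.numeric(concentration_uM); r_k <- as.numeric(rsd_pct)
    if (length(c_k) < 3L) stop("at least 3 points required", call. = FALSE)
    if (anyDuplicated(c_k)) stop("concentrations must be distinct",
                                 call. = FALSE)
    o <- order(c_k); c_k <- c_k[o]; r_k <- r_k[o]
    span <- max(r_k) - min(r_k)
    cr <- max(c_k) - min(c_k)
    bGuess <- if (span > 0 && r_k[1L] > r_k[length(r_k)])
        log(max(r_k[1L] - min(r_k), 1e-3) /
            max(r_k[length(r_k)] - min(r_k), 1e-3)) / cr else 1 / cr
    bGuess <- max(bGuess, 1e-6)
    starts <- list(
        c(A = max(span, 1e-3), B = bGuess, C = max(min(r_k), 0)),
        c(A = max(r_k[1L], 1e-3), B = bGuess, C = 0),
        c(A = max(span, 1e-3), B = 2 * bGuess, C = max(min(r_k), 0)),
        c(A = max(span, 1e-3), B = bGuess / 4, C = max(min(r_k) / 2, 0)),
        c(A = 1e-4, B = 1 / cr, C = max(mean(r_k), 1e-3)))
    best <- NULL; bestRSS <- Inf
    dat <- data.frame(c_k = c_k, r_k = r_k)
    for (st in starts) {
        fit <- tryCatch(
            minpack.lm::nlsLM(r_k ~ A * exp(-B * c_k) + C, data = dat,
                start = as.list(st),
                lower = c(A = 1e-12, B = 1e-12, C = 0),
                control = minpack.lm::nls.lm.control(maxiter = 500)),
            error = function(e) NULL)
        if (!is.null(fit)) {
            rss <- sum(stats::residuals(fit)^2)
            if (rss < bestRSS) { best <- fit; bestRSS <- rss }
        }
    }
    if (is.null(best)) {
        # a flat profile defeats the optimizer (zero-residual, A and B
        # unidentifiable); represent it as a vanishing decay on a floor
        if (diff(range(r_k)) <= 1e-8 * max(abs(r_k), 1)) {
            return(new(Class = "PrecisionProfile",
                points = data.frame(concentration_uM = c_k, rsd_pct = r_k),
                A = 1e-12, B = 1 / cr, C = mean(r_k),
                residualNorm = sqrt(sum((r_k - mean(r_k))^2))))
        }
        stop("fit error: no precision-profile start converged (",
             length(c_k), " points, RSD range ",
             paste(signif(range(r_k), 4), collapse = "-"), "%)",
             call. = FALSE)
    }
    cf <- stats::coef(best)
    # Class must be matched by full name: a slot named "C" would otherwise
    # partially match new()'s first formal
    new(Class = "PrecisionProfile",
        points = data.frame(concentration_uM = c_k, rsd_pct = r_k),
        A = unname(cf["A"]), B = unname(cf["B"]), C = unname(cf["C"]),
        residualNorm = sqrt(bestRSS))
}

#' Precision-profile limit of detection (RSD = 33.3% extrapolation)
#'
#' At the IUPAC 3-sigma detection limit the relative standard deviation is
#' 100/3 %, so the fitted profile is solved for that level:
#' `c = log(A / (100/3 - C)) / B`. If the fitted RSD is already below
#' 100/3 % at c = 0, the LOD is reported as 0 with `belowAtZero = TRUE`.
#'
#' @param profile a fitted [PrecisionProfile-class] with `C < 100/3`.
#' @return list with `lod_uM` and logical `belowAtZero`.
#' @export
lodPrecisionProfile <- function(profile) {
    stopifnot(is(profile, "PrecisionProfile"))
    target <- 100 / 3
    if (profile@C >= target)
        stop("no solution: fitted RSD floor (", signif(profile@C, 4),
             "%) is at or above 33.3%", call. = FALSE)
    if (profile@A + profile@C <= target)
        return(list(lod_uM = 0, belowAtZero = TRUE))
    list(lod_uM = log(profile@A / (target - profile@C)) / profile@B,
         belowAtZero = FALSE)
}

#' Full figures-of-merit report
#'
#' Computes REP, the per-concentration and average RSD, the calibration
#' line, the calibration-plot LOD and the precision-profile LOD. With
#' `excludeBelowLOD = TRUE`, REP and the average RSD are recomputed after
#' dropping concentration groups whose reference lies below the
#' calibration-plot LOD computed on the full set.
#'
#' @param predictions a [PredictionSet-class].
#' @param excludeBelowLOD recompute REP/RSD without below-LOD groups.
#' @param repMethod passed to [computeREP()].
#' @return a [MeritReport-class].
#' @export
meritReport <- function(predictions, excludeBelowLOD = FALSE,
                        repMethod = "mean_abs") {
    e <- predictionEntries(predictions)
    repPct <- computeREP(predictions, repMethod)
    rsd <- computeRSD(predictions)
    line <- calibrationLine(predictions)
    lodCal <- lodCalibration(line)
    lodPP <- tryCatch({
        pp <- fitPrecisionProfile(rsd$perConcentration$concentration_uM,
                                  rsd$perConcentration$rsd_pct)
        lodPrecisionProfile(pp)$lod_uM
    }, error = function(err) NA_real_)
    excluded <- character()
    repExcl <- repPct; rsdExcl <- rsd$average
    if (excludeBelowLOD) {
        drop <- unique(e$reference_uM[e$reference_uM < lodCal])
        if (length(drop)) {
            keep <- !(e$reference_uM %in% drop)
            sub <- new("PredictionSet", entries = e[keep, , drop = FALSE])
            repExcl <- computeREP(sub, repMethod)
            rsdExcl <- computeRSD(sub)$average
            excluded <- as.character(sort(drop))
        }
    }
    new("MeritReport", repPct = repPct, repExclPct = repExcl,
        rsdAvgPct = rsd$average, rsdExclPct = rsdExcl,
        rsdPerConc = rsd$perConcentration, line = line,
        lodCalibration_uM = lodCal, lodPrecisionProfile_uM = lodPP,
        excluded = excluded)
}
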