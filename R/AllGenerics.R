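#' Wavenumber axis of a spectral object
#'
#' @param x a [SpectraSet-class] (or other object carrying an axis).
#' @return numeric vector of wavenumbers in cm^-1, strictly increasing.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Intensity matrix of a SpectraSet
#'
#' @param x a [SpectraSet-class].
#' @return numeric matrix, wavenumber channels x spectra (counts).
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' Per-spectrum metadata of a SpectraSet
#'
#' @param x a [SpectraSet-class].
#' @return `data.frame`, one row per spectrum.
#' @export
setGeneric("spectraMeta", function(x) standardGeneric("spectraMeta"))

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "SpectraSet",
    function(x) rowData(x)$wavenumber_cm1)

#' @rdname intensityMatrix
#' @export
setMethod("intensityMatrix", "SpectraSet",
    function(x) assay(x, "intensity"))

#' @rdname spectraMeta
#' @export
setMethod("spectraMeta", "SpectraSet",
    function(x) as.data.frame(colData(x)))

# spectra-as-rows matrix used by all chemometric fits
.analysisMatrix <- function(x) t(assay(x, "intensity"))

setMethod("show", "SpectraSet", function(object) {
    wn <- wavenumbers(object)
    cd <- colData(object)
    cat("SpectraSet with", ncol(object), "spectra x", nrow(object),
        "wavenumber channels\n")
    if (length(wn))
        cat(sprintf("  axis: %.1f-%.1f cm-1 (median step %.2f)\n",
                    min(wn), max(wn), stats::median(diff(wn))))
    if ("analyte" %in% colnames(cd))
        cat("  analytes:", paste(names(table(cd$analyte)),
            table(cd$analyte), sep = ":", collapse = ", "), "\n")
    if ("concentration_uM" %in% colnames(cd)) {
        cc <- unique(stats::na.omit(cd$concentration_uM))
        cat("  concentrations (uM):",
            paste(signif(sort(cc), 4), collapse = ", "), "\n")
    }
    if (all(c("grid_x", "grid_y") %in% colnames(cd)) && !anyNA(cd$grid_x))
        cat("  map grid:", max(cd$grid_x), "x", max(cd$grid_y), "pixels\n")
})

setMethod("show", "BandModel", function(object) {
    cat("BandModel:", nrow(object@bands), "bands, eta =", object@eta, "\n")
    top <- object@bands[order(-object@bands$rel_amplitude), ][1:min(5,
        nrow(object@bands)), ]
    cat("  strongest:", paste(sprintf("%g cm-1 (%s, %.2f)", top$center,
        top$assignment, top$rel_amplitude), collapse = "; "), "\n")
})

setMethod("show", "PCAModel", function(object) {
    cat("PCAModel:", nrow(object@loadings), "components on",
        length(object@axis), "channels\n")
    cat("  explained variance (%):",
        paste(sprintf("%.2f", 100 * object@explainedVarFrac), collapse = ", "),
        "\n")
})

setMethod("show", "LogisticModel", function(object) {
    cat("LogisticModel on scores",
        paste(object@selectedComponents, collapse = ", "),
        sprintf("(ridge lambda = %g)\n", object@lambda))
    cat("  plane: 0 =", sprintf("%.4g", object@intercept), "+",
        paste(sprintf("%.4g*s%d", object@coefficients,
            object@selectedComponents), collapse = " + "), "\n")
    cat("  positive class:", object@classes[2], "\n")
})

setMethod("show", "PLSModel", function(object) {
    cat("PLSModel:", object@nLV, "latent variable(s),",
        length(object@axis), "channels\n")
})

setMethod("show", "PredictionSet", function(object) {
    e <- object@entries
    cat("PredictionSet:", nrow(e), "predictions,",
        length(unique(e$reference_uM)), "distinct concentrations\n")
    if (nrow(e) > 0L)
        cat(sprintf("  reference range %.4g-%.4g uM; r = %.4f\n",
            min(e$reference_uM), max(e$reference_uM),
            stats::cor(e$reference_uM, e$predicted_uM)))
})

setMethod("show", "CalibrationLine", function(object) {
    cat(sprintf(
        "CalibrationLine: chat = %.4g + %.4g * c (N = %d, syx = %.4g uM, r = %.4f)\n",
        object@intercept, object@slope, object@n, object@syx, object@r))
})

setMethod("show", "MeritReport", function(object) {
    cat(sprintf("MeritReport: REP %.2f%% (excl. below-LOD: %.2f%%)\n",
        object@repPct, object@repExclPct))
    cat(sprintf("  average RSD %.2f%% (excl.: %.2f%%)\n",
        object@rsdAvgPct, object@rsdExclPct))
    cat(sprintf("  LOD: calibration plot %.3g uM; precision profile %.3g uM\n",
        object@lodCalibration_uM, object@lodPrecisionProfile_uM))
})

setMethod("show", "ConcentrationGrid", function(object) {
    cat("ConcentrationGrid:", ncol(object@values), "radial x",
        nrow(object@values), "angular pixels, pitch", object@pitch_um,
        "um, reference", object@reference_uM, "uM\n")
})
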