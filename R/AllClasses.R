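#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData colData<-
NULL

#' SpectraSet: a container for aligned Raman spectra
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"intensity"` assay whose rows are wavenumber channels and whose
#' columns are individual spectra. The common wavenumber axis (cm^-1) lives in
#' `rowData(x)$wavenumber_cm1` and must be strictly increasing; per-spectrum
#' acquisition metadata (sample, analyte class, concentration in uM, location,
#' replicate, optional map-grid coordinates) live in `colData(x)`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#'
#' @seealso [SpectraSet()] for construction, [wavenumbers()],
#'   [spectraMeta()], [intensityMatrix()] for access.
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

.metaTriple <- c("sample_id", "location_id", "replicate_id")

setValidity("SpectraSet", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    rd <- rowData(object)
    if (!"wavenumber_cm1" %in% colnames(rd)) {
        msg <- c(msg, "rowData must contain 'wavenumber_cm1'")
    } else {
        wn <- rd$wavenumber_cm1
        if (anyNA(wn) || !is.numeric(wn))
            msg <- c(msg, "wavenumbers must be numeric and non-missing")
        else if (length(wn) > 1L && any(diff(wn) <= 0))
            msg <- c(msg, "wavenumbers must be strictly increasing")
    }
    if (length(msg) == 0L && anyNA(assay(object, "intensity")))
        msg <- c(msg, "intensities must not contain missing values")
    cd <- colData(object)
    if (all(.metaTriple %in% colnames(cd)) && ncol(object) > 0L) {
        isMap <- all(c("grid_x", "grid_y") %in% colnames(cd)) &&
            !anyNA(cd$grid_x)
        if (!isMap) {
            key <- paste(cd$sample_id, cd$location_id, cd$replicate_id)
            if (anyDuplicated(key))
                msg <- c(msg,
                    "(sample_id, location_id, replicate_id) must be unique")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet
#'
#' @param intensity numeric matrix of intensities, one column per spectrum and
#'   one row per wavenumber channel (arbitrary counts).
#' @param wavenumbers strictly increasing numeric vector of wavenumbers
#'   (cm^-1), one per row of `intensity`.
#' @param meta `data.frame` (or `DataFrame`) of per-spectrum metadata, one row
#'   per column of `intensity`. Recognised columns: `spectrum_id`, `sample_id`,
#'   `analyte` (`"albumin"` or `"glycated_albumin"`), `concentration_uM`,
#'   `location_id`, `replicate_id`, `grid_x`, `grid_y`, `measurement_order`.
#'
#' @return a [SpectraSet-class] object.
#' @examples
#' wn <- seq(600, 1800, by = 2)
#' m <- matrix(rnorm(length(wn) * 2, 100, 1), ncol = 2)
#' ss <- SpectraSet(m, wn, data.frame(spectrum_id = c("a", "b")))
#' ss
#' @export
SpectraSet <- function(intensity, wavenumbers,
                       meta = DataFrame(row.names = seq_len(ncol(intensity)))) {
    intensity <- as.matrix(intensity)
    meta <- DataFrame(meta)
    if (nrow(meta) != ncol(intensity))
        stop("meta must have one row per spectrum column", call. = FALSE)
    if (length(wavenumbers) != nrow(intensity))
        stop("wavenumbers must have one entry per intensity row",
             call. = FALSE)
    if ("spectrum_id" %in% colnames(meta))
        colnames(intensity) <- meta$spectrum_id
    se <- SummarizedExperiment(
        assays = SimpleList(intensity = intensity),
        rowData = DataFrame(wavenumber_cm1 = as.numeric(wavenumbers)),
        colData = meta)
    new("SpectraSet", se)
}

#' Pseudo-Voigt vibrational band model
#'
#' A `BandModel` is a list of vibrational bands (center in cm^-1, full width
#' at half maximum in cm^-1, relative amplitude, chemical assignment) plus a
#' Lorentzian mixing fraction `eta`; together these define a pure-component
#' Raman spectrum rendered as a sum of pseudo-Voigt profiles.
#'
#' @slot bands `data.frame` with columns `center`, `fwhm`, `rel_amplitude`,
#'   `assignment`.
#' @slot eta numeric in \[0, 1\]: Lorentzian fraction of the pseudo-Voigt.
#' @export
setClass("BandModel",
    representation(bands = "data.frame", eta = "numeric"),
    validity = function(object) {
        b <- object@bands
        need <- c("center", "fwhm", "rel_amplitude")
        if (!all(need %in% colnames(b)))
            return("bands needs columns center, fwhm, rel_amplitude")
        if (nrow(b) < 1L) return("at least one band required")
        if (any(b$fwhm <= 0)) return("fwhm must be positive")
        if (any(b$rel_amplitude < 0) || all(b$rel_amplitude == 0))
            return("amplitudes must be nonnegative and not all zero")
        if (length(object@eta) != 1L || object@eta < 0 || object@eta > 1)
            return("eta must be a single value in [0, 1]")
        TRUE
    })

#' Simulation configuration for synthetic DCDR spectra
#'
#' Bundles the wavenumber axis, the glycation effect size, the
#' signal/baseline/noise model, the between-location variability and the
#' random seed used by the spectrum simulator.
#'
#' @slot axisMin,axisMax,axisStep wavenumber axis specification (cm^-1).
#' @slot glycationEffect effect size epsilon in \[0, 1\] controlling the
#'   spectral perturbations of the glycated class.
#' @slot signalPerUM counts of peak signal per uM of analyte.
#' @slot baselineCoef length-3 polynomial coefficients (constant, linear,
#'   quadratic) of the background evaluated on the scaled axis
#'   `(wn - 1200)/600`.
#' @slot noiseFloor read-noise standard deviation sigma_read (counts).
#' @slot shotScale shot-noise scale sigma_0 (dimensionless); the per-point
#'   noise s.d. is `sqrt(noiseFloor^2 + shotScale^2 * max(clean, 0))`.
#' @slot locationSd log-scale s.d. of the lognormal per-location deposition
#'   factor.
#' @slot seed integer seed for all random draws.
#' @export
setClass("SimulationConfig",
    representation(axisMin = "numeric", axisMax = "numeric",
                   axisStep = "numeric", glycationEffect = "numeric",
                   signalPerUM = "numeric", baselineCoef = "numeric",
                   noiseFloor = "numeric", shotScale = "numeric",
                   locationSd = "numeric", seed = "integer"),
    validity = function(object) {
        if (object@axisStep <= 0) return("axisStep must be > 0")
        if (object@axisMax <= object@axisMin)
            return("axisMax must exceed axisMin")
        e <- object@glycationEffect
        if (e < 0 || e > 1) return("glycationEffect must be in [0, 1]")
        if (object@signalPerUM <= 0) return("signalPerUM must be > 0")
        if (length(object@baselineCoef) != 3L)
            return("baselineCoef must have length 3")
        if (object@noiseFloor < 0 || object@shotScale < 0)
            return("noise parameters must be nonnegative")
        if (object@locationSd < 0) return("locationSd must be nonnegative")
        TRUE
    })

#' Fitted principal component decomposition
#'
#' Mean-centered (no variance scaling) PCA of a spectral matrix via singular
#' value decomposition. Loadings are stored as orthonormal rows (components x
#' wavenumbers) with the sign convention that each loading's
#' largest-magnitude element is positive.
#'
#' @slot meanSpectrum column means of the training matrix.
#' @slot loadings n_components x n_wavenumbers orthonormal matrix.
#' @slot explainedVarFrac fraction of total variance per component,
#'   nonincreasing.
#' @slot axis training wavenumber axis (cm^-1).
#' @export
setClass("PCAModel",
    representation(meanSpectrum = "numeric", loadings = "matrix",
                   explainedVarFrac = "numeric", axis = "numeric"),
    validity = function(object) {
        k <- nrow(object@loadings)
        G <- tcrossprod(object@loadings)
        if (max(abs(G - diag(k))) > 1e-10)
            return("loading rows must be orthonormal")
        ev <- object@explainedVarFrac
        if (any(ev < -1e-12) || any(ev > 1 + 1e-12))
            return("explained fractions must lie in [0, 1]")
        if (length(ev) > 1L && any(diff(ev) > 1e-12))
            return("explained fractions must be nonincreasing")
        TRUE
    })

#' Principal-component score matrix with class labels
#'
#' @slot scores n_spectra x n_components matrix (columns score_1, score_2, ...)
#' @slot labels factor of per-spectrum class labels (may be all-NA for
#'   unlabeled data).
#' @export
setClass("ScoreMatrix",
    representation(scores = "matrix", labels = "factor"),
    validity = function(object) {
        if (length(object@labels) != nrow(object@scores))
            return("one label per score row required")
        TRUE
    })

#' Ridge-penalized logistic discrimination model on PC scores
#'
#' The decision plane is `w0 + w . s = 0` in the space of the selected
#' principal-component scores; a spectrum is called glycated when
#' `w0 + w . s > 0` (ties go to albumin).
#'
#' @slot intercept w0.
#' @slot coefficients named coefficient vector w, one per selected score.
#' @slot selectedComponents integer indices of the score columns used.
#' @slot lambda ridge penalty applied on standardized scores.
#' @slot classes length-2 character: `classes[1]` is the negative
#'   (albumin-like) class, `classes[2]` the positive.
#' @export
setClass("LogisticModel",
    representation(intercept = "numeric", coefficients = "numeric",
                   selectedComponents = "integer", lambda = "numeric",
                   classes = "character"),
    validity = function(object) {
        if (!all(is.finite(c(object@intercept, object@coefficients))))
            return("coefficients must be finite")
        if (object@lambda < 0) return("lambda must be nonnegative")
        if (length(object@classes) != 2L) return("exactly two classes")
        TRUE
    })

#' Fitted partial least squares calibration model
#'
#' Single-response NIPALS PLS on mean-centered spectra and concentrations.
#' Prediction uses the assembled regression vector:
#' `chat = (x - xMean) . b + yMean`.
#'
#' @slot nLV number of latent variables.
#' @slot xMean,yMean centering vectors/scalar.
#' @slot weights,xLoadings n_wavenumbers x nLV matrices W and P.
#' @slot yLoadings length-nLV vector q.
#' @slot coefVector regression vector b (concentration per count).
#' @slot axis training wavenumber axis (cm^-1).
#' @export
setClass("PLSModel",
    representation(nLV = "integer", xMean = "numeric", yMean = "numeric",
                   weights = "matrix", xLoadings = "matrix",
                   yLoadings = "numeric", coefVector = "numeric",
                   axis = "numeric"),
    validity = function(object) {
        if (object@nLV < 1L) return("nLV must be >= 1")
        if (!all(is.finite(object@coefVector)))
            return("regression vector must be finite")
        TRUE
    })

#' Paired reference/predicted concentrations
#'
#' Holds the output of (cross-validated) calibration: one row per spectrum
#' with its reference concentration c_i, predicted concentration chat_i, and
#' grouping metadata. Consumed by the figures-of-merit functions.
#'
#' @slot entries `data.frame` with columns `reference_uM`, `predicted_uM`,
#'   `sample_id`, `location_id`, `replicate_id` and optionally `fold`, `n_lv`.
#' @export
setClass("PredictionSet",
    representation(entries = "data.frame"),
    validity = function(object) {
        e <- object@entries
        if (!all(c("reference_uM", "predicted_uM") %in% colnames(e)))
            return("entries needs reference_uM and predicted_uM")
        if (nrow(e) > 0L && any(e$reference_uM <= 0))
            return("reference concentrations must be positive")
        TRUE
    })

#' Best-fit line of predicted on reference concentration
#'
#' Ordinary least squares of predicted concentration (response) on reference
#' concentration (regressor), the orientation used for the IUPAC 3-sigma
#' calibration-plot limit of detection `LOD = 3 * syx / slope`.
#'
#' @slot slope,intercept fitted line (intercept in uM).
#' @slot syx residual standard deviation `sqrt(sum(r^2)/(N-2))`, uM.
#' @slot r Pearson correlation of (reference, predicted).
#' @slot n number of points.
#' @export
setClass("CalibrationLine",
    representation(slope = "numeric", intercept = "numeric", syx = "numeric",
                   r = "numeric", n = "integer"),
    validity = function(object) {
        if (object@n < 3L) return("at least 3 points required")
        if (object@syx < 0) return("syx must be nonnegative")
        if (is.finite(object@r) && abs(object@r) > 1 + 1e-12)
            return("|r| must be <= 1")
        TRUE
    })

#' Precision profile: RSD versus concentration with exponential fit
#'
#' Per-concentration relative standard deviations fitted with
#' `RSD(c) = A * exp(-B * c) + C` (A, B > 0, C >= 0); extrapolating the fit to
#' RSD = 100/3 % gives the precision-profile limit of detection.
#'
#' @slot points `data.frame` with columns `concentration_uM`, `rsd_pct`.
#' @slot A,B,C fitted parameters (A, C in %, B per uM).
#' @slot residualNorm Euclidean norm of fit residuals (%).
#' @export
setClass("PrecisionProfile",
    representation(points = "data.frame", A = "numeric", B = "numeric",
                   C = "numeric", residualNorm = "numeric"),
    validity = function(object) {
        if (object@A <= 0 || object@B <= 0 || object@C < 0)
            return("require A > 0, B > 0, C >= 0")
        if (anyDuplicated(object@points$concentration_uM))
            return("profile concentrations must be distinct")
        TRUE
    })

#' Figures-of-merit report for a prediction set
#'
#' @slot repPct average relative error of prediction (%).
#' @slot repExclPct REP recomputed excluding concentration groups below the
#'   calibration-plot LOD (equals `repPct` when nothing is excluded).
#' @slot rsdAvgPct,rsdExclPct average relative standard deviation (%), full
#'   and after the same exclusion.
#' @slot rsdPerConc `data.frame` of per-concentration RSD_k (%).
#' @slot line the fitted [CalibrationLine-class].
#' @slot lodCalibration_uM IUPAC 3-sigma calibration-plot LOD (uM).
#' @slot lodPrecisionProfile_uM LOD from the precision-profile extrapolation
#'   (uM; `NA` if the profile fit failed).
#' @slot excluded character vector of excluded concentration groups.
#' @export
setClass("MeritReport",
    representation(repPct = "numeric", repExclPct = "numeric",
                   rsdAvgPct = "numeric", rsdExclPct = "numeric",
                   rsdPerConc = "data.frame", line = "CalibrationLine",
                   lodCalibration_uM = "numeric",
                   lodPrecisionProfile_uM = "numeric",
                   excluded = "character"))

#' Predicted concentration grid over a 2D ring map
#'
#' Predicted concentrations arranged on the mapping grid: columns are radial
#' pixels (X, pixel 1 innermost), rows are angular-direction pixels (Y).
#'
#' @slot values ny x nx matrix of predicted concentrations (uM); column j
#'   holds all Y-pixels at radial pixel j.
#' @slot pitch_um inter-point distance (um).
#' @slot reference_uM reference analyte concentration of the mapped sample.
#' @export
setClass("ConcentrationGrid",
    representation(values = "matrix", pitch_um = "numeric",
                   reference_uM = "numeric"),
    validity = function(object) {
        if (object@pitch_um <= 0) return("pixel pitch must be positive")
        TRUE
    })
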