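#' Predict a concentration grid from a 2D map dataset
#'
#' Applies a PLS calibration model (trained without the mapped sample) to
#' every grid spectrum and arranges the predictions by `(grid_x, grid_y)`:
#' columns of the result are radial pixels (X, pixel 1 innermost), rows the
#' angular-direction pixels (Y).
#'
#' @param model a [PLSModel-class].
#' @param mapSet a [SpectraSet-class] with complete `grid_x`, `grid_y`
#'   metadata covering a full `nx` x `ny` grid.
#' @return a [ConcentrationGrid-class].
#' @export
predictMap <- function(model, mapSet) {
    stopifnot(is(model, "PLSModel"), is(mapSet, "SpectraSet"))
    meta <- spectraMeta(mapSet)
    if (!all(c("grid_x", "grid_y") %in% colnames(meta)) ||
        anyNA(meta$grid_x) || anyNA(meta$grid_y))
        stop("consistency error: complete grid_x/grid_y metadata required",
             call. = FALSE)
    nx <- max(meta$grid_x); ny <- max(meta$grid_y)
    idx <- matrix(NA_integer_, ny, nx)
    idx[cbind(meta$grid_y, meta$grid_x)] <- seq_len(nrow(meta))
    if (anyNA(idx))
        stop("consistency error: missing grid cells in the map dataset",
             call. = FALSE)
    pred <- predictPLS(model, mapSet)
    vals <- matrix(pred[idx], ny, nx)
    ref <- if ("concentration_uM" %in% colnames(meta))
        meta$concentration_uM[1L] else NA_real_
    pitch <- metadata(mapSet)$pitch_um
    new("ConcentrationGrid", values = vals,
        pitch_um = if (is.null(pitch)) 8 else pitch, reference_uM = ref)
}

#' Radial concentration profile of a map
#'
#' Mean predicted concentration over the angular (Y) pixels for each radial
#' (X) pixel.
#'
#' @param grid a [ConcentrationGrid-class].
#' @return numeric vector of per-column means (uM), innermost pixel first.
#' @export
radialProfile <- function(grid) {
    stopifnot(is(grid, "ConcentrationGrid"))
    colMeans(grid@values)
}

#' Angular coefficients of variation of a map
#'
#' For each radial pixel, the coefficient of variation of the predictions
#' along the angular (Y) direction: sample (n-1) standard deviation over the
#' column mean. Columns with zero mean are flagged `NA` rather than raising
#' an error.
#'
#' @param grid a [ConcentrationGrid-class] with at least 2 angular pixels.
#' @return list with `perColumn` (CV per radial pixel), `min`, `max`,
#'   `mean` (over defined columns) and `undefinedColumns`.
#' @export
angularCV <- function(grid) {
    stopifnot(is(grid, "ConcentrationGrid"))
    v <- grid@values
    if (nrow(v) < 2L) stop("at least 2 angular pixels required",
                           call. = FALSE)
    mu <- colMeans(v)
    cv <- apply(v, 2L, stats::sd) / mu
    cv[mu == 0] <- NA_real_
    und <- which(mu == 0)
    if (length(und))
        warning("undefined CV (zero column mean) at radial pixel(s) ",
                paste(und, collapse = ", "), call. = FALSE)
    list(perColumn = cv, min = min(cv, na.rm = TRUE),
         max = max(cv, na.rm = TRUE), mean = mean(cv, na.rm = TRUE),
         undefinedColumns = und)
}

#' Mean predicted concentration over the ring-center radial pixels
#'
#' Average over all pixels of the listed radial columns — by default the
#' plateau columns 5 and 6 at the analyte-rich center of the annular ring,
#' where predictions should reproduce the reference concentration.
#'
#' @param grid a [ConcentrationGrid-class].
#' @param columns radial pixel indices, default `c(5, 6)`.
#' @return mean concentration (uM).
#' @export
centerBandMean <- function(grid, columns = c(5L, 6L)) {
    stopifnot(is(grid, "ConcentrationGrid"))
    if (any(columns < 1L | columns > ncol(grid@values)))
        stop("parameter error: column index outside 1..",
             ncol(grid@values), call. = FALSE)
    mean(grid@values[, columns])
}
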