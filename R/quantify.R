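# Extract X (spectra x wavenumbers), y (uM) and sample groups from inputs
.plsInputs <- function(x, y = NULL, groups = NULL) {
    if (is(x, "SpectraSet")) {
        meta <- spectraMeta(x)
        if (is.null(y)) y <- meta$concentration_uM
        if (is.null(groups) && "sample_id" %in% colnames(meta))
            groups <- meta$sample_id
        list(X = .analysisMatrix(x), y = as.numeric(y), groups = groups,
             axis = wavenumbers(x))
    } else {
        list(X = as.matrix(x), y = as.numeric(y), groups = groups,
             axis = as.numeric(seq_len(ncol(as.matrix(x)))))
    }
}

# NIPALS decomposition for a single response; returns centering info and
# the W, P, q sequences so regression vectors for any 1..nLV are cheap
.nipals <- function(X, y, nLV) {
    n <- nrow(X); p <- ncol(X)
    xMean <- colMeans(X); yMean <- mean(y)
    E <- sweep(X, 2L, xMean); f <- y - yMean
    W <- matrix(0, p, nLV); P <- matrix(0, p, nLV); q <- numeric(nLV)
    for (a in seq_len(nLV)) {
        w <- drop(crossprod(E, f))
        nw <- sqrt(sum(w^2))
        if (nw < .Machine$double.eps)
            stop("parameter error: no covariance left to extract at latent ",
                 "variable ", a, call. = FALSE)
        w <- w / nw
        t <- drop(E %*% w)
        tt <- sum(t^2)
        pp <- drop(crossprod(E, t)) / tt
        q[a] <- sum(f * t) / tt
        E <- E - tcrossprod(t, pp)
        f <- f - q[a] * t
        W[, a] <- w; P[, a] <- pp
    }
    list(xMean = xMean, yMean = yMean, W = W, P = P, q = q)
}

.plsCoef <- function(dec, k) {
    W <- dec$W[, seq_len(k), drop = FALSE]
    P <- dec$P[, seq_len(k), drop = FALSE]
    drop(W %*% solve(crossprod(P, W), dec$q[seq_len(k)]))
}

#' Fit a NIPALS partial least squares calibration model
#'
#' Single-response NIPALS: each latent variable takes the weight
#' `w = X'y / |X'y|`, scores `t = Xw`, loadings `p = X't/t't`,
#' `q = y't/t't`, then deflates X (and y). X and y are mean-centered only —
#' no per-channel autoscaling. The regression vector is
#' `b = W (P'W)^-1 q`, so `predict(xMean) = yMean` exactly.
#'
#' @param x a [SpectraSet-class] (concentrations taken from metadata) or a
#'   spectra-by-wavenumbers matrix.
#' @param y reference concentrations (uM); taken from `concentration_uM`
#'   metadata when `x` is a `SpectraSet`.
#' @param nLV number of latent variables
#'   (`1 <= nLV <= min(n - 1, n_wavenumbers)`).
#' @return a [PLSModel-class].
#' @export
fitPLS <- function(x, y = NULL, nLV = 2L) {
    inp <- .plsInputs(x, y)
    X <- inp$X; y <- inp$y
    if (nrow(X) < 2L) stop("at least 2 spectra required", call. = FALSE)
    if (stats::sd(y) == 0)
        stop("input error: constant response y", call. = FALSE)
    nLV <- as.integer(nLV)
    if (nLV < 1L || nLV > min(nrow(X) - 1L, ncol(X)))
        stop("parameter error: nLV must be in 1..",
             min(nrow(X) - 1L, ncol(X)), call. = FALSE)
    dec <- .nipals(X, y, nLV)
    new("PLSModel", nLV = nLV, xMean = dec$xMean, yMean = dec$yMean,
        weights = dec$W, xLoadings = dec$P, yLoadings = dec$q,
        coefVector = .plsCoef(dec, nLV), axis = inp$axis)
}

#' Predict concentrations with a fitted PLS model
#'
#' `chat = (x - xMean) . b + yMean` per spectrum.
#'
#' @param model a [PLSModel-class].
#' @param x a [SpectraSet-class] on the training axis, or a matrix with the
#'   training channel count. Negative predictions are returned as-is
#'   (clipping would bias detection-limit statistics).
#' @return numeric vector of predicted concentrations (uM).
#' @export
predictPLS <- function(model, x) {
    stopifnot(is(model, "PLSModel"))
    if (is(x, "SpectraSet")) {
        if (length(wavenumbers(x)) != length(model@axis) ||
            any(wavenumbers(x) != model@axis))
            stop("consistency error: axis does not match the training axis",
                 call. = FALSE)
        X <- .analysisMatrix(x)
    } else {
        X <- as.matrix(x)
        if (ncol(X) != length(model@xMean))
            stop("consistency error: channel count mismatch", call. = FALSE)
    }
    unname(drop(sweep(X, 2L, model@xMean) %*% model@coefVector) +
           model@yMean)
}

#' @describeIn predictPLS `predict` method for `PLSModel`.
#' @param object a [PLSModel-class].
#' @param newdata spectra to predict.
#' @param ... ignored.
#' @export
setMethod("predict", "PLSModel",
    function(object, newdata, ...) predictPLS(object, newdata))

# leave-one-group-out RMSECV for each latent-variable count 1..maxLV
.rmsecvByLV <- function(X, y, groups, maxLV) {
    folds <- split(seq_len(nrow(X)), groups)
    sse <- numeric(maxLV)
    for (fold in folds) {
        Xtr <- X[-fold, , drop = FALSE]; ytr <- y[-fold]
        d <- svd(sweep(Xtr, 2, colMeans(Xtr)), nu = 0, nv = 0)$d
        kmax <- min(maxLV, nrow(Xtr) - 1L, ncol(Xtr),
                    sum(d > max(d) * 1e-10))
        dec <- .nipals(Xtr, ytr, kmax)
        Xte <- sweep(X[fold, , drop = FALSE], 2L, dec$xMean)
        for (k in seq_len(maxLV)) {
            kk <- min(k, kmax)
            pred <- drop(Xte %*% .plsCoef(dec, kk)) + dec$yMean
            sse[k] <- sse[k] + sum((pred - y[fold])^2)
        }
    }
    sqrt(sse / length(y))
}

#' Choose the PLS latent-variable count by grouped cross-validation
#'
#' Inner leave-one-group-out RMSECV over `1..maxLV`, then the parsimony
#' rule: the smallest count whose RMSECV is within 2% of the minimum.
#'
#' @param x spectra ([SpectraSet-class] or matrix).
#' @param y reference concentrations (uM).
#' @param groups sample identifiers defining the CV groups (>= 3 groups).
#' @param maxLV largest count considered (>= 1), default 8.
#' @return chosen integer latent-variable count.
#' @export
selectNumLV <- function(x, y = NULL, groups = NULL, maxLV = 8L) {
    inp <- .plsInputs(x, y, groups)
    if (maxLV < 1L) stop("parameter error: maxLV must be >= 1",
                         call. = FALSE)
    if (length(unique(inp$groups)) < 3L)
        stop("at least 3 groups required", call. = FALSE)
    maxLV <- min(as.integer(maxLV), nrow(inp$X) - 2L, ncol(inp$X))
    rmsecv <- .rmsecvByLV(inp$X, inp$y, inp$groups, maxLV)
    which(rmsecv <= 1.02 * min(rmsecv))[1L]
}

#' Leave-one-sample-out cross-validated PLS predictions
#'
#' For each sample: the calibration model is fitted on all other samples
#' (with the latent-variable count chosen by [selectNumLV()] strictly inside
#' the training fold) and used to predict the left-out sample's spectra.
#' Under the study design this gives 6 folds of 75 training / 15 test
#' spectra and 90 predictions in total, each spectrum predicted exactly once.
#'
#' @param x a [SpectraSet-class] calibration set with `sample_id` and
#'   `concentration_uM` metadata (>= 3 samples).
#' @param maxLV largest latent-variable count considered per fold.
#' @return a [PredictionSet-class] with `fold` and `n_lv` columns.
#' @export
losoCrossValidate <- function(x, maxLV = 8L) {
    stopifnot(is(x, "SpectraSet"))
    meta <- spectraMeta(x)
    if (!all(c("sample_id", "concentration_uM") %in% colnames(meta)))
        stop("sample_id and concentration_uM metadata required",
             call. = FALSE)
    X <- .analysisMatrix(x)
    y <- meta$concentration_uM
    samples <- unique(meta$sample_id)
    if (length(samples) < 3L)
        stop("at least 3 samples required", call. = FALSE)
    out <- vector("list", length(samples))
    for (i in seq_along(samples)) {
        test <- which(meta$sample_id == samples[i])
        if (length(test) == 0L)
            stop("consistency error: sample ", samples[i],
                 " has no spectra", call. = FALSE)
        train <- setdiff(seq_len(nrow(X)), test)
        Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
        grTr <- meta$sample_id[train]
        k <- if (length(unique(grTr)) >= 3L && length(train) > 3L)
            selectNumLV(Xtr, ytr, grTr, maxLV) else
            min(maxLV, length(train) - 1L)
        model <- fitPLS(Xtr, ytr, k)
        pred <- predictPLS(model, X[test, , drop = FALSE])
        out[[i]] <- data.frame(
            spectrum_id = if ("spectrum_id" %in% colnames(meta))
                meta$spectrum_id[test] else as.character(test),
            sample_id = meta$sample_id[test],
            location_id = if ("location_id" %in% colnames(meta))
                meta$location_id[test] else NA_integer_,
            replicate_id = if ("replicate_id" %in% colnames(meta))
                meta$replicate_id[test] else NA_integer_,
            reference_uM = y[test], predicted_uM = pred,
            fold = i, n_lv = k, stringsAsFactors = FALSE)
    }
    new("PredictionSet", entries = do.call(rbind, out))
}

#' Construct a PredictionSet from reference/predicted pairs
#'
#' @param reference_uM,predicted_uM paired concentrations (uM); references
#'   must be positive.
#' @param sample_id,location_id,replicate_id optional grouping metadata.
#' @return a [PredictionSet-class].
#' @export
PredictionSet <- function(reference_uM, predicted_uM,
                          sample_id = as.character(reference_uM),
                          location_id = NA_integer_,
                          replicate_id = NA_integer_) {
    n <- length(reference_uM)
    new("PredictionSet", entries = data.frame(
        reference_uM = as.numeric(reference_uM),
        predicted_uM = as.numeric(predicted_uM),
        sample_id = rep_len(sample_id, n),
        location_id = rep_len(location_id, n),
        replicate_id = rep_len(replicate_id, n), stringsAsFactors = FALSE))
}

#' Entries of a PredictionSet
#'
#' @param x a [PredictionSet-class].
#' @return `data.frame` of paired reference/predicted concentrations.
#' @export
predictionEntries <- function(x) {
    stopifnot(is(x, "PredictionSet"))
    x@entries
}
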