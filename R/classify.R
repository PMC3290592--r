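#' Fit a mean-centered PCA model to a spectral dataset
#'
#' Column-mean-centered singular value decomposition without variance
#' scaling (relative band intensity is the signal in Raman spectra). Each
#' loading's largest-magnitude element is made positive; the explained
#' fraction of component j is its squared singular value over the total.
#'
#' @param x a [SpectraSet-class] or a spectra-by-wavenumbers matrix.
#' @param nComponents number of components to retain
#'   (<= min(n_spectra, n_wavenumbers)).
#' @return a [PCAModel-class].
#' @export
fitPCA <- function(x, nComponents = 4L) {
    if (is(x, "SpectraSet")) {
        axis <- wavenumbers(x)
        X <- .analysisMatrix(x)
    } else {
        X <- as.matrix(x)
        axis <- as.numeric(seq_len(ncol(X)))
    }
    nComponents <- as.integer(nComponents)
    if (nComponents < 1L || nComponents > min(dim(X)))
        stop("parameter error: nComponents must be in 1..",
             min(dim(X)), call. = FALSE)
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    sv <- svd(Xc, nu = 0L, nv = nComponents)
    tot <- sum(sv$d^2)
    if (tot > 0) {
        V <- t(sv$v)                   # components x wavenumbers
        flip <- apply(V, 1L, function(v) sign(v[which.max(abs(v))]))
        V <- V * flip
        frac <- sv$d[seq_len(nComponents)]^2 / tot
    } else {
        # constant dataset: no variance to decompose; canonical axes
        V <- diag(ncol(X))[seq_len(nComponents), , drop = FALSE]
        frac <- rep(0, nComponents)
    }
    new("PCAModel", meanSpectrum = mu, loadings = V,
        explainedVarFrac = frac, axis = axis)
}

#' Project spectra onto a fitted PCA model
#'
#' `scores = (X - mean_spectrum) %*% t(loadings)`, with the analyte class
#' carried along as labels when present.
#'
#' @param model a [PCAModel-class].
#' @param x a [SpectraSet-class] on the model's axis, or a matrix with
#'   matching column count.
#' @return a [ScoreMatrix-class]; columns named `score1`, `score2`, ...
#' @export
projectScores <- function(model, x) {
    stopifnot(is(model, "PCAModel"))
    if (is(x, "SpectraSet")) {
        if (length(wavenumbers(x)) != length(model@axis) ||
            any(wavenumbers(x) != model@axis))
            stop("consistency error: dataset axis does not match the model",
                 call. = FALSE)
        labels <- if ("analyte" %in% colnames(colData(x)))
            factor(colData(x)$analyte) else
            factor(rep(NA_character_, ncol(x)))
        X <- .analysisMatrix(x)
    } else {
        X <- as.matrix(x)
        if (ncol(X) != ncol(model@loadings))
            stop("consistency error: matrix width does not match the model",
                 call. = FALSE)
        labels <- factor(rep(NA_character_, nrow(X)))
    }
    S <- sweep(X, 2L, model@meanSpectrum) %*% t(model@loadings)
    colnames(S) <- paste0("score", seq_len(ncol(S)))
    new("ScoreMatrix", scores = S, labels = labels)
}

# ridge-penalized logistic log-likelihood maximised by damped IRLS;
# the penalty acts on the slope coefficients only (not the intercept)
.ridgeLogisticIRLS <- function(Z, y01, lambda, maxIter = 200L, tol = 1e-8) {
    p <- ncol(Z)
    beta <- numeric(p + 1L)
    D <- diag(c(0, rep(1, p)))
    X1 <- cbind(1, Z)
    objective <- function(b) {
        eta <- drop(X1 %*% b)
        # log(1 + exp(eta)) computed overflow-safe
        lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
        sum(y01 * eta - lse) - lambda * sum(b[-1L]^2)
    }
    obj <- objective(beta)
    for (it in seq_len(maxIter)) {
        eta <- drop(X1 %*% beta)
        p1 <- stats::plogis(eta)
        W <- pmax(p1 * (1 - p1), 1e-12)
        grad <- drop(crossprod(X1, y01 - p1)) - 2 * lambda * D %*% beta
        H <- crossprod(X1 * W, X1) + 2 * lambda * D
        step <- drop(solve(H, grad))
        # step-halving keeps the penalized likelihood nondecreasing
        alpha <- 1
        repeat {
            cand <- beta + alpha * step
            candObj <- objective(cand)
            if (candObj >= obj - 1e-12 || alpha < 1e-8) break
            alpha <- alpha / 2
        }
        delta <- max(abs(cand - beta))
        beta <- cand; obj <- candObj
        if (delta < tol) break
    }
    beta
}

#' Fit ridge-penalized logistic discrimination on PC scores
#'
#' Maximum penalized likelihood via iteratively reweighted least squares on
#' the selected score columns, standardized internally so the ridge penalty
#' is scale-free; coefficients are returned on the raw score scale. The small
#' default ridge keeps the optimum finite and well-defined even under perfect
#' class separation.
#'
#' @param scores a [ScoreMatrix-class] with exactly two label classes.
#' @param selectedComponents score columns used as features (default 2, 3, 4;
#'   the first component mostly tracks overall intensity and is excluded).
#' @param lambda ridge penalty on standardized scores (>= 0), default 1e-3.
#' @param positiveClass label treated as positive; default
#'   `"glycated_albumin"` when present, else the second factor level.
#' @return a [LogisticModel-class].
#' @export
fitLogistic <- function(scores, selectedComponents = c(2L, 3L, 4L),
                        lambda = 1e-3, positiveClass = NULL) {
    stopifnot(is(scores, "ScoreMatrix"))
    if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
    labels <- droplevels(scores@labels)
    if (nlevels(labels) != 2L)
        stop("input error: exactly two classes required (got ",
             nlevels(labels), ")", call. = FALSE)
    if (is.null(positiveClass))
        positiveClass <- if ("glycated_albumin" %in% levels(labels))
            "glycated_albumin" else levels(labels)[2L]
    negClass <- setdiff(levels(labels), positiveClass)
    selectedComponents <- as.integer(selectedComponents)
    if (max(selectedComponents) > ncol(scores@scores))
        stop("parameter error: selected components exceed available scores",
             call. = FALSE)
    Z <- scores@scores[, selectedComponents, drop = FALSE]
    y01 <- as.numeric(labels == positiveClass)
    mu <- colMeans(Z)
    sdv <- apply(Z, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    Zs <- sweep(sweep(Z, 2L, mu), 2L, sdv, "/")
    beta <- .ridgeLogisticIRLS(Zs, y01, lambda)
    w <- beta[-1L] / sdv
    w0 <- beta[1L] - sum(beta[-1L] * mu / sdv)
    names(w) <- colnames(Z)
    new("LogisticModel", intercept = w0, coefficients = w,
        selectedComponents = selectedComponents, lambda = lambda,
        classes = c(negClass, positiveClass))
}

#' Classify score rows with a fitted logistic model
#'
#' A spectrum is assigned the positive (glycated-like) class iff
#' `w0 + w . s > 0`; points exactly on the plane go to the negative
#' (albumin-like) class.
#'
#' @param model a [LogisticModel-class].
#' @param scores a [ScoreMatrix-class] whose columns cover the model's
#'   selected components.
#' @return list with `labels` (factor of predictions) and `accuracy`
#'   (fraction correct; `NA` when the scores carry no labels).
#' @export
classifyScores <- function(model, scores) {
    stopifnot(is(model, "LogisticModel"), is(scores, "ScoreMatrix"))
    if (max(model@selectedComponents) > ncol(scores@scores))
        stop("score columns do not cover the selected components",
             call. = FALSE)
    S <- scores@scores[, model@selectedComponents, drop = FALSE]
    d <- model@intercept + drop(S %*% model@coefficients)
    pred <- factor(ifelse(d > 0, model@classes[2L], model@classes[1L]),
                   levels = model@classes)
    acc <- if (all(is.na(scores@labels))) NA_real_ else
        mean(as.character(pred) == as.character(scores@labels))
    list(labels = pred, accuracy = acc)
}

# fit + training accuracy for one label vector on fixed scores
.trainAccuracy <- function(scores, labels, selectedComponents, lambda) {
    sm <- new("ScoreMatrix", scores = scores@scores, labels = factor(labels))
    fit <- fitLogistic(sm, selectedComponents, lambda)
    classifyScores(fit, sm)$accuracy
}

#' Permutation control studies for the PCA-score logistic pipeline
#'
#' Rebuilds the discrimination step under null labelings to show that the
#' real-label accuracy is not a chance artifact. `"random"` mode permutes the
#' class labels uniformly over all spectra. `"measurement_order"` mode draws
#' a random sample-blocked acquisition order (each sample's spectra
#' contiguous, samples interleaved arbitrarily) and labels the first half of
#' the order as one class and the second half as the other, probing temporal
#' drift. PCA is label-independent, so the scores are computed once and the
#' logistic plane is refit for every repeat.
#'
#' @param x a [SpectraSet-class] with `analyte` labels (and, for order mode,
#'   `measurement_order` and `sample_id` metadata).
#' @param mode `"random"` or `"measurement_order"`.
#' @param nRepeats number of relabelings (>= 1).
#' @param seed integer seed for the relabeling draws.
#' @param nComponents components to extract (default 4).
#' @param selectedComponents,lambda passed to [fitLogistic()].
#' @return list with `mean`, `sd` and `accuracies` (per-repeat training
#'   accuracy fractions).
#' @export
permutationControl <- function(x, mode = c("random", "measurement_order"),
                               nRepeats = 200L, seed = 1L,
                               nComponents = 4L,
                               selectedComponents = c(2L, 3L, 4L),
                               lambda = 1e-3) {
    mode <- match.arg(mode)
    stopifnot(is(x, "SpectraSet"), nRepeats >= 1L)
    meta <- spectraMeta(x)
    if (!"analyte" %in% colnames(meta))
        stop("input error: dataset has no analyte labels", call. = FALSE)
    if (mode == "measurement_order" &&
        !all(c("measurement_order", "sample_id") %in% colnames(meta)))
        stop("input error: measurement_order mode needs measurement_order ",
             "and sample_id metadata", call. = FALSE)
    pca <- fitPCA(x, nComponents)
    sc <- projectScores(pca, x)
    classes <- levels(droplevels(factor(meta$analyte)))
    n <- ncol(x)
    half <- n %/% 2L
    acc <- .withSeed(seed, vapply(seq_len(nRepeats), function(i) {
        lab <- if (mode == "random") {
            sample(as.character(meta$analyte))
        } else {
            # fresh sample-blocked interleaving per repeat
            blocks <- sample(unique(meta$sample_id))
            pos <- order(match(meta$sample_id, blocks))
            ord <- integer(n); ord[pos] <- seq_len(n)
            ifelse(ord <= half, classes[1L], classes[2L])
        }
        .trainAccuracy(sc, lab, selectedComponents, lambda)
    }, numeric(1)))
    list(mean = mean(acc), sd = stats::sd(acc), accuracies = acc)
}
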