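test_that("PCA matches an independent covariance eigendecomposition", {
    set.seed(21)
    X <- matrix(rnorm(20 * 50), 20, 50)
    pca <- fitPCA(X, 10L)
    # oracle: brute-force eigendecomposition of the covariance matrix
    ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
    fracOracle <- ev[1:10] / sum(ev)
    expect_equal(pca@explainedVarFrac, fracOracle, tolerance = 1e-10)
    # orthonormal loadings, nonincreasing variance
    G <- tcrossprod(pca@loadings)
    expect_lt(max(abs(G - diag(10))), 1e-10)
    expect_true(all(diff(pca@explainedVarFrac) <= 1e-12))
    # reconstruction with all components is complete
    full <- fitPCA(X, 20L)
    S <- sweep(X, 2, full@meanSpectrum) %*% t(full@loadings)
    rec <- S %*% full@loadings + rep(1, 20) %o% full@meanSpectrum
    expect_lt(max(abs(rec - X)) / max(abs(X)), 1e-8)
})

test_that("two distinct spectra give a rank-one decomposition", {
    wn <- seq(600, 700, 10)
    ds <- SpectraSet(cbind(a = seq(0, 10), b = c(rep(0, 6), rep(5, 5))), wn,
                     data.frame(spectrum_id = c("a", "b")))
    pca <- fitPCA(ds, 2L)
    expect_equal(pca@explainedVarFrac[1], 1, tolerance = 1e-12)
})

test_that("score projection is centered and reproduces explained variance", {
    ds <- simulateDiscriminationSet(studyConfig(seed = 22L))
    pca <- fitPCA(ds, 4L)
    sc <- projectScores(pca, ds)
    expect_lt(max(abs(colMeans(sc@scores))) / stats::sd(sc@scores[, 1]), 1e-9)
    # projecting the mean spectrum itself gives a zero score row
    z <- projectScores(pca, matrix(pca@meanSpectrum, nrow = 1))
    expect_lt(max(abs(z@scores)), 1e-6 * stats::sd(sc@scores[, 1]))
    # training score covariance diagonal equals the explained variances
    emp <- unname(apply(sc@scores, 2, function(v) sum(v^2)))
    expect_equal(emp / sum(emp) * sum(pca@explainedVarFrac),
                 pca@explainedVarFrac, tolerance = 1e-8)
    # axis mismatch is refused
    ds2 <- resampleSpectra(ds, seq(700, 1700, 2))
    expect_error(projectScores(pca, ds2), "consistency error")
})

test_that("ridge logistic matches a direct penalized-likelihood grid search", {
    # 2 points, 1 feature scaled to unit sd so standardization is identity
    z <- c(-1, 1) / sqrt(2)
    sm <- new("ScoreMatrix", scores = cbind(score1 = z),
              labels = factor(c("albumin", "glycated_albumin")))
    fit <- fitLogistic(sm, selectedComponents = 1L, lambda = 0.01)
    obj <- function(w0, w) {
        eta1 <- w0 + w * z[1]; eta2 <- w0 + w * z[2]
        (0 - log1p(exp(eta1))) + (eta2 - log1p(exp(eta2))) - 0.01 * w^2
    }
    # staged grid search (oracle independent of IRLS)
    best <- c(0, 0); step <- 0.02; span <- 10
    for (stage in 1:3) {
        grid <- expand.grid(
            w0 = seq(best[1] - span, best[1] + span, by = step),
            w = seq(best[2] - span, best[2] + span, by = step))
        vals <- obj(grid$w0, grid$w)
        best <- unlist(grid[which.max(vals), ])
        span <- 2 * step; step <- step / 50
    }
    expect_equal(unname(fit@intercept), unname(best[1]), tolerance = 1e-4)
    expect_equal(unname(fit@coefficients[1]), unname(best[2]),
                 tolerance = 1e-4)
})

test_that("separable scores classify perfectly; degenerate scores at chance", {
    set.seed(23)
    s2 <- c(rnorm(40, -4), rnorm(40, 4))
    sm <- new("ScoreMatrix",
              scores = cbind(score1 = rnorm(80), score2 = s2,
                             score3 = rnorm(80), score4 = rnorm(80)),
              labels = factor(rep(c("albumin", "glycated_albumin"),
                                  each = 40)))
    fit <- fitLogistic(sm)
    res <- classifyScores(fit, sm)
    expect_equal(res$accuracy, 1)
    # flipping all labels complements the accuracy
    flip <- new("ScoreMatrix", scores = sm@scores,
                labels = factor(rep(c("glycated_albumin", "albumin"),
                                    each = 40)))
    expect_equal(classifyScores(fit, flip)$accuracy, 1 - res$accuracy)
    # both classes at identical score values: accuracy 50%
    same <- new("ScoreMatrix",
                scores = cbind(score1 = rep(1, 40), score2 = rep(2, 40),
                               score3 = 0, score4 = 0),
                labels = factor(rep(c("albumin", "glycated_albumin"), 20)))
    expect_equal(classifyScores(fitLogistic(same), same)$accuracy, 0.5)
    # a point exactly on the plane goes to albumin
    m <- new("LogisticModel", intercept = 0, coefficients = c(score2 = 1),
             selectedComponents = 2L, lambda = 0,
             classes = c("albumin", "glycated_albumin"))
    onPlane <- new("ScoreMatrix", scores = cbind(score1 = 1, score2 = 0),
                   labels = factor("albumin",
                       levels = c("albumin", "glycated_albumin")))
    expect_equal(as.character(classifyScores(m, onPlane)$labels), "albumin")
    # single-class input is an input error
    one <- new("ScoreMatrix", scores = sm@scores,
               labels = factor(rep("albumin", 80),
                               levels = c("albumin", "glycated_albumin")))
    expect_error(fitLogistic(one), "two classes")
})

test_that("default two-class dataset separates perfectly on scores 2-4", {
    ds <- simulateDiscriminationSet(studyConfig(seed = 24L))
    sc <- projectScores(fitPCA(ds, 4L), ds)
    fit <- fitLogistic(sc)
    expect_equal(classifyScores(fit, sc)$accuracy, 1)
})

test_that("permutation controls are reproducible and behave at the null", {
    ds <- simulateDiscriminationSet(studyConfig(seed = 25L))
    a1 <- permutationControl(ds, "random", nRepeats = 1L, seed = 99L)
    a2 <- permutationControl(ds, "random", nRepeats = 1L, seed = 99L)
    expect_identical(a1$accuracies, a2$accuracies)
    r <- permutationControl(ds, "random", nRepeats = 30L, seed = 7L)
    expect_lt(abs(r$mean - 0.5), 0.1)  # near chance
    # identical spectra: accuracy degenerate at the majority-class fraction
    wn <- seq(600, 700, 10)
    flat <- SpectraSet(matrix(5, 11, 20), wn,
        data.frame(spectrum_id = sprintf("s%02d", 1:20),
                   sample_id = rep(c("a", "b"), each = 10),
                   analyte = rep(c("albumin", "glycated_albumin"), each = 10),
                   location_id = rep(1:2, 10), replicate_id = rep(1:5, 4)))
    fr <- permutationControl(flat, "random", nRepeats = 10L, seed = 1L,
                             nComponents = 4L)
    expect_true(all(fr$accuracies == 0.5))
    # order mode requires order metadata
    noOrd <- simulateCalibrationSet(studyConfig(seed = 26L), "albumin")
    expect_error(permutationControl(noOrd, "measurement_order", 2L),
                 "input error")
})

test_that("pipeline accuracy is invariant to global intensity rescaling", {
    ds <- simulateDiscriminationSet(studyConfig(seed = 27L))
    run <- function(x) {
        sc <- projectScores(fitPCA(x, 4L), x)
        classifyScores(fitLogistic(sc), sc)$accuracy
    }
    scaled <- SpectraSet(intensityMatrix(ds) * 3.7, wavenumbers(ds),
                         spectraMeta(ds))
    expect_equal(run(ds), run(scaled))
})

test_that("accuracy does not decrease with the glycation effect size", {
    acc <- sapply(c(0, 0.1, 0.2, 0.3), function(eps) {
        mean(sapply(1:12, function(s) {
            d <- simulateDiscriminationSet(
                studyConfig(seed = 300L + s, glycationEffect = eps))
            sc <- projectScores(fitPCA(d, 4L), d)
            classifyScores(fitLogistic(sc), sc)$accuracy
        }))
    })
    expect_true(all(diff(acc) >= -1e-9))
})

test_that("at zero effect size held-out accuracy is chance-level", {
    accs <- sapply(1:20, function(s) {
        d <- simulateDiscriminationSet(
            studyConfig(seed = 400L + s, glycationEffect = 0))
        samples <- unique(spectraMeta(d)$sample_id)
        train <- c(samples[1:3], samples[7:9])  # 3 samples per class
        heldOutAccuracy(d, train)
    })
    expect_lt(abs(mean(accs) - 0.5), 3 * stats::sd(accs) / sqrt(20) + 0.05)
    # training accuracy of the 3-feature logistic stays modest at the null
    trAcc <- sapply(1:10, function(s) {
        d <- simulateDiscriminationSet(
            studyConfig(seed = 500L + s, glycationEffect = 0))
        sc <- projectScores(fitPCA(d, 4L), d)
        classifyScores(fitLogistic(sc), sc)$accuracy
    })
    expect_lt(mean(trAcc), 0.70)
})
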