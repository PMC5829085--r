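## hand-built external signal with M = N "patches" mirroring an
## internal structure (identity coupling toy)
mirrorSignal <- function(I) {
    J <- length(I); N <- nrow(I[[1]])
    S <- array(0, c(N, 3, J))
    for (j in seq_len(J)) S[, , j] <- I[[j]]
    new("ExternalSignal", S = S, A = array(0, c(0, 0, 0)),
        patchIds = seq_len(N))
}

randomDVFs <- function(M, J, seed = 1) {
    set.seed(seed)
    dvfs <- lapply(seq_len(J), function(j) matrix(rnorm(M * 3), M, 3))
    midp <- Reduce(`+`, dvfs) / J
    lapply(dvfs, function(d) d - midp)   # phase-mean zero, like MidP DVFs
}

test_that("composite assembly centers columns with the stated layout", {
    I <- randomDVFs(2, 3)
    sig <- directionalSignal(mirrorSignal(randomDVFs(2, 3, seed = 2)))
    comp <- assembleComposite(I, sig, "SurMod")
    expect_equal(dim(comp@D), c(3 * 2 + 6 * 2, 3))
    expect_equal(rowSums(comp@D), rep(0, nrow(comp@D)),
                 tolerance = 1e-12)
    ## layout: internal block is vertex-major x,y,z; external block is
    ## per patch [S triple, A triple]
    j <- 2
    d2 <- comp@D[, j] + comp@dbar
    expect_equal(d2[1:3], unname(I[[j]][1, ]))
    expect_equal(d2[6 + 1:3], unname(sig@S[1, , j]))
    expect_equal(d2[6 + 4:6], unname(sig@A[1, , j]))
    ## identical phases -> zero matrix, dbar = d_1
    Ic <- lapply(1:3, function(j) matrix(1, 2, 3))
    sc <- mirrorSignal(Ic)
    compc <- assembleComposite(Ic, directionalSignal(sc), "SurMod")
    expect_true(all(abs(compc@D) < 1e-14))
    ## J = 2: centered columns are opposite
    I2 <- randomDVFs(2, 2)
    comp2 <- assembleComposite(I2, mirrorSignal(randomDVFs(2, 2, 3)),
                               "SurphaMod")
    expect_equal(comp2@D[, 1], -comp2@D[, 2])
    expect_error(assembleComposite(I, mirrorSignal(randomDVFs(2, 4)),
                                   "SurphaMod"), "mismatch")
})

test_that("Gram-matrix PCA matches direct covariance eigendecomposition", {
    for (seed in 1:20) {
        set.seed(seed)
        D <- matrix(rnorm(8 * 5), 8, 5)
        ## oracle: brute-force eigendecomposition of the 8 x 8 covariance
        oracleVals <- eigen(D %*% t(D), symmetric = TRUE)$values
        got <- pcaSmall(D, K = 4)
        expect_equal(got$values, oracleVals[seq_along(got$values)],
                     tolerance = 1e-9)
        ## eigenvectors satisfy the covariance eigen equation
        for (k in seq_len(got$K)) {
            e <- got$vectors[, k]
            expect_equal(as.vector(D %*% t(D) %*% e), got$values[k] * e,
                         tolerance = 1e-8 * got$values[1])
            expect_equal(sum(e^2), 1, tolerance = 1e-12)
            expect_gt(e[which.max(abs(e))], 0)   # sign convention
        }
    }
})

test_that("rank-1 matrices yield exactly one retained mode", {
    u <- c(1, -2, 3, 0.5); v <- c(2, 1, -1)
    got <- pcaSmall(u %*% t(v), K = 2)
    expect_equal(got$K, 1L)
    expect_equal(got$values[1], sum(u^2) * sum(v^2), tolerance = 1e-12)
})

test_that("K = J - 1 reconstruction of a centered matrix is complete", {
    set.seed(4)
    d <- matrix(rnorm(40 * 6), 40, 6)
    D <- d - rowMeans(d)
    got <- pcaSmall(D, K = 5)
    E <- got$vectors
    expect_lt(norm(D - E %*% (t(E) %*% D), "F") / norm(D, "F"), 1e-9)
    expect_error(pcaSmall(D, K = 6), "J - 1")
})

test_that("rank-1 split gives the closed-form correlation operator", {
    alpha <- 0.8; beta <- 0.6
    u <- c(1, 2, -1) / sqrt(6)
    v <- c(3, 0, 4, 0, 0, 0) / 5
    E <- matrix(c(alpha * u, beta * v), ncol = 1)
    lay <- compositeLayout(M = 1, N = 1, variant = "SurMod")
    model <- splitAndCorrelate(list(vectors = E, values = 1, K = 1L),
                               dbar = rep(0, 9), layout = lay)
    expect_equal(model@B, (alpha / beta) * u %*% t(v),
                 tolerance = 1e-12)
})

test_that("identity coupling reproduces internal motion exactly", {
    I <- randomDVFs(5, 6, seed = 11)
    sig <- mirrorSignal(I)
    comp <- assembleComposite(I, sig, "SurphaMod")
    pca <- pcaSmall(comp, K = 5)
    model <- splitAndCorrelate(pca, comp@dbar, comp@layout)
    for (j in seq_along(I)) {
        pred <- predictInternal(model, sig@S[, , j])
        expect_equal(pred$dvf, I[[j]], tolerance = 1e-8,
                     ignore_attr = TRUE)
    }
})

test_that("training phases are recovered in-sample at K = J - 1", {
    pair <- smallCyclePair("1")
    model <- suppressWarnings(
        fitCorrelationModel(pair$internal, pair$external, "SurMod"))
    midpI <- midpReference(pair$internal)
    Idvf <- phasicDVF(pair$internal, midpI)
    sig <- suppressWarnings(externalSignal(
        pair$external, model@grid, midp = model@midpExternal))
    relI <- max(vapply(Idvf, function(d) max(abs(d)), numeric(1)))
    for (j in seq_len(nPhases(pair$internal))) {
        pred <- predictInternal(model, sig@S[, , j], sig@A[, , j])
        expect_lt(max(abs(pred$dvf - Idvf[[j]])) / relI, 1e-6)
        expect_equal(pred$vertices, pair$internal@vertices[[j]],
                     tolerance = 1e-6, ignore_attr = TRUE)
    }
    ## oracle cross-check: least-squares fit of the mode weights from
    ## the external block reproduces the internal block
    comp <- assembleComposite(Idvf, sig, "SurMod")
    pca <- pcaSmall(comp, K = 9)
    ES <- pca$vectors[comp@layout$idxExternal, , drop = FALSE]
    EI <- pca$vectors[comp@layout$idxInternal, , drop = FALSE]
    for (j in c(2, 7)) {
        W <- qr.solve(ES, comp@D[comp@layout$idxExternal, j])
        expect_equal(as.vector(EI %*% W),
                     comp@D[comp@layout$idxInternal, j],
                     tolerance = 1e-8)
    }
})

test_that("the mean breathing state predicts zero deformation", {
    pair <- smallCyclePair("1")
    model <- suppressWarnings(
        fitCorrelationModel(pair$internal, pair$external, "SurphaMod"))
    N <- length(model@patchIds)
    Sbar <- matrix(model@dbarS, ncol = 3, byrow = TRUE)
    pred <- predictInternal(model, Sbar)
    expect_equal(pred$dvf, matrix(0, nVertices(pair$internal), 3),
                 tolerance = 1e-10, ignore_attr = TRUE)
    ## affine linearity of the prediction operator
    set.seed(5)
    s1 <- matrix(rnorm(N * 3), N, 3); s2 <- matrix(rnorm(N * 3), N, 3)
    p12 <- predictInternal(model, s1 + s2 - Sbar)$dvf
    expect_equal(p12, predictInternal(model, s1)$dvf +
                      predictInternal(model, s2)$dvf, tolerance = 1e-9)
})

test_that("SurMod without a directional term demands an explicit choice", {
    pair <- smallCyclePair("1")
    model <- suppressWarnings(
        fitCorrelationModel(pair$internal, pair$external, "SurMod"))
    N <- length(model@patchIds)
    S0 <- matrix(0, N, 3)
    expect_error(predictInternal(model, S0), "cyclic|zeroA")
    expect_silent(predictInternal(model, S0, zeroA = TRUE))
})

test_that("B is invariant under eigenvector rescaling", {
    I <- randomDVFs(4, 6, seed = 21)
    sig <- directionalSignal(mirrorSignal(randomDVFs(4, 6, seed = 22)))
    comp <- assembleComposite(I, sig, "SurMod")
    pca <- pcaSmall(comp, K = 5)
    model <- splitAndCorrelate(pca, comp@dbar, comp@layout)
    set.seed(23)
    scales <- runif(pca$K, 0.2, 5) * sample(c(-1, 1), pca$K, TRUE)
    pca2 <- pca
    pca2$vectors <- sweep(pca$vectors, 2, scales, "*")
    model2 <- splitAndCorrelate(pca2, comp@dbar, comp@layout)
    expect_equal(model2@B, model@B, tolerance = 1e-9)
})

test_that("RoiMod patch selection ranks by mean displacement magnitude", {
    ## construct a signal with known amplitudes
    N <- 6; J <- 4
    amp <- c(5, 1, 3, 0, 2, 4)
    S <- array(0, c(N, 3, J))
    for (j in seq_len(J)) S[, 3, j] <- amp * sin(2 * pi * j / J)
    sig <- new("ExternalSignal", S = S, A = array(0, c(0, 0, 0)),
               patchIds = seq_len(N))
    ## brute-force amplitude ranking oracle
    mag <- sapply(seq_len(N), function(n)
        mean(sapply(seq_len(J), function(j) sqrt(sum(S[n, , j]^2)))))
    oracle <- sort(order(-mag)[1:3])
    expect_equal(selectRoiPatches(sig, 3), oracle)
    expect_equal(selectRoiPatches(sig, N), seq_len(N))  # degenerate
    ## static patch excluded at count = N - 1
    expect_false(4L %in% selectRoiPatches(sig, N - 1))
    expect_error(selectRoiPatches(sig, N + 1), "patches")
})

test_that("training error degrades monotonically as K decreases", {
    pair <- smallCyclePair("1")
    midpI <- midpReference(pair$internal)
    Idvf <- phasicDVF(pair$internal, midpI)
    errAtK <- function(K) {
        model <- suppressWarnings(fitCorrelationModel(
            pair$internal, pair$external, "SurphaMod", K = K))
        sig <- suppressWarnings(externalSignal(
            pair$external, model@grid, midp = model@midpExternal,
            directional = FALSE))
        mean(vapply(seq_len(nPhases(pair$internal)), function(j)
            mean(abs(predictInternal(model, sig@S[, , j])$dvf -
                     Idvf[[j]])), numeric(1)))
    }
    errs <- vapply(c(9, 2, 1), errAtK, numeric(1))
    expect_true(all(diff(errs) >= -1e-12))
})

test_that("phase-indexed prediction is period-invariant", {
    ## same amplitude, different period: phase-indexed motion identical
    cfg <- smallConfig()
    cys <- standardCycles()
    train <- generatePhantom(cfg, cys[["1"]],
                             voxelizeMasks = character(0))
    cyT <- cycleSpec(6L, period = 4.0, amplitude = 12, tumorDiameter = 30)
    test <- generatePhantom(cfg, cyT, voxelizeMasks = character(0))
    model <- suppressWarnings(fitCorrelationModel(
        train@meshes$tumor, train@meshes$external, "SurMod"))
    dvfs <- lapply(test@meshes$external@vertices, function(v)
        v - model@midpExternal@vertices)
    sig <- directionalSignal(patchSignal(dvfs, model@grid))
    for (j in seq_len(10)) {
        pred <- predictInternal(model, sig@S[, , j], sig@A[, , j])
        truthCom <- colMeans(test@meshes$tumor@vertices[[j]])
        expect_lt(max(abs(colMeans(pred$vertices) - truthCom)), 1e-3)
    }
})

test_that("model serialization round-trips losslessly", {
    pair <- smallCyclePair("1")
    model <- suppressWarnings(
        fitCorrelationModel(pair$internal, pair$external, "SurMod"))
    path <- tempfile(fileext = ".rcm")
    writeModel(model, path)
    back <- readModel(path)
    expect_equal(back@B, model@B, tolerance = 1e-12)
    expect_equal(back@dbarS, model@dbarS, tolerance = 1e-12)
    expect_identical(back@variant, model@variant)
    expect_identical(back@patchIds, model@patchIds)
    expect_equal(meshVertices(back@midpInternal),
                 meshVertices(model@midpInternal), tolerance = 1e-12)
    suppressWarnings(expect_error(readModel(tempfile())))
})

test_that("variance-fraction mode selection picks the smallest adequate K", {
    expect_equal(chooseK(c(8, 1, 1), 0.8), 1L)
    expect_equal(chooseK(c(8, 1, 1), 0.9), 2L)
    expect_equal(chooseK(c(8, 1, 1), 1.0), 3L)
    pair <- smallCyclePair("1")
    model <- suppressWarnings(
        fitCorrelationModel(pair$internal, pair$external, "SurMod"))
    ## the phantom has two temporal modes: 95% needs at most 2
    expect_lte(chooseK(modelEigenvalues(model), 0.95), 2L)
    expect_equal(sum(varianceExplained(model)), 1, tolerance = 1e-12)
})
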