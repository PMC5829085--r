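## tiny two-phase mesh set with a single triangle pair (tetrahedron)
tetra <- function(shift = c(0, 0, 0)) {
    v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
    new("SurfaceMesh", vertices = sweep(v, 2, shift, "+"), faces = f,
        structureName = "tetra")
}

test_that("mid-position reference is the per-vertex phase mean", {
    ms <- new("PhaseMeshSet", structureName = "t",
              vertices = list(tetra()@vertices,
                              tetra(c(2, 0, 0))@vertices),
              faces = tetra()@faces)
    midp <- midpReference(ms)
    expect_equal(meshVertices(midp)[1, ], c(1, 0, 0))
    same <- new("PhaseMeshSet", structureName = "t",
                vertices = list(tetra()@vertices, tetra()@vertices),
                faces = tetra()@faces)
    expect_equal(meshVertices(midpReference(same)), tetra()@vertices)
})

test_that("mid-position tumor centroid equals the phase-averaged trajectory", {
    ph <- smallCyclePair("1")$phantom
    cy <- ph@cycle
    ## independent average of the closed-form trajectory samples
    trBar <- colMeans(breathingTrajectory(cy, phaseTimes(cy)))
    midpCom <- colMeans(meshVertices(midpReference(ph@meshes$tumor)))
    expect_equal(unname(midpCom), unname(ph@config@tumorCenter + trBar),
                 tolerance = 1e-10)
})

test_that("phasic DVFs sum to zero over phases and handle toy cases", {
    ms <- new("PhaseMeshSet", structureName = "t",
              vertices = list(tetra()@vertices,
                              tetra(c(2, 0, 0))@vertices),
              faces = tetra()@faces)
    dvfs <- phasicDVF(ms)
    expect_equal(dvfs[[1]][, 1], rep(-1, 4))
    expect_equal(dvfs[[2]][, 1], rep(1, 4))
    ph <- smallCyclePair("1")$phantom
    dv <- phasicDVF(ph@meshes$lung)
    expect_equal(Reduce(`+`, dv), matrix(0, nrow(dv[[1]]), 3),
                 tolerance = 1e-9, ignore_attr = TRUE)
    static <- new("PhaseMeshSet", structureName = "t",
                  vertices = list(tetra()@vertices, tetra()@vertices),
                  faces = tetra()@faces)
    expect_true(all(phasicDVF(static)[[1]] == 0))
    bad <- midpReference(ms)
    bad@vertices <- bad@vertices[-1, , drop = FALSE]
    bad@faces <- matrix(c(1L, 2L, 3L), 1)
    expect_error(phasicDVF(ms, bad), "correspondence")
})

test_that("patch grid has the standard 14 x 11 layout and partitions", {
    ph <- smallCyclePair("1")$phantom
    midp <- midpReference(ph@meshes$external)
    grid <- suppressWarnings(buildPatchGrid(midp))
    expect_equal(grid@rows * grid@cols, 154L)
    ## partition: every anterior vertex in exactly one patch
    expect_setequal(unlist(grid@members), grid@anteriorVertices)
    expect_equal(sum(lengths(grid@members)),
                 length(grid@anteriorVertices))
    single <- buildPatchGrid(midp, rows = 1, cols = 1)
    expect_equal(length(single@members[[1]]),
                 length(single@anteriorVertices))
})

test_that("bin boundaries assign to the lower-index bin", {
    ## flat anterior plate: vertices on exact bin boundaries
    xs <- c(0, 1, 2, 3, 4); zs <- c(0, 1, 2)
    g <- expand.grid(x = xs, z = zs)
    v <- cbind(g$x, 1, g$z)
    ## fan triangulation just to give outward (+y) normals
    f <- t(vapply(seq_len(nrow(v) - 2), function(i)
        c(1L, i + 1L, i + 2L), integer(3)))
    ## ensure +y normals: orient consistently
    mesh <- new("SurfaceMesh", vertices = v,
                faces = f[, c(1, 3, 2), drop = FALSE],
                structureName = "plate")
    vn <- respicor:::.vertexNormalsFast(mesh@vertices, mesh@faces)
    if (mean(sign(vn[vn[, 2] != 0, 2])) < 0)
        mesh@faces <- mesh@faces[, c(1, 3, 2), drop = FALSE]
    grid <- suppressWarnings(buildPatchGrid(mesh, rows = 2, cols = 2))
    ## x = 2 sits exactly on the ML boundary -> lower column;
    ## z = 1 sits exactly on the SI boundary -> lower row
    vtx <- which(v[, 1] == 2 & v[, 3] == 1)
    patch <- which(vapply(grid@members, function(m) vtx %in% m,
                          logical(1)))
    expect_equal(patch, 1L)  # row 1, col 1
})

test_that("patch averaging is the member mean and is linear", {
    ph <- smallCyclePair("1")$phantom
    midp <- midpReference(ph@meshes$external)
    grid <- suppressWarnings(buildPatchGrid(midp, rows = 3, cols = 3))
    M <- nVertices(ph@meshes$external)
    u <- c(1, -2, 0.5)
    uni <- list(matrix(u, M, 3, byrow = TRUE))
    sig <- patchSignal(uni, grid)
    for (n in seq_len(dim(sig@S)[1]))
        expect_equal(unname(sig@S[n, , 1]), u)
    ## linearity
    set.seed(7)
    U <- list(matrix(rnorm(M * 3), M, 3))
    V <- list(matrix(rnorm(M * 3), M, 3))
    lin <- patchSignal(list(2 * U[[1]] + 3 * V[[1]]), grid)
    expect_equal(lin@S, 2 * patchSignal(U, grid)@S +
                        3 * patchSignal(V, grid)@S, tolerance = 1e-12)
    ## cancellation within one patch
    memb <- grid@members[[which(grid@active)[1]]]
    W <- matrix(0, M, 3)
    half <- seq_along(memb) %% 2 == 0
    if (sum(half) == sum(!half)) {
        W[memb[half], 3] <- 2
        W[memb[!half], 3] <- -2
        sw <- patchSignal(list(W), grid)
        expect_equal(unname(sw@S[1, , 1]), c(0, 0, 0))
    }
})

test_that("directional DVFs telescope to zero with cyclic wraparound", {
    ## scalar toy sequence S = (1, 3, 2) -> A = (-1, +2, -1)
    S <- array(0, c(1, 3, 3))
    S[1, 1, ] <- c(1, 3, 2)
    sig <- new("ExternalSignal", S = S, A = array(0, c(0, 0, 0)),
               patchIds = 1L)
    d <- directionalSignal(sig)
    expect_equal(d@A[1, 1, ], c(-1, 2, -1))
    expect_equal(sum(d@A), 0)
    ## constant signal -> zero directional DVFs
    Sc <- array(2, c(2, 3, 4))
    dc <- directionalSignal(new("ExternalSignal", S = Sc,
                                A = array(0, c(0, 0, 0)),
                                patchIds = 1:2))
    expect_true(all(dc@A == 0))
    ## phantom signals: exact telescoping
    ph <- smallCyclePair("1")$phantom
    grid <- suppressWarnings(
        buildPatchGrid(midpReference(ph@meshes$external)))
    sigp <- externalSignal(ph@meshes$external, grid)
    expect_equal(apply(sigp@A, c(1, 2), sum),
                 matrix(0, dim(sigp@A)[1], 3), tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("empty patches are flagged and excluded consistently", {
    ph <- smallCyclePair("1")$phantom
    midp <- midpReference(ph@meshes$external)
    expect_warning(grid <- buildPatchGrid(midp, rows = 30, cols = 30),
                   "empty")
    sig <- patchSignal(phasicDVF(ph@meshes$external, midp), grid)
    expect_equal(dim(sig@S)[1], sum(grid@active))
    expect_identical(sig@patchIds, which(grid@active))
})

test_that("correspondence providers map perturbed meshes back", {
    mesh <- ellipsoidMesh(c(0, 0, 0), c(10, 12, 14), 8, 12)
    expect_identical(correspondVertices(mesh, mesh, "exact"),
                     seq_len(nVertices(mesh)))
    ## mild jitter, shuffled vertex order: nearest neighbor recovers it
    set.seed(17)
    perm <- sample(nVertices(mesh))
    shuffled <- new("SurfaceMesh",
                    vertices = mesh@vertices[perm, ] +
                        matrix(rnorm(3 * nVertices(mesh), sd = 0.01),
                               ncol = 3),
                    faces = mesh@faces, structureName = "shuffled")
    idx <- correspondVertices(shuffled, mesh, "nearest")
    expect_identical(idx, match(seq_len(nVertices(mesh)), perm))
    ## custom provider function is honored
    expect_identical(
        correspondVertices(mesh, mesh, function(t, r) rep(1L, 5)),
        rep(1L, 5))
    small <- ellipsoidMesh(c(0, 0, 0), c(1, 1, 1), 4, 6)
    expect_error(correspondVertices(small, mesh, "exact"),
                 "vertex counts")
})

test_that("patch grids round-trip through the text format", {
    ph <- smallCyclePair("1")$phantom
    grid <- suppressWarnings(
        buildPatchGrid(midpReference(ph@meshes$external)))
    path <- tempfile(fileext = ".txt")
    writePatchGrid(grid, path)
    back <- readPatchGrid(path)
    expect_identical(back@rows, grid@rows)
    expect_identical(back@members, grid@members)
    expect_identical(back@active, grid@active)
    expect_equal(back@siRange, grid@siRange, tolerance = 1e-9)
})
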