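test_that("breathing trajectory matches its closed form", {
    cy <- cycleSpec(1, period = 5, amplitude = 12, tumorDiameter = 30)
    tr0 <- breathingTrajectory(cy, 0)
    expect_equal(unname(tr0[1, ]), c(0, 0, 0), tolerance = 1e-12)
    trq <- breathingTrajectory(cy, 5 / 4)
    expect_equal(unname(trq[1, "AP"]), 1.2)
    expect_equal(unname(trq[1, "SI"]), 6)
    ## peak-to-peak SI excursion over one period equals H
    t <- seq(0, 5, length.out = 2001)
    si <- breathingTrajectory(cy, t)[, "SI"]
    expect_equal(max(si) - min(si), 12, tolerance = 1e-4)
    expect_error(cycleSpec(1, period = -1, amplitude = 12,
                           tumorDiameter = 30), "positive")
})

test_that("trajectory is periodic with period T", {
    for (cy in standardCycles()) {
        t <- seq(0, cy@period, length.out = 17)
        expect_equal(breathingTrajectory(cy, t),
                     breathingTrajectory(cy, t + cy@period),
                     tolerance = 1e-12)
    }
})

test_that("standard cycles carry the study parameters", {
    cys <- standardCycles()
    got <- t(vapply(cys, function(c)
        c(c@period, c@amplitude, c@tumorDiameter), numeric(3)))
    expect_equal(unname(got),
                 rbind(c(5, 12, 30), c(4.5, 10, 30), c(5.5, 14, 30),
                       c(4.5, 8, 20), c(6, 16, 20)))
    expect_true(all(vapply(cys, function(c) c@nPhases, integer(1)) == 10L))
})

test_that("phantom generation is seed-deterministic", {
    cfg <- smallConfig(noiseSigma = 0.5)
    cy <- standardCycles()[["1"]]
    a <- generatePhantom(cfg, cy, voxelizeMasks = character(0))
    b <- generatePhantom(cfg, cy, voxelizeMasks = character(0))
    expect_identical(a@meshes$tumor@vertices, b@meshes$tumor@vertices)
    expect_identical(a@meshes$external@vertices,
                     b@meshes$external@vertices)
    cfg2 <- smallConfig(noiseSigma = 0.5, seed = 99L)
    c <- generatePhantom(cfg2, cy, voxelizeMasks = character(0))
    expect_false(identical(a@meshes$tumor@vertices,
                           c@meshes$tumor@vertices))
})

test_that("tumor centroid follows the trajectory exactly", {
    pair <- smallCyclePair("1")
    ph <- pair$phantom
    cy <- ph@cycle
    tr <- breathingTrajectory(cy, phaseTimes(cy))
    trBar <- colMeans(tr)
    midp <- midpReference(ph@meshes$tumor)
    midpCom <- colMeans(meshVertices(midp))
    for (j in c(1, 4, 8)) {
        com <- colMeans(meshVertices(ph@meshes$tumor, j))
        expect_equal(unname(com - midpCom), unname(tr[j, ] - trBar),
                     tolerance = 1e-10)
    }
})

test_that("external motion is anterior-weighted and posterior-static", {
    ph <- smallCyclePair("1")$phantom
    ext <- ph@meshes$external
    disp <- ext@vertices[[4]] - ext@vertices[[1]]
    mag <- sqrt(rowSums(disp^2))
    y <- ext@vertices[[1]][, 2]
    expect_gt(max(mag[y > 100]), 0)           # anterior wall moves
    expect_equal(max(mag[y < 0]), 0)          # couch side static
    ## anterior AP peak-to-peak equals H at the anterior pole
    apAll <- vapply(seq_len(nPhases(ext)), function(j)
        max(ext@vertices[[j]][, 2]), numeric(1))
    expect_equal(max(apAll) - min(apAll), ph@cycle@amplitude,
                 tolerance = 0.05 * ph@cycle@amplitude)
})

test_that("noise-free displacements have temporal rank at most 2", {
    ph <- smallCyclePair("1")$phantom
    for (s in names(ph@meshes)) {
        dvfs <- phasicDVF(ph@meshes[[s]])
        X <- do.call(cbind, lapply(dvfs, as.vector))
        sv <- svd(X)$d
        expect_lt(sv[3] / sv[1], 1e-10)
    }
})

test_that("mask and mesh centroids agree within a voxel diagonal", {
    ph <- smallCyclePair("1")$phantom
    diagv <- sqrt(sum(ph@config@spacing^2))
    for (s in c("tumor", "lung")) for (j in c(1, 6)) {
        meshCom <- colMeans(meshVertices(ph@meshes[[s]], j))
        expect_lt(sqrt(sum((maskCentroid(ph@masks[[s]][[j]]) -
                            meshCom)^2)), diagv)
    }
})

test_that("tumor mask volume scales with the cube of the diameter", {
    st <- smallStudy(c("1", "5"))
    v1 <- sum(maskArray(st[["1"]]@masks$tumor[[1]]))
    v5 <- sum(maskArray(st[["5"]]@masks$tumor[[1]]))
    expect_equal(v5 / v1, (20 / 30)^3, tolerance = 0.10)
})

test_that("a tumor escaping the lung is a configuration error", {
    cfg <- smallConfig(tumorCenter = c(65, 0, 120))
    expect_error(generatePhantom(cfg, standardCycles()[["1"]]),
                 "configuration error")
})

test_that("voxelization recovers analytic volumes and equivariance", {
    sph <- ellipsoidMesh(c(0, 0, 0), c(1, 1, 1), nTheta = 40, nPhi = 60)
    m <- voxelizeMesh(sph, spacing = rep(0.05, 3))
    vol <- sum(maskArray(m)) * prod(maskSpacing(m))
    expect_equal(vol, 4 * pi / 3, tolerance = 0.05 * 4 * pi / 3)

    ## integer-voxel translation of the mesh translates the mask
    sp <- c(0.2, 0.2, 0.2)
    m0 <- voxelizeMesh(sph, spacing = sp, origin = c(-2, -2, -2),
                       dim = c(40, 40, 40))
    shifted <- new("SurfaceMesh",
                   vertices = sweep(sph@vertices, 2, 3 * sp, "+"),
                   faces = sph@faces, structureName = "s")
    m1 <- voxelizeMesh(shifted, spacing = sp, origin = c(-2, -2, -2),
                       dim = c(40, 40, 40))
    a0 <- maskArray(m0); a1 <- maskArray(m1)
    expect_identical(a0[1:30, 1:30, 1:30], a1[4:33, 4:33, 4:33])
})

test_that("voxelization rejects bad input and warns when off-grid", {
    sph <- ellipsoidMesh(c(0, 0, 0), c(1, 1, 1), nTheta = 6, nPhi = 8)
    open <- new("SurfaceMesh", vertices = sph@vertices,
                faces = sph@faces[-1, , drop = FALSE],
                structureName = "holey")
    expect_error(voxelizeMesh(open, spacing = rep(0.5, 3)),
                 "not watertight.*closed")
    expect_warning(
        m <- voxelizeMesh(sph, spacing = rep(0.5, 3),
                          origin = c(50, 50, 50), dim = c(5, 5, 5)),
        "outside")
    expect_equal(sum(maskArray(m)), 0)
    expect_error(voxelizeMesh(sph, spacing = rep(0.5, 3),
                              origin = c(0, 0, 0), dim = c(0, 5, 5)),
                 "degenerate grid")
})
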