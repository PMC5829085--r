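## Analytic 4D thorax phantom: nested ellipsoids (torso shell, lung,
## spherical tumor) driven by sinusoidal breathing trajectories with
## exact cross-phase vertex correspondences.

#' Construct a breathing-cycle specification
#'
#' @param cycleId integer cycle label.
#' @param period breathing period T, seconds.
#' @param amplitude maximal anterior-surface AP amplitude H, mm.
#' @param tumorDiameter tumor diameter, mm.
#' @param nPhases number of phases J (default 10).
#' @return a [CycleSpec-class].
#' @examples
#' cycleSpec(1, period = 5, amplitude = 12, tumorDiameter = 30)
#' @export
cycleSpec <- function(cycleId, period, amplitude, tumorDiameter,
                      nPhases = 10L) {
    if (!is.finite(period) || period <= 0)
        stop("'period' must be positive")
    new("CycleSpec", cycleId = as.integer(cycleId), period = period,
        amplitude = amplitude, tumorDiameter = tumorDiameter,
        nPhases = as.integer(nPhases))
}

#' The five standard phantom breathing cycles
#'
#' The default simulation conditions of the phantom study: five cycles
#' with (period s, amplitude mm, tumor diameter mm) =
#' (5, 12, 30), (4.5, 10, 30), (5.5, 14, 30), (4.5, 8, 20), (6, 16, 20).
#' Cycle 1 is the modeling cycle; cycles 2-3 share the tumor diameter
#' (intra-fraction testing) and cycles 4-5 carry a shrunk tumor
#' (inter-fraction testing).
#'
#' @param nPhases phases per cycle (default 10).
#' @return named list of five [CycleSpec-class] objects ("1" .. "5").
#' @export
standardCycles <- function(nPhases = 10L) {
    pars <- list(c(5, 12, 30), c(4.5, 10, 30), c(5.5, 14, 30),
                 c(4.5, 8, 20), c(6, 16, 20))
    out <- lapply(seq_along(pars), function(i)
        cycleSpec(i, pars[[i]][1], pars[[i]][2], pars[[i]][3], nPhases))
    names(out) <- as.character(seq_along(pars))
    out
}

#' Tumor centroid breathing trajectory
#'
#' Sinusoidal tumor centroid displacement at time t within a cycle of
#' period T and surface amplitude H:
#' \deqn{ML = (H/10) \sin(2\pi/T (t - T/2))}
#' \deqn{AP = (H/10) (\sin(2\pi/T (t - T/4)) + 1)}
#' \deqn{SI = (H/2) (\sin(2\pi/T (t - T/4)) + 1)}
#' The SI excursion is largest (peak-to-peak H), AP is H/5 and ML is H/5
#' but in temporal quadrature with AP/SI: ML peaks a quarter period away
#' from the AP/SI peaks, which is the phantom's built-in inhale/exhale
#' asymmetry (hysteresis).
#'
#' @param cycle a [CycleSpec-class].
#' @param t numeric vector of times, seconds (>= 0).
#' @return numeric length(t) x 3 matrix, columns ML, AP, SI (mm).
#' @examples
#' cy <- cycleSpec(1, 5, 12, 30)
#' breathingTrajectory(cy, c(0, 1.25))
#' @export
breathingTrajectory <- function(cycle, t) {
    stopifnot(is(cycle, "CycleSpec"))
    if (any(t < 0)) stop("'t' must be non-negative")
    H <- cycle@amplitude; T <- cycle@period
    w <- 2 * pi / T
    ml <- (H / 10) * sin(w * (t - T / 2))
    ap <- (H / 10) * (sin(w * (t - T / 4)) + 1)
    si <- (H / 2) * (sin(w * (t - T / 4)) + 1)
    cbind(ML = ml, AP = ap, SI = si)
}

#' Phase sampling times of a cycle
#'
#' Phase j is sampled at t_j = (j - 1) T / J, j = 1..J.
#'
#' @param cycle a [CycleSpec-class].
#' @return numeric vector of J times, seconds.
#' @export
phaseTimes <- function(cycle) {
    stopifnot(is(cycle, "CycleSpec"))
    (seq_len(cycle@nPhases) - 1) * cycle@period / cycle@nPhases
}

#' Triangulated ellipsoid (UV sphere parameterization)
#'
#' Closed, consistently outward-oriented triangle mesh of an axis-aligned
#' ellipsoid: two pole vertices plus nTheta latitude rings of nPhi
#' vertices, triangulated with pole fans and split quads.
#'
#' @param center,semiAxes numeric length-3 (mm).
#' @param nTheta latitude rings (>= 2).
#' @param nPhi longitudes (>= 3).
#' @param structureName label for the mesh.
#' @return a [SurfaceMesh-class] with nTheta * nPhi + 2 vertices.
#' @export
ellipsoidMesh <- function(center, semiAxes, nTheta = 30L, nPhi = 50L,
                          structureName = "ellipsoid") {
    stopifnot(nTheta >= 2L, nPhi >= 3L)
    theta <- pi * seq_len(nTheta) / (nTheta + 1)
    phi <- 2 * pi * (seq_len(nPhi) - 1) / nPhi
    g <- expand.grid(phi = phi, theta = theta)   # phi fastest: ring-major
    st <- sin(g$theta)
    ring <- cbind(st * cos(g$phi), st * sin(g$phi), cos(g$theta))
    v <- rbind(c(0, 0, 1), ring, c(0, 0, -1))    # 1 = north, last = south
    v <- sweep(sweep(v, 2, semiAxes, "*"), 2, center, "+")
    np <- nPhi
    idx <- function(i, k) 1L + (i - 1L) * np + ((k - 1L) %% np) + 1L
    faces <- vector("list", 2L * nTheta * np)
    f <- 0L
    for (k in seq_len(np)) {   # north fan (ring 1)
        f <- f + 1L
        faces[[f]] <- c(1L, idx(1L, k), idx(1L, k + 1L))
    }
    for (i in seq_len(nTheta - 1L)) for (k in seq_len(np)) {
        a <- idx(i, k); b <- idx(i, k + 1L)
        c2 <- idx(i + 1L, k); d <- idx(i + 1L, k + 1L)
        f <- f + 1L; faces[[f]] <- c(a, c2, b)
        f <- f + 1L; faces[[f]] <- c(b, c2, d)
    }
    south <- nrow(v)
    for (k in seq_len(np)) {   # south fan (ring nTheta)
        f <- f + 1L
        faces[[f]] <- c(south, idx(nTheta, k + 1L), idx(nTheta, k))
    }
    new("SurfaceMesh", vertices = v,
        faces = matrix(as.integer(unlist(faces[seq_len(f)])), ncol = 3,
                       byrow = TRUE),
        structureName = structureName)
}

## ring counts giving approximately `target` vertices at a 5:3
## longitude:latitude aspect
.meshDims <- function(target) {
    nTheta <- max(2L, as.integer(round(sqrt(0.6 * target))))
    nPhi <- max(3L, as.integer(round((target - 2) / nTheta)))
    c(nTheta = nTheta, nPhi = nPhi)
}

#' Construct a phantom configuration
#'
#' Defaults place a right lung ellipsoid inside a torso shell with a
#' spherical tumor in the inferior lung, meshed at about 1500 vertices
#' per structure, voxelized at 2.0 x 2.0 x 2.5 mm. Coupling gains map
#' the tumor trajectory components onto the other structures: the
#' anterior chest wall AP excursion equals H (gain 5 on the AP
#' component, whose own peak-to-peak is H/5), tapering to zero at the
#' posterior (couch) side; the lung moves predominantly in SI with the
#' largest gain at the diaphragm.
#'
#' @param torsoCenter,torsoSemiAxes torso ellipsoid (mm).
#' @param lungCenter,lungSemiAxes lung ellipsoid (mm).
#' @param tumorCenter tumor sphere center (mm).
#' @param meshVertices approximate vertices per structure (named or
#'   single number).
#' @param spacing voxel spacing (mm).
#' @param gridMargin voxel margin around each structure's moving
#'   bounding box.
#' @param externalGainAP,externalGainSI external anterior-pole gains.
#' @param lungGainML,lungGainAP,lungGainSI lung coupling gains.
#' @param noiseSigma mesh vertex jitter SD (mm); 0 disables.
#' @param seed integer RNG seed.
#' @return a [PhantomConfig-class].
#' @export
phantomConfig <- function(torsoCenter = c(0, 0, 0),
                          torsoSemiAxes = c(170, 110, 240),
                          lungCenter = c(65, 0, 40),
                          lungSemiAxes = c(55, 70, 95),
                          tumorCenter = c(65, 10, 20),
                          meshVertices = 1500L,
                          spacing = c(2, 2, 2.5),
                          gridMargin = 2L,
                          externalGainAP = 5, externalGainSI = 0.2,
                          lungGainML = 0.1, lungGainAP = 0.25,
                          lungGainSI = 0.9,
                          noiseSigma = 0, seed = 1L) {
    if (length(meshVertices) == 1L)
        meshVertices <- c(external = meshVertices, lung = meshVertices,
                          tumor = meshVertices)
    meshVertices <- stats::setNames(as.integer(meshVertices),
                                    names(meshVertices))
    new("PhantomConfig", torsoCenter = as.numeric(torsoCenter),
        torsoSemiAxes = as.numeric(torsoSemiAxes),
        lungCenter = as.numeric(lungCenter),
        lungSemiAxes = as.numeric(lungSemiAxes),
        tumorCenter = as.numeric(tumorCenter),
        meshVertices = meshVertices,
        spacing = as.numeric(spacing), gridMargin = as.integer(gridMargin),
        externalGainAP = externalGainAP, externalGainSI = externalGainSI,
        lungGainML = lungGainML, lungGainAP = lungGainAP,
        lungGainSI = lungGainSI, noiseSigma = noiseSigma,
        seed = as.integer(seed))
}

## evaluate an expression under a private RNG stream, restoring the
## caller's stream afterwards
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

## per-vertex displacement of one structure at trajectory row `traj`
## (length-3 ML/AP/SI); gains is an M x 3 matrix of per-vertex scalar
## gains, so every structure's motion is a spatial gain field times the
## shared breathing signal
.applyGains <- function(refVertices, gains, traj) {
    refVertices + sweep(gains, 2, traj, "*")
}

.structureGains <- function(config, structure, refVertices) {
    M <- nrow(refVertices)
    switch(structure,
        tumor = matrix(1, M, 3),
        lung = {
            z <- refVertices[, 3]
            zr <- range(z)
            inf.w <- (zr[2] - z) / max(zr[2] - zr[1], 1e-9)  # 1 at base
            cbind(rep(config@lungGainML, M),
                  rep(config@lungGainAP, M),
                  config@lungGainSI * inf.w)
        },
        external = {
            y <- refVertices[, 2] - config@torsoCenter[2]
            w <- pmax(0, y / config@torsoSemiAxes[2])  # anterior weight
            cbind(rep(0, M),
                  config@externalGainAP * w,
                  config@externalGainSI * w)
        },
        stop("unknown structure: ", structure))
}

## conservative containment check of the moving tumor inside the static
## lung ellipsoid: the 6 axis-extreme sphere points at every phase
.checkTumorInLung <- function(config, cycle, times) {
    r <- cycle@tumorDiameter / 2
    traj <- breathingTrajectory(cycle, times)
    offs <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0),
                  c(0, 0, r), c(0, 0, -r))
    for (j in seq_len(nrow(traj))) {
        ctr <- config@tumorCenter + traj[j, ]
        pts <- sweep(offs, 2, ctr, "+")
        q <- sweep(pts, 2, config@lungCenter, "-")
        q <- sweep(q, 2, config@lungSemiAxes, "/")
        if (any(rowSums(q^2) > 1))
            stop("configuration error: tumor (diameter ",
                 cycle@tumorDiameter,
                 " mm) leaves the lung ellipsoid during the cycle")
    }
    invisible(TRUE)
}

#' Generate one breathing cycle of the analytic thorax phantom
#'
#' Builds the external torso surface, lung and tumor meshes at J phases
#' sampling one breathing period uniformly (phase j at t = (j-1) T / J).
#' The tumor translates rigidly along [breathingTrajectory()]; the lung
#' and external surface move by smooth per-vertex gain fields times the
#' same trajectory components, so all structures share the temporal
#' structure the correlation model assumes. External motion is largest
#' on the anterior wall and zero posteriorly (couch side). Vertex
#' correspondence across phases is exact by construction. Optional
#' Gaussian vertex jitter (emulating surface-registration error) is
#' applied to the emitted meshes only; masks are voxelized from the
#' noise-free geometry and play the role of contoured ground truth.
#'
#' @param config a [PhantomConfig-class].
#' @param cycle a [CycleSpec-class].
#' @param voxelizeMasks character subset of c("tumor", "lung") to
#'   voxelize (default both); use character(0) to skip.
#' @return a [Phantom4D-class].
#' @export
generatePhantom <- function(config, cycle,
                            voxelizeMasks = c("tumor", "lung")) {
    stopifnot(is(config, "PhantomConfig"), is(cycle, "CycleSpec"))
    validObject(config); validObject(cycle)
    times <- phaseTimes(cycle)
    .checkTumorInLung(config, cycle, times)
    traj <- breathingTrajectory(cycle, times)

    dims <- lapply(c(external = "external", lung = "lung",
                     tumor = "tumor"),
                   function(s) .meshDims(config@meshVertices[[s]]))
    refs <- list(
        external = ellipsoidMesh(config@torsoCenter, config@torsoSemiAxes,
                                 dims$external["nTheta"],
                                 dims$external["nPhi"], "external"),
        lung = ellipsoidMesh(config@lungCenter, config@lungSemiAxes,
                             dims$lung["nTheta"], dims$lung["nPhi"],
                             "lung"),
        tumor = ellipsoidMesh(config@tumorCenter,
                              rep(cycle@tumorDiameter / 2, 3),
                              dims$tumor["nTheta"], dims$tumor["nPhi"],
                              "tumor"))

    J <- cycle@nPhases
    meshes <- list(); cleanVerts <- list()
    .withSeed(config@seed + 1000L * cycle@cycleId, {
        for (s in names(refs)) {
            ref <- refs[[s]]
            gains <- .structureGains(config, s, ref@vertices)
            verts <- lapply(seq_len(J), function(j)
                .applyGains(ref@vertices, gains, traj[j, ]))
            cleanVerts[[s]] <- verts
            if (config@noiseSigma > 0)
                verts <- lapply(verts, function(v)
                    v + matrix(rnorm(length(v), sd = config@noiseSigma),
                               nrow(v), 3))
            meshes[[s]] <- new("PhaseMeshSet", structureName = s,
                               vertices = verts, faces = ref@faces)
        }
    })

    masks <- list()
    for (s in intersect(voxelizeMasks, c("tumor", "lung"))) {
        geom <- .autoGrid(cleanVerts[[s]], config@spacing,
                          config@gridMargin)
        masks[[s]] <- lapply(seq_len(J), function(j)
            voxelizeMesh(new("SurfaceMesh", vertices = cleanVerts[[s]][[j]],
                             faces = refs[[s]]@faces, structureName = s),
                         spacing = config@spacing, origin = geom$origin,
                         dim = geom$dim))
    }

    new("Phantom4D", cycle = cycle, config = config, times = times,
        meshes = meshes, masks = masks)
}

## fixed voxel grid covering all phases of one structure (one grid per
## structure per cycle, so per-phase masks share a world frame)
.autoGrid <- function(vertList, spacing, margin) {
    lo <- Reduce(pmin, lapply(vertList, function(v) apply(v, 2, min)))
    hi <- Reduce(pmax, lapply(vertList, function(v) apply(v, 2, max)))
    origin <- lo - margin * spacing
    dim <- as.integer(ceiling((hi - origin) / spacing)) + margin + 1L
    list(origin = origin, dim = dim)
}

#' Generate a full phantom study
#'
#' Convenience wrapper generating several cycles with a shared
#' configuration (the anatomy is identical across cycles up to the
#' cycle's tumor diameter).
#'
#' @param config a [PhantomConfig-class].
#' @param cycles list of [CycleSpec-class] (default [standardCycles()]).
#' @param voxelizeMasks passed to [generatePhantom()].
#' @return named list of [Phantom4D-class], names the cycle ids.
#' @export
generatePhantomStudy <- function(config = phantomConfig(),
                                 cycles = standardCycles(),
                                 voxelizeMasks = c("tumor", "lung")) {
    out <- lapply(cycles, function(cy)
        generatePhantom(config, cy, voxelizeMasks = voxelizeMasks))
    names(out) <- vapply(cycles, function(cy)
        as.character(cy@cycleId), character(1))
    out
}
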