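## Mid-position references, phasic/directional DVFs and the external
## patch grid. All DVFs are relative to the mid-position (MidP)
## reference, the per-vertex time average of the phases.

#' Mid-position reference mesh
#'
#' The per-vertex arithmetic mean of the J corresponded phase meshes:
#' the time-averaged anatomy all phasic DVFs are measured from.
#'
#' @param phases a [PhaseMeshSet-class].
#' @return a [SurfaceMesh-class].
#' @export
midpReference <- function(phases) {
    stopifnot(is(phases, "PhaseMeshSet"))
    validObject(phases)
    mid <- Reduce(`+`, phases@vertices) / length(phases@vertices)
    new("SurfaceMesh", vertices = mid, faces = phases@faces,
        structureName = phases@structureName)
}

#' Phasic deformation vector fields
#'
#' Per-vertex displacement from the mid-position reference to each
#' phase: DVF of vertex k, phase j = position(k, j) - position(k, MidP).
#' When \code{midp} is the phase mean of \code{phases}, the per-vertex
#' sum of the DVFs over phases is exactly zero.
#'
#' @param phases a [PhaseMeshSet-class].
#' @param midp reference [SurfaceMesh-class] (default
#'   \code{midpReference(phases)}).
#' @return list of J numeric M x 3 DVF matrices (mm).
#' @export
phasicDVF <- function(phases, midp = midpReference(phases)) {
    stopifnot(is(phases, "PhaseMeshSet"), is(midp, "SurfaceMesh"))
    if (nrow(midp@vertices) != nVertices(phases))
        stop("correspondence error: reference and phases differ in vertex count")
    lapply(phases@vertices, function(v) v - midp@vertices)
}

## outward vertex normals: sum of incident face normals (vectorized)
.vertexNormalsFast <- function(vertices, faces) {
    e1 <- vertices[faces[, 2], , drop = FALSE] -
        vertices[faces[, 1], , drop = FALSE]
    e2 <- vertices[faces[, 3], , drop = FALSE] -
        vertices[faces[, 1], , drop = FALSE]
    fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    vn <- matrix(0, nrow(vertices), 3)
    for (c in 1:3) {
        acc <- rowsum(fn, faces[, c])
        rows <- as.integer(rownames(acc))
        vn[rows, ] <- vn[rows, ] + acc
    }
    vn
}

#' Build the anterior external-surface patch grid
#'
#' Anterior-facing vertices (outward normal with positive AP component)
#' of the external mid-position mesh are binned into a uniform
#' rows (SI) x cols (ML) grid over the SI x ML bounding box of the
#' anterior surface. Patches are numbered row-major (SI bin first). A
#' vertex exactly on a bin boundary goes to the lower-index bin. Empty
#' patches trigger a warning and are flagged inactive; they are excluded
#' consistently from signals and models downstream.
#'
#' @param midp external mid-position [SurfaceMesh-class].
#' @param rows SI bins (default 14).
#' @param cols ML bins (default 11).
#' @return a [PatchGrid-class] with rows * cols patches.
#' @export
buildPatchGrid <- function(midp, rows = 14L, cols = 11L) {
    stopifnot(is(midp, "SurfaceMesh"), rows >= 1L, cols >= 1L)
    vn <- .vertexNormalsFast(midp@vertices, midp@faces)
    anterior <- which(vn[, 2] > 0)
    if (!length(anterior))
        stop("no anterior-facing vertices found on the external surface")
    si <- midp@vertices[anterior, 3]
    ml <- midp@vertices[anterior, 1]
    siR <- range(si); mlR <- range(ml)
    bin <- function(v, r, n) {
        if (n == 1L) return(rep(1L, length(v)))
        w <- (r[2] - r[1]) / n
        if (w <= 0) return(rep(1L, length(v)))
        ## boundary values fall to the lower-index bin
        i <- as.integer(ceiling((v - r[1]) / w))
        pmin(pmax(i, 1L), n)
    }
    rowIdx <- bin(si, siR, as.integer(rows))
    colIdx <- bin(ml, mlR, as.integer(cols))
    pid <- (rowIdx - 1L) * as.integer(cols) + colIdx
    members <- lapply(seq_len(rows * cols), function(p)
        anterior[pid == p])
    active <- lengths(members) > 0L
    if (any(!active))
        warning(sum(!active), " of ", rows * cols,
                " patches are empty and will be excluded from modeling")
    new("PatchGrid", rows = as.integer(rows), cols = as.integer(cols),
        members = members, active = active,
        anteriorVertices = as.integer(anterior),
        siRange = siR, mlRange = mlR)
}

#' Patch-averaged phasic external signal
#'
#' Averages the per-vertex external DVFs over the member vertices of
#' each active patch, per phase and per component.
#'
#' @param dvfs list of J numeric M x 3 external DVF matrices (from
#'   [phasicDVF()]).
#' @param grid a [PatchGrid-class] built on the same mesh.
#' @return an [ExternalSignal-class] with the phasic part S filled.
#' @export
patchSignal <- function(dvfs, grid) {
    stopifnot(is.list(dvfs), is(grid, "PatchGrid"))
    ids <- which(grid@active)
    J <- length(dvfs)
    S <- array(0, dim = c(length(ids), 3, J))
    for (j in seq_len(J)) {
        d <- dvfs[[j]]
        if (max(unlist(grid@members)) > nrow(d))
            stop("grid does not cover the DVF's mesh")
        S[, , j] <- t(vapply(ids, function(p)
            colMeans(d[grid@members[[p]], , drop = FALSE]),
            numeric(3)))
    }
    new("ExternalSignal", S = S, A = array(0, c(0, 0, 0)),
        patchIds = as.integer(ids))
}

#' Directional external signal
#'
#' The directional DVFs A_j = S_j - S_{j-1} capture the inhale-versus-
#' exhale asymmetry of the surface motion. The predecessor of phase 1 is
#' the last phase (breathing phases are cyclic), which makes the phase
#' sum of the A_j exactly zero by telescoping.
#'
#' @param signal an [ExternalSignal-class] with phasic S over a complete
#'   ordered phase sequence.
#' @return the signal with the A slot filled.
#' @export
directionalSignal <- function(signal) {
    stopifnot(is(signal, "ExternalSignal"))
    J <- dim(signal@S)[3]
    if (J < 2L) stop("directional DVFs need at least two phases")
    A <- array(0, dim = dim(signal@S))
    for (j in seq_len(J)) {
        prev <- if (j == 1L) J else j - 1L
        A[, , j] <- signal@S[, , j] - signal@S[, , prev]
    }
    initialize(signal, A = A)
}

#' External signal of a corresponded external mesh set
#'
#' Convenience pipeline: phasic DVFs relative to \code{midp}, patch
#' averaging, and (optionally) directional DVFs.
#'
#' @param phases external [PhaseMeshSet-class].
#' @param grid a [PatchGrid-class].
#' @param midp reference mesh the DVFs are measured from (default the
#'   phase mean).
#' @param directional also compute A (default TRUE).
#' @return an [ExternalSignal-class].
#' @export
externalSignal <- function(phases, grid, midp = midpReference(phases),
                           directional = TRUE) {
    sig <- patchSignal(phasicDVF(phases, midp), grid)
    if (directional) sig <- directionalSignal(sig)
    sig
}

#' Establish vertex correspondence with a reference mesh
#'
#' Surface registration is outside this package's scope; instead,
#' correspondence is pluggable. The built-in providers are "exact"
#' (vertex k corresponds to vertex k -- the phantom's native
#' correspondence) and "nearest" (each reference vertex takes its
#' nearest neighbor on the target, adequate for mild perturbations of
#' an already-aligned surface). A registration-backed provider can be
#' supplied as a function(target, reference) returning an index vector.
#'
#' @param target [SurfaceMesh-class] whose vertices are to be matched.
#' @param reference [SurfaceMesh-class] defining the vertex order.
#' @param method "exact", "nearest", or a function.
#' @return integer vector idx of length nVertices(reference):
#'   reference vertex k corresponds to target vertex idx[k].
#' @export
correspondVertices <- function(target, reference,
                               method = c("exact", "nearest")) {
    stopifnot(is(target, "SurfaceMesh"), is(reference, "SurfaceMesh"))
    if (is.function(method)) return(method(target, reference))
    method <- match.arg(method)
    if (method == "exact") {
        if (nVertices(target) != nVertices(reference))
            stop("exact correspondence needs equal vertex counts")
        return(seq_len(nVertices(reference)))
    }
    ## nearest neighbor, chunked to bound memory
    ref <- reference@vertices; tv <- target@vertices
    idx <- integer(nrow(ref))
    step <- 512L
    for (s in seq(1L, nrow(ref), by = step)) {
        e <- min(s + step - 1L, nrow(ref))
        d2 <- outer(rowSums(ref[s:e, , drop = FALSE]^2),
                    rowSums(tv^2), "+") -
            2 * ref[s:e, , drop = FALSE] %*% t(tv)
        idx[s:e] <- max.col(-d2, ties.method = "first")
    }
    idx
}

#' Write / read a patch grid as a structured text file
#'
#' Plain-text serialization: a header with the grid shape and ranges,
#' then one line per patch mapping the patch id to its member vertex
#' ids.
#'
#' @param grid a [PatchGrid-class].
#' @param path file path.
#' @return the path ([writePatchGrid()]) or a [PatchGrid-class]
#'   ([readPatchGrid()]).
#' @export
writePatchGrid <- function(grid, path) {
    stopifnot(is(grid, "PatchGrid"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# respicor patch grid"),
                 sprintf("rows %d", grid@rows),
                 sprintf("cols %d", grid@cols),
                 sprintf("siRange %.10g %.10g", grid@siRange[1],
                         grid@siRange[2]),
                 sprintf("mlRange %.10g %.10g", grid@mlRange[1],
                         grid@mlRange[2])), con)
    for (p in seq_along(grid@members))
        writeLines(paste(c(p, grid@members[[p]]), collapse = " "), con)
    invisible(path)
}

#' @rdname writePatchGrid
#' @export
readPatchGrid <- function(path) {
    txt <- readLines(path)
    txt <- txt[!startsWith(txt, "#")]
    kv <- strsplit(txt, "\\s+")
    rows <- as.integer(kv[[1]][2]); cols <- as.integer(kv[[2]][2])
    siR <- as.numeric(kv[[3]][2:3]); mlR <- as.numeric(kv[[4]][2:3])
    members <- lapply(kv[-(1:4)], function(x)
        as.integer(x[-1]))
    ord <- order(vapply(kv[-(1:4)], function(x) as.integer(x[1]),
                        integer(1)))
    members <- members[ord]
    new("PatchGrid", rows = rows, cols = cols, members = members,
        active = lengths(members) > 0L,
        anteriorVertices = as.integer(sort(unlist(members))),
        siRange = siR, mlRange = mlR)
}
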