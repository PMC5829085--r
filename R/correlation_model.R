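## The internal-external correlation model. A composite vector per
## phase stacks the internal DVF entries with the external phasic (and,
## for SurMod, directional) patch DVFs; PCA of the centered composite
## matrix via the small J x J Gram matrix yields an eigenbasis whose
## internal and external row blocks are correlated through
## B = E_I pinv(E_S), the operator that predicts internal DVFs from
## external observations.

#' Composite vector layout descriptor
#'
#' Describes the index structure of the composite vector d_j: the
#' internal block first (3M entries, vertex-major x, y, z), then the
#' external block with, per patch, the phasic triple followed (SurMod
#' only) by the directional triple.
#'
#' @param M internal vertex count.
#' @param N active patch count.
#' @param variant "SurMod" (external dim 6N) or "SurphaMod"/"RoiMod"
#'   (external dim 3N).
#' @return list with fields M, N, variant, dim, idxInternal,
#'   idxExternal, extPerPatch.
#' @export
compositeLayout <- function(M, N, variant) {
    variant <- match.arg(variant, c("SurMod", "SurphaMod", "RoiMod"))
    perPatch <- if (variant == "SurMod") 6L else 3L
    dim <- 3L * M + perPatch * N
    list(M = as.integer(M), N = as.integer(N), variant = variant,
         dim = dim, idxInternal = seq_len(3L * M),
         idxExternal = 3L * M + seq_len(perPatch * N),
         extPerPatch = perPatch)
}

## stack an M x 3 matrix into vertex-major [x1, y1, z1, x2, ...]
.flattenXYZ <- function(m) as.vector(t(m))

#' Compose the external part of a composite vector
#'
#' @param S numeric N x 3 phasic patch DVFs.
#' @param A numeric N x 3 directional patch DVFs, or NULL.
#' @param variant model variant.
#' @return numeric vector of length 6N (SurMod) or 3N.
#' @export
composeExternal <- function(S, A = NULL, variant = "SurMod") {
    variant <- match.arg(variant, c("SurMod", "SurphaMod", "RoiMod"))
    if (variant == "SurMod") {
        if (is.null(A))
            stop("SurMod requires directional DVFs A; supply the ",
                 "previous observation (or use the cyclic predecessor ",
                 "in phase-indexed evaluation, or an explicit zero-A ",
                 "mode)")
        .flattenXYZ(cbind(S, A))  # per patch [Sx,Sy,Sz,Ax,Ay,Az]
    } else {
        .flattenXYZ(S)
    }
}

#' Assemble the centered composite internal-external matrix
#'
#' Builds d_j for every phase, the phase mean dbar, and the centered
#' matrix D whose column j is d_j - dbar. Row sums of D are zero and
#' rank(D) <= J - 1 by centering.
#'
#' @param internalDVFs list of J numeric M x 3 internal DVF matrices.
#' @param signal an [ExternalSignal-class]; must carry directional DVFs
#'   for variant "SurMod".
#' @param variant model variant.
#' @return a [CompositeMatrix-class].
#' @export
assembleComposite <- function(internalDVFs, signal,
                              variant = c("SurMod", "SurphaMod",
                                          "RoiMod")) {
    variant <- match.arg(variant)
    stopifnot(is(signal, "ExternalSignal"))
    J <- length(internalDVFs)
    if (dim(signal@S)[3] != J)
        stop("phase count mismatch between internal DVFs (", J,
             ") and external signal (", dim(signal@S)[3], ")")
    if (variant == "SurMod" && !length(signal@A))
        stop("variant SurMod needs directional DVFs; call ",
             "directionalSignal() first")
    M <- nrow(internalDVFs[[1]]); N <- dim(signal@S)[1]
    lay <- compositeLayout(M, N, variant)
    d <- matrix(0, lay$dim, J)
    for (j in seq_len(J)) {
        A <- if (variant == "SurMod") signal@A[, , j] else NULL
        d[, j] <- c(.flattenXYZ(internalDVFs[[j]]),
                    composeExternal(signal@S[, , j], A, variant))
    }
    if (anyNA(d) || any(!is.finite(d)))
        stop("non-finite entries in the composite matrix")
    dbar <- rowMeans(d)
    new("CompositeMatrix", D = d - dbar, dbar = dbar, layout = lay)
}

#' PCA of the composite matrix via the small Gram matrix
#'
#' Eigendecomposes the J x J Gram matrix D^T D instead of the large
#' covariance D D^T: if D^T D X = lambda X then D D^T (D X) = lambda
#' (D X), so the columns of D X are the covariance eigenvectors with
#' identical nonzero eigenvalues. Columns are normalized to unit length
#' with the sign fixed so each column's largest-magnitude entry is
#' positive. Eigenpairs whose eigenvalue is numerically zero (below
#' 1e-12 of the largest) are dropped, so the retained count can be
#' smaller than K; near-degenerate retained eigenvalues trigger a
#' warning (deterministic order: descending eigenvalue, ties resolved
#' by the symmetric eigensolver's fixed output order plus the sign
#' rule).
#'
#' @param D a [CompositeMatrix-class] or numeric matrix (columns =
#'   phases).
#' @param K number of modes to keep; at most J - 1.
#' @return list with \code{values} (retained eigenvalues, descending),
#'   \code{vectors} (columns e_k, unit norm) and \code{K} (retained
#'   count).
#' @export
pcaSmall <- function(D, K = NULL) {
    if (is(D, "CompositeMatrix")) D <- D@D
    J <- ncol(D)
    if (is.null(K)) K <- J - 1L
    if (K > J - 1L)
        stop("K must be at most J - 1 = ", J - 1L)
    if (K < 1L) stop("K must be at least 1")
    eg <- eigen(crossprod(D), symmetric = TRUE)
    vals <- eg$values
    keep <- which(vals > 1e-12 * max(vals, 0))
    keep <- keep[seq_len(min(length(keep), K))]
    if (!length(keep))
        stop("composite matrix is numerically zero; nothing to model")
    vals <- vals[keep]
    if (length(vals) > 1L &&
        any(abs(diff(vals)) < 1e-9 * vals[1]))
        warning("near-degenerate eigenvalues; mode order fixed by the ",
                "deterministic tie-break")
    E <- D %*% eg$vectors[, keep, drop = FALSE]
    for (k in seq_len(ncol(E))) {
        nk <- sqrt(sum(E[, k]^2))
        E[, k] <- E[, k] / nk
        i <- which.max(abs(E[, k]))
        if (E[i, k] < 0) E[, k] <- -E[, k]
    }
    list(values = vals, vectors = E, K = length(keep))
}

#' Moore-Penrose pseudo-inverse with singular-value truncation
#'
#' @param A numeric matrix.
#' @param rtol relative truncation threshold: singular values below
#'   \code{rtol * max(sv)} are treated as zero.
#' @return the pseudo-inverse matrix.
#' @export
pinvTruncated <- function(A, rtol = 1e-10) {
    sv <- svd(A)
    keep <- sv$d > rtol * max(sv$d, 0)
    if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
    sv$v[, keep, drop = FALSE] %*%
        (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Split the eigenbasis and form the correlation operator
#'
#' Splits the eigenbasis rows into the internal block E_I (first 3M
#' rows) and the external block E_S (remaining rows), splits the mean
#' composite vector the same way, and forms the correlation operator
#' B = E_I pinv(E_S). E_S is rectangular ((6N or 3N) x K), so its
#' "inverse" is the Moore-Penrose pseudo-inverse with singular values
#' truncated at 1e-10 of the largest -- the least-squares estimate of
#' the mode weights from an external observation. A rank-deficient E_S
#' triggers a warning; the truncated pseudo-inverse regularizes it. B
#' is invariant under rescaling of the eigenbasis columns.
#'
#' @param pca result of [pcaSmall()] (or a list with \code{vectors},
#'   \code{values}).
#' @param dbar mean composite vector.
#' @param layout layout from [compositeLayout()].
#' @param K the requested mode count (recorded; the retained count is
#'   \code{pca$K}).
#' @return a [CompositeModel-class] (anatomy slots unset; see
#'   [fitCorrelationModel()]).
#' @export
splitAndCorrelate <- function(pca, dbar, layout, K = pca$K) {
    E <- pca$vectors
    if (nrow(E) != layout$dim)
        stop("layout dimension (", layout$dim,
             ") disagrees with eigenbasis rows (", nrow(E), ")")
    EI <- E[layout$idxInternal, , drop = FALSE]
    ES <- E[layout$idxExternal, , drop = FALSE]
    sv <- svd(ES)$d
    if (sum(sv > 1e-10 * max(sv, 0)) < ncol(ES))
        warning("external eigenbasis block is rank deficient; using a ",
                "truncated pseudo-inverse")
    B <- EI %*% pinvTruncated(ES, rtol = 1e-10)
    new("CompositeModel", variant = layout$variant, K = as.integer(K),
        Keff = as.integer(ncol(E)), evalues = pca$values, EI = EI,
        ES = ES, B = B, dbarI = dbar[layout$idxInternal],
        dbarS = dbar[layout$idxExternal], layout = layout,
        patchIds = integer(0), grid = NULL, midpInternal = NULL,
        midpExternal = NULL)
}

#' Select high-amplitude patches for RoiMod
#'
#' Returns the \code{count} active patches with the largest mean
#' displacement magnitude (mean over phases of the Euclidean norm of
#' the phasic patch DVF), ties broken by ascending patch id.
#'
#' @param signal an [ExternalSignal-class] of the training data.
#' @param count number of patches (default 10).
#' @return integer patch ids, sorted ascending.
#' @export
selectRoiPatches <- function(signal, count = 10L) {
    stopifnot(is(signal, "ExternalSignal"))
    N <- dim(signal@S)[1]
    if (N < count)
        stop("only ", N, " active patches available, need ", count)
    mag <- rowMeans(sqrt(apply(signal@S^2, c(1, 3), sum)))
    ord <- order(-mag, signal@patchIds)
    sort(signal@patchIds[ord[seq_len(count)]])
}

## restrict an external signal to a subset of patch ids
.subsetSignal <- function(signal, ids) {
    keep <- match(ids, signal@patchIds)
    if (anyNA(keep)) stop("patch ids not present in the signal")
    A <- if (length(signal@A))
        signal@A[keep, , , drop = FALSE] else array(0, c(0, 0, 0))
    new("ExternalSignal", S = signal@S[keep, , , drop = FALSE], A = A,
        patchIds = as.integer(ids))
}

#' Fit an internal-external correlation model
#'
#' End-to-end training: mid-position references for the internal and
#' external mesh sets, phasic internal DVFs, the external patch signal
#' (phasic, plus directional for SurMod), RoiMod patch selection when
#' requested, composite assembly, Gram-matrix PCA and the eigenbasis
#' split.
#'
#' @param internal internal-structure [PhaseMeshSet-class] (training
#'   phases).
#' @param external external-surface [PhaseMeshSet-class] (same phases).
#' @param variant model variant.
#' @param K modes to keep (default J - 1).
#' @param grid optional [PatchGrid-class]; built (14 x 11) from the
#'   external mid-position mesh when NULL.
#' @param roiCount RoiMod patch count (default 10).
#' @return a fitted [CompositeModel-class] carrying the training
#'   mid-position anatomy and patch grid.
#' @export
fitCorrelationModel <- function(internal, external,
                                variant = c("SurMod", "SurphaMod",
                                            "RoiMod"),
                                K = NULL, grid = NULL, roiCount = 10L) {
    variant <- match.arg(variant)
    stopifnot(is(internal, "PhaseMeshSet"), is(external, "PhaseMeshSet"))
    if (nPhases(internal) != nPhases(external))
        stop("internal and external phase counts differ")
    J <- nPhases(internal)
    if (is.null(K)) K <- J - 1L
    midpI <- midpReference(internal)
    midpE <- midpReference(external)
    if (is.null(grid)) grid <- buildPatchGrid(midpE)
    sig <- externalSignal(external, grid, midp = midpE,
                          directional = (variant == "SurMod"))
    if (variant == "RoiMod")
        sig <- .subsetSignal(sig, selectRoiPatches(sig, roiCount))
    comp <- assembleComposite(phasicDVF(internal, midpI), sig, variant)
    pca <- pcaSmall(comp, K = K)
    model <- splitAndCorrelate(pca, comp@dbar, comp@layout, K = K)
    initialize(model, patchIds = sig@patchIds, grid = grid,
               midpInternal = midpI, midpExternal = midpE)
}

#' Predict internal motion from an external observation
#'
#' Forms the external composite observation s(t) (phasic patch DVFs,
#' plus directional for SurMod), centers it with the model's external
#' mean, and applies the correlation operator: I(t) = B (s(t) -
#' dbar_S). The absolute predicted surface is the training (or rebased)
#' internal mid-position plus the internal mean plus the predicted DVF.
#'
#' @param model a fitted [CompositeModel-class].
#' @param S numeric N x 3 observed phasic patch DVFs on the model's
#'   patch set (relative to the model's external mid-position).
#' @param A numeric N x 3 observed directional patch DVFs (SurMod). In
#'   streaming use pass \code{S - Sprev}; in phase-indexed evaluation
#'   use the cyclic previous phase; \code{zeroA = TRUE} substitutes
#'   zeros explicitly.
#' @param zeroA logical; use a zero directional term (SurMod only).
#' @return list with \code{dvf} (M x 3 predicted internal DVF, mm) and
#'   \code{vertices} (M x 3 absolute predicted surface, mm; NULL if the
#'   model carries no anatomy).
#' @export
predictInternal <- function(model, S, A = NULL, zeroA = FALSE) {
    stopifnot(is(model, "CompositeModel"))
    if (nrow(S) != model@layout$N)
        stop("observation has ", nrow(S), " patches; model expects ",
             model@layout$N)
    if (model@variant == "SurMod" && is.null(A)) {
        if (!zeroA)
            stop("SurMod prediction needs a directional term: supply ",
                 "A = S - Sprev (streaming), the cyclic-predecessor ",
                 "difference (phase-indexed), or set zeroA = TRUE")
        A <- matrix(0, nrow(S), 3)
    }
    s <- composeExternal(S, if (model@variant == "SurMod") A else NULL,
                         model@variant)
    stilde <- s - model@dbarS
    ivec <- as.vector(model@B %*% stilde)
    dvf <- matrix(ivec, ncol = 3, byrow = TRUE)
    verts <- NULL
    if (is(model@midpInternal, "SurfaceMesh"))
        verts <- model@midpInternal@vertices +
            matrix(model@dbarI, ncol = 3, byrow = TRUE) + dvf
    list(dvf = dvf, vertices = verts)
}

#' Rebase a model to a new fraction's mid-position anatomy
#'
#' Inter-fraction update: the correlation operator B is kept, while the
#' mid-position anatomy is replaced by the new fraction's mid-position
#' meshes and the composite mean is reset to zero (observations on the
#' new fraction are measured from its own mid-position, whose phase
#' mean vanishes). This mirrors updating the model by registering the
#' treatment-day anatomy to the planning anatomy.
#'
#' @param model a fitted [CompositeModel-class].
#' @param newInternalMidp,newExternalMidp [SurfaceMesh-class]
#'   mid-position meshes of the new fraction.
#' @return the rebased model.
#' @export
rebaseModel <- function(model, newInternalMidp, newExternalMidp = NULL) {
    stopifnot(is(model, "CompositeModel"),
              is(newInternalMidp, "SurfaceMesh"))
    m <- initialize(model, midpInternal = newInternalMidp,
                    dbarI = numeric(length(model@dbarI)),
                    dbarS = numeric(length(model@dbarS)))
    if (!is.null(newExternalMidp))
        m <- initialize(m, midpExternal = newExternalMidp)
    m
}

#' Fraction of motion variance captured per mode
#'
#' @param model a [CompositeModel-class] (or [pcaSmall()] result).
#' @return numeric vector summing to at most 1 over retained modes.
#' @export
varianceExplained <- function(model) {
    v <- if (is(model, "CompositeModel")) model@evalues else model$values
    v / sum(v)
}

#' Choose the mode count from a variance fraction
#'
#' Alternative to the default K = J - 1: the smallest K whose leading
#' eigenvalues capture at least the requested fraction of the total
#' motion variance.
#'
#' @param values eigenvalues (descending), e.g. from [pcaSmall()] or
#'   [modelEigenvalues()].
#' @param varianceFraction target fraction in (0, 1], default 0.95.
#' @return integer K.
#' @export
chooseK <- function(values, varianceFraction = 0.95) {
    stopifnot(varianceFraction > 0, varianceFraction <= 1)
    cum <- cumsum(values) / sum(values)
    as.integer(which(cum >= varianceFraction - 1e-12)[1])
}
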