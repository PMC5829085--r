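## Tracking-accuracy metrics on binary volumes and boundary point sets:
## center-of-mass error, Dice coefficient, percent error, Hausdorff
## distance. Volume overlap metrics are computed on the ground-truth
## grid; a predicted mask on a different grid is first resampled to it
## by nearest neighbor.

.checkMask <- function(x, name) {
    if (!is(x, "VolumeMask")) stop("'", name, "' must be a VolumeMask")
    invisible(TRUE)
}

.sameGrid <- function(A, B) {
    identical(dim(A@mask), dim(B@mask)) &&
        isTRUE(all.equal(A@spacing, B@spacing)) &&
        isTRUE(all.equal(A@origin, B@origin))
}

#' Resample a mask to a reference grid (nearest neighbor)
#'
#' Each reference voxel takes the value of the source voxel whose
#' center is nearest to the reference voxel's world center.
#'
#' @param x source [VolumeMask-class].
#' @param ref reference [VolumeMask-class] supplying the grid.
#' @return a [VolumeMask-class] on the reference grid.
#' @export
resampleMask <- function(x, ref) {
    .checkMask(x, "x"); .checkMask(ref, "ref")
    if (.sameGrid(x, ref)) return(x)
    d <- dim(ref@mask)
    ax <- lapply(1:3, function(k) {
        world <- ref@origin[k] + (seq_len(d[k]) - 1) * ref@spacing[k]
        idx <- as.integer(round((world - x@origin[k]) / x@spacing[k])) + 1L
        idx[idx < 1L | idx > dim(x@mask)[k]] <- NA_integer_
        idx
    })
    out <- array(FALSE, d)
    ok1 <- !is.na(ax[[1]]); ok2 <- !is.na(ax[[2]]); ok3 <- !is.na(ax[[3]])
    out[ok1, ok2, ok3] <- x@mask[ax[[1]][ok1], ax[[2]][ok2], ax[[3]][ok3]]
    new("VolumeMask", mask = out, spacing = ref@spacing,
        origin = ref@origin)
}

#' Center of mass of a binary mask
#'
#' Unweighted centroid of the foreground voxel centers, world mm.
#'
#' @param mask a non-empty [VolumeMask-class].
#' @return numeric length-3 (mm).
#' @export
maskCentroid <- function(mask) {
    .checkMask(mask, "mask")
    if (!any(mask@mask)) stop("empty mask: centroid undefined")
    colMeans(maskVoxelCenters(mask))
}

#' Center-of-mass error
#'
#' 3D Euclidean distance between the mass centers of the ground-truth
#' and predicted volumes. The two masks may live on different grids as
#' long as they share the world frame.
#'
#' @param A ground-truth [VolumeMask-class].
#' @param B predicted [VolumeMask-class].
#' @return distance in mm.
#' @export
comError <- function(A, B) {
    sqrt(sum((maskCentroid(A) - maskCentroid(B))^2))
}

#' Dice coefficient
#'
#' Volume overlap 2|A n B| / (|A| + |B|) in [0, 1] (1 = perfect).
#' Computed on A's grid; B is resampled by nearest neighbor if needed.
#'
#' @param A ground-truth [VolumeMask-class].
#' @param B predicted [VolumeMask-class].
#' @return unitless in [0, 1].
#' @export
diceCoefficient <- function(A, B) {
    .checkMask(A, "A"); .checkMask(B, "B")
    B <- resampleMask(B, A)
    na <- sum(A@mask); nb <- sum(B@mask)
    if (na + nb == 0) stop("both masks are empty: Dice undefined")
    2 * sum(A@mask & B@mask) / (na + nb)
}

#' Percent error
#'
#' Mismatch normalized by the ground truth,
#' (|A u B| - |A n B|) / |A|, in [0, Inf) (0 = perfect). Not symmetric
#' in A and B.
#'
#' @param A ground-truth [VolumeMask-class] (non-empty).
#' @param B predicted [VolumeMask-class].
#' @return unitless >= 0.
#' @export
percentError <- function(A, B) {
    .checkMask(A, "A"); .checkMask(B, "B")
    if (!any(A@mask)) stop("empty ground truth: percent error undefined")
    B <- resampleMask(B, A)
    (sum(A@mask | B@mask) - sum(A@mask & B@mask)) / sum(A@mask)
}

#' Boundary points of a binary mask
#'
#' World-mm centers of the foreground voxels that have at least one
#' six-connected background neighbor (voxels on the array border count
#' as boundary).
#'
#' @param mask a non-empty [VolumeMask-class].
#' @return numeric P x 3 matrix of mm coordinates.
#' @export
maskBoundary <- function(mask) {
    .checkMask(mask, "mask")
    m <- mask@mask
    if (!any(m)) stop("empty mask: boundary undefined")
    d <- dim(m)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
    core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
          pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
          pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
          pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
          pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
          pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
    boundary <- core & !nb
    idx <- which(boundary, arr.ind = TRUE)
    sweep(sweep(idx - 1, 2, mask@spacing, "*"), 2, mask@origin, "+")
}

#' Hausdorff distance between boundary point sets
#'
#' Exact symmetric Hausdorff distance
#' max(h(A, B), h(B, A)) with h(A, B) = max over a of min over b of
#' ||a - b|| (no percentile variant). Inputs are point matrices or
#' [VolumeMask-class] objects, whose 6-connectivity boundaries are
#' extracted first (the default pathway).
#'
#' @param A,B numeric P x 3 point matrices (mm) or
#'   [VolumeMask-class] objects.
#' @return distance in mm.
#' @export
hausdorffDistance <- function(A, B) {
    toPts <- function(x) {
        if (is(x, "VolumeMask")) return(maskBoundary(x))
        x <- as.matrix(x)
        if (ncol(x) != 3 || nrow(x) < 1)
            stop("boundary points must form a non-empty P x 3 matrix")
        if (anyNA(x) || any(!is.finite(x)))
            stop("boundary points must be finite")
        x
    }
    .hausdorffCpp(toPts(A), toPts(B))
}

#' All four tracking metrics between two masks
#'
#' @param truth ground-truth [VolumeMask-class].
#' @param pred predicted [VolumeMask-class].
#' @return named numeric: com (mm), dc, pe, hd (mm).
#' @export
trackingMetrics <- function(truth, pred) {
    c(com = comError(truth, pred),
      dc = diceCoefficient(truth, pred),
      pe = percentError(truth, pred),
      hd = hausdorffDistance(truth, pred))
}
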