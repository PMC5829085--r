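## Central S4 containers. Validity methods enforce the structural
## invariants that the numerical code relies on (corresponded phases,
## positive spacings, consistent layouts).

#' Breathing-cycle simulation parameters
#'
#' One breathing cycle of the analytic thorax phantom: period \code{T}
#' (seconds), maximal anterior-surface AP amplitude \code{H} (mm), tumor
#' diameter (mm) and the number of phases \code{J} the cycle is sampled
#' into.
#'
#' @slot cycleId integer cycle label.
#' @slot period breathing period T in seconds.
#' @slot amplitude maximal AP amplitude H of the anterior surface, mm.
#' @slot tumorDiameter tumor diameter, mm.
#' @slot nPhases number of phases J the cycle is sampled into.
#' @seealso [cycleSpec()], [standardCycles()], [breathingTrajectory()]
#' @exportClass CycleSpec
setClass("CycleSpec",
    representation(cycleId = "integer", period = "numeric",
                   amplitude = "numeric", tumorDiameter = "numeric",
                   nPhases = "integer"),
    validity = function(object) {
        msg <- character()
        if (length(object@period) != 1L || !is.finite(object@period) ||
            object@period <= 0)
            msg <- c(msg, "'period' must be a single positive number")
        if (length(object@amplitude) != 1L || !is.finite(object@amplitude) ||
            object@amplitude <= 0)
            msg <- c(msg, "'amplitude' must be a single positive number")
        if (length(object@tumorDiameter) != 1L ||
            !is.finite(object@tumorDiameter) || object@tumorDiameter <= 0)
            msg <- c(msg, "'tumorDiameter' must be a single positive number")
        if (length(object@nPhases) != 1L || is.na(object@nPhases) ||
            object@nPhases < 3L)
            msg <- c(msg, "'nPhases' must be an integer >= 3")
        if (length(msg)) msg else TRUE
    })

#' Triangulated surface mesh
#'
#' A triangle mesh in world millimetres. Faces index vertices (1-based);
#' internal structures are expected to be closed, consistently oriented
#' surfaces.
#'
#' @slot vertices numeric M x 3 matrix of vertex positions (mm).
#' @slot faces integer F x 3 matrix of vertex indices.
#' @slot structureName character label (e.g. "tumor").
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
    representation(vertices = "matrix", faces = "matrix",
                   structureName = "character"),
    validity = function(object) {
        msg <- character()
        if (ncol(object@vertices) != 3L)
            msg <- c(msg, "'vertices' must have 3 columns")
        if (ncol(object@faces) != 3L)
            msg <- c(msg, "'faces' must have 3 columns")
        if (nrow(object@faces) &&
            (max(object@faces) > nrow(object@vertices) ||
             min(object@faces) < 1L))
            msg <- c(msg, "face indices out of range")
        if (anyNA(object@vertices) || any(!is.finite(object@vertices)))
            msg <- c(msg, "vertex coordinates must be finite")
        if (length(msg)) msg else TRUE
    })

#' Corresponded surface meshes across breathing phases
#'
#' The J phase meshes of one structure with exact vertex correspondence:
#' vertex k of phase j corresponds to vertex k of every other phase, and
#' all phases share one face list.
#'
#' @slot structureName character label.
#' @slot vertices list of J numeric M x 3 matrices (mm).
#' @slot faces shared integer F x 3 face matrix.
#' @exportClass PhaseMeshSet
setClass("PhaseMeshSet",
    representation(structureName = "character", vertices = "list",
                   faces = "matrix"),
    validity = function(object) {
        msg <- character()
        if (length(object@vertices) < 1L)
            msg <- c(msg, "at least one phase is required")
        nv <- vapply(object@vertices, nrow, integer(1))
        if (length(unique(nv)) > 1L)
            msg <- c(msg, "all phases must have the same vertex count")
        if (!all(vapply(object@vertices, ncol, integer(1)) == 3L))
            msg <- c(msg, "phase vertices must be M x 3 matrices")
        if (ncol(object@faces) != 3L)
            msg <- c(msg, "'faces' must have 3 columns")
        if (nrow(object@faces) && length(nv) && max(object@faces) > nv[1])
            msg <- c(msg, "face indices exceed vertex count")
        if (length(msg)) msg else TRUE
    })

#' Binary voxel mask with world geometry
#'
#' A 3D binary occupancy grid. Voxel (i, j, k) (1-based array index) has
#' world-mm center \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @slot mask logical 3D array.
#' @slot spacing numeric length-3 voxel spacing, mm.
#' @slot origin numeric length-3 world position of the first voxel
#'   center, mm.
#' @exportClass VolumeMask
setClass("VolumeMask",
    representation(mask = "array", spacing = "numeric", origin = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@mask)) != 3L)
            msg <- c(msg, "'mask' must be a 3D array")
        if (!is.logical(object@mask))
            msg <- c(msg, "'mask' must be logical")
        if (length(object@spacing) != 3L || any(object@spacing <= 0) ||
            any(!is.finite(object@spacing)))
            msg <- c(msg, "'spacing' must be 3 positive numbers")
        if (length(object@origin) != 3L || any(!is.finite(object@origin)))
            msg <- c(msg, "'origin' must be 3 finite numbers")
        if (length(msg)) msg else TRUE
    })

#' Uniform SI x ML patch grid on the anterior external surface
#'
#' Anterior-facing vertices of the external mid-position surface binned
#' into a rows (SI) x cols (ML) uniform grid. Patches are numbered
#' row-major, patch id \code{(row - 1) * cols + col}. Patches that
#' receive no vertex are flagged inactive and excluded from modeling.
#'
#' @slot rows integer, bins along SI (default 14).
#' @slot cols integer, bins along ML (default 11).
#' @slot members list of length rows * cols; integer vertex indices per
#'   patch.
#' @slot active logical vector, patch non-empty.
#' @slot anteriorVertices integer indices of the anterior-facing vertices
#'   that were binned.
#' @slot siRange,mlRange numeric length-2 bounding intervals (mm) used
#'   for binning.
#' @exportClass PatchGrid
setClass("PatchGrid",
    representation(rows = "integer", cols = "integer", members = "list",
                   active = "logical", anteriorVertices = "integer",
                   siRange = "numeric", mlRange = "numeric"),
    validity = function(object) {
        msg <- character()
        n <- object@rows * object@cols
        if (length(object@members) != n)
            msg <- c(msg, "'members' must have rows * cols entries")
        if (length(object@active) != n)
            msg <- c(msg, "'active' must have rows * cols entries")
        all.mem <- unlist(object@members, use.names = FALSE)
        if (anyDuplicated(all.mem))
            msg <- c(msg, "a vertex may belong to at most one patch")
        if (length(msg)) msg else TRUE
    })

#' Patch-averaged external surface signal
#'
#' Per-phase external surrogate signal on the active patches: the phasic
#' DVFs S_j (patch-averaged displacement from the mid-position reference
#' to phase j) and, optionally, the directional DVFs A_j = S_j - S_{j-1}
#' (cyclic predecessor at j = 1).
#'
#' @slot S numeric N x 3 x J array of phasic patch DVFs (mm).
#' @slot A numeric N x 3 x J array of directional patch DVFs, or a
#'   zero-length array when not computed.
#' @slot patchIds integer ids of the active patches (rows of S).
#' @exportClass ExternalSignal
setClass("ExternalSignal",
    representation(S = "array", A = "array", patchIds = "integer"),
    validity = function(object) {
        msg <- character()
        ds <- dim(object@S)
        if (length(ds) != 3L || ds[2] != 3L)
            msg <- c(msg, "'S' must be an N x 3 x J array")
        if (length(object@patchIds) != ds[1])
            msg <- c(msg, "'patchIds' must match the rows of S")
        if (length(object@A)) {
            if (!identical(dim(object@A), ds))
                msg <- c(msg, "'A' must have the same dimensions as 'S'")
        }
        if (length(msg)) msg else TRUE
    })

#' Centered composite internal-external motion matrix
#'
#' Column j holds the centered composite vector d_j - dbar, where d_j
#' stacks the internal DVF entries (3M, vertex-major x, y, z) followed by
#' the external block (per patch the phasic triple and, for SurMod, the
#' directional triple).
#'
#' @slot D numeric P x J centered matrix.
#' @slot dbar numeric length-P phase-mean composite vector.
#' @slot layout list describing the block structure (see
#'   [compositeLayout()]).
#' @exportClass CompositeMatrix
setClass("CompositeMatrix",
    representation(D = "matrix", dbar = "numeric", layout = "list"),
    validity = function(object) {
        msg <- character()
        if (nrow(object@D) != length(object@dbar))
            msg <- c(msg, "'dbar' length must equal nrow(D)")
        if (!is.null(object@layout$dim) &&
            object@layout$dim != nrow(object@D))
            msg <- c(msg, "layout dimension disagrees with D")
        if (length(msg)) msg else TRUE
    })

#' Fitted internal-external correlation model
#'
#' Holds the truncated eigenbasis of the composite motion matrix split
#' into internal (E_I) and external (E_S) row blocks, the correlation
#' operator B = E_I pinv(E_S), the mean composite vector split
#' accordingly, and the training mid-position anatomy needed to turn
#' predicted DVFs into absolute surfaces.
#'
#' @slot variant one of "SurMod", "SurphaMod", "RoiMod".
#' @slot K requested number of eigenmodes.
#' @slot Keff retained number of eigenmodes (numerically nonzero).
#' @slot evalues retained eigenvalues, descending.
#' @slot EI internal rows of the eigenbasis, 3M x Keff.
#' @slot ES external rows of the eigenbasis, (6N or 3N) x Keff.
#' @slot B correlation operator, 3M x (6N or 3N).
#' @slot dbarI,dbarS internal / external parts of the composite mean.
#' @slot layout composite layout descriptor.
#' @slot patchIds active patch ids the model was trained on.
#' @slot grid the [PatchGrid-class] used for the external signal.
#' @slot midpInternal training internal mid-position [SurfaceMesh-class].
#' @slot midpExternal training external mid-position [SurfaceMesh-class].
#' @exportClass CompositeModel
setClass("CompositeModel",
    representation(variant = "character", K = "integer", Keff = "integer",
                   evalues = "numeric", EI = "matrix", ES = "matrix",
                   B = "matrix", dbarI = "numeric", dbarS = "numeric",
                   layout = "list", patchIds = "integer", grid = "ANY",
                   midpInternal = "ANY", midpExternal = "ANY"),
    validity = function(object) {
        msg <- character()
        if (!object@variant %in% c("SurMod", "SurphaMod", "RoiMod"))
            msg <- c(msg, "unknown variant")
        if (length(object@evalues) &&
            any(diff(object@evalues) > 1e-12 * max(object@evalues)))
            msg <- c(msg, "eigenvalues must be in descending order")
        if (length(object@evalues) && min(object@evalues) < -1e-8)
            msg <- c(msg, "eigenvalues must be non-negative")
        if (ncol(object@EI) != object@Keff ||
            ncol(object@ES) != object@Keff)
            msg <- c(msg, "eigenbasis width must equal Keff")
        if (nrow(object@B) != nrow(object@EI) ||
            ncol(object@B) != nrow(object@ES))
            msg <- c(msg, "B must be (3M) x (external dim)")
        if (length(object@dbarI) != nrow(object@EI) ||
            length(object@dbarS) != nrow(object@ES))
            msg <- c(msg, "mean split disagrees with eigenbasis blocks")
        if (length(msg)) msg else TRUE
    })

#' Analytic 4D thorax phantom output
#'
#' One simulated breathing cycle: corresponded phase meshes for the
#' external surface, lung and tumor, plus (optionally) per-phase binary
#' masks of the internal structures, with the generating configuration
#' attached.
#'
#' @slot cycle the [CycleSpec-class] that was simulated.
#' @slot config the [PhantomConfig-class] used.
#' @slot times numeric phase times t_j (seconds).
#' @slot meshes named list of [PhaseMeshSet-class] ("external", "lung",
#'   "tumor").
#' @slot masks named list; per structure a list of J [VolumeMask-class]
#'   objects (empty when voxelization was skipped).
#' @exportClass Phantom4D
setClass("Phantom4D",
    representation(cycle = "ANY", config = "ANY", times = "numeric",
                   meshes = "list", masks = "list"))

#' Phantom geometry and coupling configuration
#'
#' Static anatomy (nested ellipsoids: torso shell, lung, spherical
#' tumor), mesh densities, voxel grid settings and the per-structure
#' coupling gains that map the breathing trajectory components onto each
#' structure's displacement field.
#'
#' @slot torsoCenter,torsoSemiAxes torso ellipsoid, mm.
#' @slot lungCenter,lungSemiAxes lung ellipsoid, mm.
#' @slot tumorCenter tumor sphere center, mm.
#' @slot meshVertices named integer: approximate vertex count per
#'   structure.
#' @slot spacing voxel spacing, mm (default 2.0 x 2.0 x 2.5).
#' @slot gridMargin voxels of margin around each structure's bounding
#'   box.
#' @slot externalGainAP,externalGainSI anterior-pole gains applied to
#'   the AP/SI trajectory components for the external surface.
#' @slot lungGainML,lungGainAP,lungGainSI lung coupling gains.
#' @slot noiseSigma per-vertex Gaussian jitter SD, mm.
#' @slot seed integer RNG seed.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
    representation(torsoCenter = "numeric", torsoSemiAxes = "numeric",
                   lungCenter = "numeric", lungSemiAxes = "numeric",
                   tumorCenter = "numeric", meshVertices = "integer",
                   spacing = "numeric", gridMargin = "integer",
                   externalGainAP = "numeric", externalGainSI = "numeric",
                   lungGainML = "numeric", lungGainAP = "numeric",
                   lungGainSI = "numeric", noiseSigma = "numeric",
                   seed = "integer"),
    validity = function(object) {
        msg <- character()
        for (nm in c("torsoCenter", "torsoSemiAxes", "lungCenter",
                     "lungSemiAxes", "tumorCenter", "spacing")) {
            v <- slot(object, nm)
            if (length(v) != 3L || any(!is.finite(v)))
                msg <- c(msg, sprintf("'%s' must be 3 finite numbers", nm))
        }
        if (any(object@spacing <= 0))
            msg <- c(msg, "'spacing' must be positive")
        if (any(object@torsoSemiAxes <= 0) || any(object@lungSemiAxes <= 0))
            msg <- c(msg, "semi-axes must be positive")
        if (any(object@meshVertices < 100L))
            msg <- c(msg, "at least 100 vertices per structure")
        gains <- c(object@externalGainAP, object@externalGainSI,
                   object@lungGainML, object@lungGainAP, object@lungGainSI)
        if (any(!is.finite(gains)))
            msg <- c(msg, "coupling gains must be finite")
        if (length(object@noiseSigma) != 1L || object@noiseSigma < 0)
            msg <- c(msg, "'noiseSigma' must be a single non-negative number")
        if (length(msg)) msg else TRUE
    })

#' Evaluation protocol description
#'
#' @slot mode one of "phantom_intra", "phantom_inter", "loo_intra",
#'   "inter_4dct".
#' @slot trainCycles,testCycles integer cycle ids (phantom modes) or
#'   fraction indices.
#' @slot variants character subset of c("RoiMod", "SurphaMod", "SurMod").
#' @slot structures character subset of c("tumor", "lung").
#' @slot K integer number of eigenmodes.
#' @slot roiCount integer number of RoiMod patches.
#' @slot seed integer seed recorded with the results.
#' @exportClass ProtocolSpec
setClass("ProtocolSpec",
    representation(mode = "character", trainCycles = "integer",
                   testCycles = "integer", variants = "character",
                   structures = "character", K = "integer",
                   roiCount = "integer", seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (!object@mode %in% c("phantom_intra", "phantom_inter",
                                "loo_intra", "inter_4dct"))
            msg <- c(msg, "unknown protocol mode")
        if (!all(object@variants %in% c("RoiMod", "SurphaMod", "SurMod")))
            msg <- c(msg, "unknown variant")
        if (object@mode %in% c("phantom_intra", "phantom_inter") &&
            length(intersect(object@trainCycles, object@testCycles)))
            msg <- c(msg, "train and test cycles must be disjoint")
        if (length(msg)) msg else TRUE
    })

#' Per-phase tracking-accuracy results
#'
#' Long-format results: one row per (variant, structure, cycle, phase,
#' metric). Summaries (mean +/- SD) are recomputed from these rows by
#' [summarizeResults()] so reported aggregates are always reproducible
#' from the stored per-phase values.
#'
#' @slot results data.frame with columns variant, structure, cycle,
#'   phase, metric, value.
#' @slot protocol the generating [ProtocolSpec-class].
#' @exportClass ResultsTable
setClass("ResultsTable",
    representation(results = "data.frame", protocol = "ANY"),
    validity = function(object) {
        need <- c("variant", "structure", "cycle", "phase", "metric",
                  "value")
        if (!all(need %in% names(object@results)))
            return(paste("results must have columns:",
                         paste(need, collapse = ", ")))
        TRUE
    })
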