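#' Number of breathing phases
#' @param x an object with phase structure.
#' @return integer phase count J.
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' Number of mesh vertices
#' @param x a mesh-bearing object.
#' @return integer vertex count M.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' Structure label
#' @param x an object carrying a structure name.
#' @return character label.
#' @export
setGeneric("structureName", function(x) standardGeneric("structureName"))

#' @describeIn nPhases phases of a corresponded mesh set.
#' @export
setMethod("nPhases", "PhaseMeshSet", function(x) length(x@vertices))

#' @describeIn nPhases phases of an external signal.
#' @export
setMethod("nPhases", "ExternalSignal", function(x) dim(x@S)[3])

#' @describeIn nPhases phases of a phantom cycle.
#' @export
setMethod("nPhases", "Phantom4D", function(x) length(x@times))

#' @describeIn nVertices vertices of a mesh.
#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))

#' @describeIn nVertices vertices per phase of a corresponded set.
#' @export
setMethod("nVertices", "PhaseMeshSet", function(x) nrow(x@vertices[[1]]))

#' @describeIn structureName label of a mesh.
#' @export
setMethod("structureName", "SurfaceMesh", function(x) x@structureName)

#' @describeIn structureName label of a corresponded mesh set.
#' @export
setMethod("structureName", "PhaseMeshSet", function(x) x@structureName)

#' Accessors for meshes, masks and models
#'
#' Small accessor family used instead of direct slot access.
#'
#' @param x the object.
#' @param phase integer phase index.
#' @name accessors
NULL

#' @rdname accessors
#' @return `meshVertices()`: numeric M x 3 vertex matrix (mm).
#' @export
meshVertices <- function(x, phase = NULL) {
    if (is(x, "SurfaceMesh")) return(x@vertices)
    if (is(x, "PhaseMeshSet")) {
        if (is.null(phase)) stop("'phase' is required for a PhaseMeshSet")
        return(x@vertices[[phase]])
    }
    stop("no vertices in an object of class ", class(x))
}

#' @rdname accessors
#' @return `meshFaces()`: integer F x 3 face matrix.
#' @export
meshFaces <- function(x) {
    if (is(x, "SurfaceMesh") || is(x, "PhaseMeshSet")) return(x@faces)
    stop("no faces in an object of class ", class(x))
}

#' @rdname accessors
#' @return `phaseMesh()`: the [SurfaceMesh-class] of one phase.
#' @export
phaseMesh <- function(x, phase) {
    stopifnot(is(x, "PhaseMeshSet"))
    new("SurfaceMesh", vertices = x@vertices[[phase]], faces = x@faces,
        structureName = x@structureName)
}

#' @rdname accessors
#' @return `maskArray()`: logical 3D array.
#' @export
maskArray <- function(x) { stopifnot(is(x, "VolumeMask")); x@mask }

#' @rdname accessors
#' @return `maskSpacing()`, `maskOrigin()`: numeric length-3 (mm).
#' @export
maskSpacing <- function(x) { stopifnot(is(x, "VolumeMask")); x@spacing }

#' @rdname accessors
#' @export
maskOrigin <- function(x) { stopifnot(is(x, "VolumeMask")); x@origin }

#' @rdname accessors
#' @return `modelVariant()`: the model variant string.
#' @export
modelVariant <- function(x) { stopifnot(is(x, "CompositeModel")); x@variant }

#' @rdname accessors
#' @return `modelOperator()`: the 3M x (6N or 3N) correlation matrix B.
#' @export
modelOperator <- function(x) { stopifnot(is(x, "CompositeModel")); x@B }

#' @rdname accessors
#' @return `modelEigenvalues()`: retained eigenvalues, descending.
#' @export
modelEigenvalues <- function(x) {
    stopifnot(is(x, "CompositeModel")); x@evalues
}

#' @rdname accessors
#' @return `resultsData()`: the long per-phase results data.frame.
#' @export
resultsData <- function(x) { stopifnot(is(x, "ResultsTable")); x@results }

setMethod("show", "CycleSpec", function(object) {
    cat(sprintf(
        "CycleSpec %d: T = %g s, H = %g mm, tumor diameter = %g mm, J = %d\n",
        object@cycleId, object@period, object@amplitude,
        object@tumorDiameter, object@nPhases))
})

setMethod("show", "SurfaceMesh", function(object) {
    cat(sprintf("SurfaceMesh '%s': %d vertices, %d faces\n",
                object@structureName, nrow(object@vertices),
                nrow(object@faces)))
})

setMethod("show", "PhaseMeshSet", function(object) {
    cat(sprintf("PhaseMeshSet '%s': %d phases x %d vertices, %d faces\n",
                object@structureName, nPhases(object), nVertices(object),
                nrow(object@faces)))
})

setMethod("show", "VolumeMask", function(object) {
    d <- dim(object@mask)
    cat(sprintf(
        "VolumeMask %d x %d x %d, spacing %g x %g x %g mm, %d foreground\n",
        d[1], d[2], d[3], object@spacing[1], object@spacing[2],
        object@spacing[3], sum(object@mask)))
})

setMethod("show", "PatchGrid", function(object) {
    cat(sprintf(
        "PatchGrid %d (SI) x %d (ML) = %d patches, %d active, %d vertices\n",
        object@rows, object@cols, object@rows * object@cols,
        sum(object@active), length(object@anteriorVertices)))
})

setMethod("show", "ExternalSignal", function(object) {
    cat(sprintf("ExternalSignal: %d patches x %d phases, directional: %s\n",
                dim(object@S)[1], dim(object@S)[3],
                if (length(object@A)) "yes" else "no"))
})

setMethod("show", "CompositeModel", function(object) {
    cat(sprintf(
        "CompositeModel [%s]: K = %d (retained %d), internal dim %d, external dim %d\n",
        object@variant, object@K, object@Keff, nrow(object@EI),
        nrow(object@ES)))
    if (length(object@evalues))
        cat("  eigenvalues:",
            paste(signif(object@evalues, 4), collapse = ", "), "\n")
})

setMethod("show", "Phantom4D", function(object) {
    cat(sprintf("Phantom4D cycle %d: %d phases, structures: %s\n",
                object@cycle@cycleId, length(object@times),
                paste(names(object@meshes), collapse = ", ")))
    if (length(object@masks))
        cat("  masks:", paste(names(object@masks), collapse = ", "), "\n")
})

setMethod("show", "ResultsTable", function(object) {
    cat(sprintf("ResultsTable: %d rows (%s)\n", nrow(object@results),
                if (is(object@protocol, "ProtocolSpec"))
                    object@protocol@mode else "custom"))
    print(utils::head(summarizeResults(object)))
})
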