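## Experimental protocols: phantom intra-fraction (train one cycle,
## test held-out cycles), phantom inter-fraction (changed period and
## tumor size, baseline re-centering), leave-one-out within one cycle,
## and two-fraction inter-4DCT evaluation.

#' Construct a protocol specification
#'
#' @param mode "phantom_intra", "phantom_inter", "loo_intra" or
#'   "inter_4dct".
#' @param trainCycles,testCycles integer cycle ids (indices into the
#'   data source). Defaults follow the phantom study design: train on
#'   cycle 1, test on cycles 2-3 (intra) or 4-5 (inter).
#' @param variants model variants to evaluate.
#' @param structures internal structures to track.
#' @param K eigenmode count (default 9 = J - 1 for J = 10).
#' @param roiCount RoiMod patch count.
#' @param seed integer recorded with the results.
#' @return a [ProtocolSpec-class].
#' @export
protocolSpec <- function(mode = c("phantom_intra", "phantom_inter",
                                  "loo_intra", "inter_4dct"),
                         trainCycles = 1L,
                         testCycles = NULL,
                         variants = c("RoiMod", "SurphaMod", "SurMod"),
                         structures = c("tumor", "lung"),
                         K = 9L, roiCount = 10L, seed = 1L) {
    mode <- match.arg(mode)
    if (is.null(testCycles))
        testCycles <- switch(mode,
            phantom_intra = c(2L, 3L),
            phantom_inter = c(4L, 5L),
            loo_intra = integer(0),
            inter_4dct = 2L)
    new("ProtocolSpec", mode = mode,
        trainCycles = as.integer(trainCycles),
        testCycles = as.integer(testCycles),
        variants = variants, structures = structures, K = as.integer(K),
        roiCount = as.integer(roiCount), seed = as.integer(seed))
}

#' Subset the phases of a corresponded mesh set
#'
#' @param x a [PhaseMeshSet-class].
#' @param phases integer phase indices to keep.
#' @return a [PhaseMeshSet-class].
#' @export
subsetPhases <- function(x, phases) {
    stopifnot(is(x, "PhaseMeshSet"))
    new("PhaseMeshSet", structureName = x@structureName,
        vertices = x@vertices[phases], faces = x@faces)
}

## external observation signal for a test mesh set, measured from a
## given external reference mesh, restricted to the model's patch set
.observedSignal <- function(model, externalTest, refMesh) {
    dvfs <- lapply(externalTest@vertices, function(v)
        v - refMesh@vertices)
    sig <- patchSignal(dvfs, model@grid)
    if (model@variant == "SurMod") sig <- directionalSignal(sig)
    if (!identical(sig@patchIds, model@patchIds))
        sig <- .subsetSignal(sig, model@patchIds)
    sig
}

## predict the requested phases of a test fraction and score them
## against the per-phase truth masks; the observed signal (and hence
## the cyclic directional term) is always built from the complete phase
## sequence. Returns a long data.frame.
.scorePhases <- function(model, externalTest, refMesh, truthMasks,
                         variant, structure, cycleLabel,
                         testPhases = seq_len(nPhases(externalTest))) {
    sig <- .observedSignal(model, externalTest, refMesh)
    rows <- vector("list", length(testPhases))
    for (i in seq_along(testPhases)) {
        j <- testPhases[i]
        A <- if (model@variant == "SurMod") sig@A[, , j] else NULL
        pred <- predictInternal(model, sig@S[, , j], A)
        truth <- truthMasks[[j]]
        predMesh <- new("SurfaceMesh", vertices = pred$vertices,
                        faces = model@midpInternal@faces,
                        structureName = structure)
        predMask <- voxelizeMesh(predMesh, spacing = truth@spacing,
                                 origin = truth@origin,
                                 dim = dim(truth@mask))
        met <- trackingMetrics(truth, predMask)
        dir.err <- abs(maskCentroid(truth) - maskCentroid(predMask))
        rows[[i]] <- data.frame(
            variant = variant, structure = structure, cycle = cycleLabel,
            phase = j,
            metric = c("com", "dc", "pe", "hd", "com_ml", "com_ap",
                       "com_si"),
            value = c(unname(met), unname(dir.err)))
    }
    do.call(rbind, rows)
}

.fitForProtocol <- function(phantom, variant, structure, spec, grid) {
    fitCorrelationModel(phantom@meshes[[structure]],
                        phantom@meshes$external, variant = variant,
                        K = spec@K, grid = grid,
                        roiCount = spec@roiCount)
}

#' Run an evaluation protocol
#'
#' Fits the requested model variants on the training data, predicts
#' internal surfaces from the external signal of every test phase,
#' voxelizes the predictions on the ground-truth grid and scores all
#' four tracking metrics (plus per-direction ML/AP/SI centroid errors).
#'
#' The data source is a named list of [Phantom4D-class] objects (cycle
#' ids as names), as produced by [generatePhantomStudy()] or read back
#' from a simulation directory.
#'
#' Protocol semantics: \code{phantom_intra} fits on the training cycle
#' and predicts test-cycle phases from external DVFs measured against
#' the training mid-position (same-fraction anatomy);
#' \code{phantom_inter} and \code{inter_4dct} first rebase the model to
#' each test fraction's own mid-position anatomy
#' (see [rebaseModel()]); \code{loo_intra} leaves one phase of the
#' training cycle out at a time, fitting on the remaining J - 1 phases.
#'
#' @param data named list of [Phantom4D-class].
#' @param spec a [ProtocolSpec-class].
#' @return a [ResultsTable-class].
#' @export
runProtocol <- function(data, spec = protocolSpec()) {
    stopifnot(is(spec, "ProtocolSpec"))
    getCycle <- function(id) {
        x <- data[[as.character(id)]]
        if (is.null(x))
            stop("protocol/data mismatch: cycle ", id,
                 " is not in the data source")
        for (s in c(spec@structures, "external"))
            if (is.null(x@meshes[[s]]))
                stop("protocol/data mismatch: cycle ", id,
                     " lacks structure '", s, "'")
        x
    }
    out <- list()
    if (spec@mode == "loo_intra") {
        ph <- getCycle(spec@trainCycles[1])
        J <- nPhases(ph)
        for (variant in spec@variants) for (s in spec@structures) {
            for (hold in seq_len(J)) {
                trainIdx <- setdiff(seq_len(J), hold)
                model <- fitCorrelationModel(
                    subsetPhases(ph@meshes[[s]], trainIdx),
                    subsetPhases(ph@meshes$external, trainIdx),
                    variant = variant, K = min(spec@K, J - 2L),
                    roiCount = spec@roiCount)
                out[[length(out) + 1L]] <- .scorePhases(
                    model, ph@meshes$external, model@midpExternal,
                    ph@masks[[s]], variant, s,
                    cycleLabel = spec@trainCycles[1],
                    testPhases = hold)
            }
        }
    } else {
        train <- getCycle(spec@trainCycles[1])
        grid <- buildPatchGrid(midpReference(train@meshes$external))
        rebase <- spec@mode %in% c("phantom_inter", "inter_4dct")
        for (variant in spec@variants) for (s in spec@structures) {
            model <- .fitForProtocol(train, variant, s, spec, grid)
            for (id in spec@testCycles) {
                test <- getCycle(id)
                if (rebase) {
                    newE <- midpReference(test@meshes$external)
                    m <- rebaseModel(model,
                                     midpReference(test@meshes[[s]]),
                                     newE)
                    ref <- newE
                } else {
                    m <- model
                    ref <- model@midpExternal
                }
                out[[length(out) + 1L]] <- .scorePhases(
                    m, test@meshes$external, ref, test@masks[[s]],
                    variant, s, cycleLabel = id)
            }
        }
    }
    new("ResultsTable", results = do.call(rbind, out), protocol = spec)
}

#' Mean and SD per (variant, structure, metric)
#'
#' Recomputed from the stored per-phase values, so the summary is
#' always reproducible from the table itself.
#'
#' @param x a [ResultsTable-class] or its long data.frame.
#' @return data.frame with columns variant, structure, metric, mean,
#'   sd, n.
#' @export
summarizeResults <- function(x) {
    df <- if (is(x, "ResultsTable")) x@results else x
    agg <- aggregate(value ~ variant + structure + metric, data = df,
                     FUN = function(v) c(mean = mean(v), sd = sd(v),
                                         n = length(v)))
    out <- data.frame(agg[, c("variant", "structure", "metric")],
                      mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                      n = agg$value[, "n"])
    out[order(out$structure, out$metric, out$variant), ]
}

#' Rank model variants per structure and metric
#'
#' Descriptive comparison (no hypothesis testing): per (structure,
#' metric) the variant means, ordered best-first. "Best" is the
#' smallest mean for error-type metrics (com, pe, hd, directional
#' errors) and the largest for Dice.
#'
#' @param x a [ResultsTable-class] (the variants must come from one
#'   protocol run) or a list of single-variant tables sharing a
#'   protocol.
#' @return data.frame with columns structure, metric, variant, mean,
#'   rank.
#' @export
compareVariants <- function(x) {
    if (is.list(x) && !is(x, "ResultsTable")) {
        protos <- lapply(x, function(t) t@protocol@mode)
        if (length(unique(unlist(protos))) > 1L)
            stop("variant tables come from different protocols")
        df <- do.call(rbind, lapply(x, resultsData))
    } else df <- resultsData(x)
    s <- summarizeResults(df)
    parts <- split(s, list(s$structure, s$metric), drop = TRUE)
    out <- do.call(rbind, lapply(parts, function(p) {
        better <- if (unique(p$metric) == "dc") -p$mean else p$mean
        p <- p[order(better, p$variant), ]
        p$rank <- seq_len(nrow(p))
        p
    }))
    rownames(out) <- NULL
    out[, c("structure", "metric", "variant", "mean", "sd", "rank")]
}

#' Render a results summary as a fixed-width text table
#'
#' @param x a [ResultsTable-class].
#' @return character vector of lines, invisibly printed.
#' @export
formatResultsTable <- function(x) {
    s <- summarizeResults(x)
    lines <- sprintf("%-10s %-8s %-7s %8.3f +/- %.3f  (n=%d)",
                     s$variant, s$structure, s$metric, s$mean, s$sd, s$n)
    header <- sprintf("%-10s %-8s %-7s %15s", "variant", "structure",
                      "metric", "mean +/- sd")
    c(header, lines)
}
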