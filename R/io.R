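## File formats: PLY (ascii and binary little-endian) and OBJ for
## meshes, NIfTI-1 for masks (via RNifti), tidy CSV for DVFs and patch
## signals, a single-file archive for fitted models, and JSON run
## manifests.

#' Write a surface mesh as PLY
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output file.
#' @param format "binary" (little-endian, default) or "ascii".
#' @return the path, invisibly.
#' @export
writePLY <- function(mesh, path, format = c("binary", "ascii")) {
    stopifnot(is(mesh, "SurfaceMesh"))
    format <- match.arg(format)
    nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
    fmt <- if (format == "binary") "binary_little_endian" else "ascii"
    header <- c("ply", paste("format", fmt, "1.0"),
                paste("element vertex", nv),
                "property double x", "property double y",
                "property double z",
                paste("element face", nf),
                "property list uchar int vertex_indices",
                "end_header")
    if (format == "ascii") {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(header, con)
        writeLines(apply(mesh@vertices, 1, paste, collapse = " "), con)
        writeLines(apply(mesh@faces - 1L, 1, function(f)
            paste(c(3L, f), collapse = " ")), con)
    } else {
        con <- file(path, "wb")
        on.exit(close(con))
        writeLines(header, con)
        writeBin(as.vector(t(mesh@vertices)), con, size = 8,
                 endian = "little")
        for (i in seq_len(nf)) {
            writeBin(as.raw(3L), con)
            writeBin(as.integer(mesh@faces[i, ] - 1L), con, size = 4,
                     endian = "little")
        }
    }
    invisible(path)
}

#' Read a PLY surface mesh
#'
#' Supports ascii and binary little-endian PLY with double or float
#' vertex properties and uchar/int face lists.
#'
#' @param path PLY file.
#' @param structureName label for the mesh (default the file stem).
#' @return a [SurfaceMesh-class].
#' @export
readPLY <- function(path, structureName = NULL) {
    if (is.null(structureName))
        structureName <- sub("\\.[^.]*$", "", basename(path))
    con <- file(path, "rb")
    on.exit(close(con))
    header <- character(); repeat {
        ln <- readLines(con, n = 1)
        header <- c(header, ln)
        if (identical(ln, "end_header")) break
        if (length(header) > 200) stop("malformed PLY header")
    }
    fmt <- sub("^format ([a-z_]+).*", "\\1",
               grep("^format", header, value = TRUE))
    nv <- as.integer(sub("^element vertex ", "",
                         grep("^element vertex", header, value = TRUE)))
    nf <- as.integer(sub("^element face ", "",
                         grep("^element face", header, value = TRUE)))
    vprops <- grep("^property (double|float)", header, value = TRUE)
    vsize <- if (grepl("double", vprops[1])) 8L else 4L
    if (fmt == "ascii") {
        txt <- readLines(con)
        vtx <- do.call(rbind, lapply(strsplit(trimws(txt[seq_len(nv)]),
                                              "\\s+"), as.numeric))
        fc <- do.call(rbind, lapply(
            strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+"),
            function(x) as.integer(x[2:4])))
    } else if (fmt == "binary_little_endian") {
        vtx <- matrix(readBin(con, "double", n = nv * length(vprops),
                              size = vsize, endian = "little"),
                      nv, length(vprops), byrow = TRUE)
        fc <- matrix(0L, nf, 3)
        for (i in seq_len(nf)) {
            cnt <- as.integer(readBin(con, "raw", n = 1))
            idx <- readBin(con, "integer", n = cnt, size = 4,
                           endian = "little")
            fc[i, ] <- idx[1:3]
        }
    } else stop("unsupported PLY format: ", fmt)
    new("SurfaceMesh", vertices = vtx[, 1:3, drop = FALSE],
        faces = fc + 1L, structureName = structureName)
}

#' Write / read a surface mesh as Wavefront OBJ
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path file path.
#' @return the path ([writeOBJ()]) or a [SurfaceMesh-class]
#'   ([readOBJ()]).
#' @export
writeOBJ <- function(mesh, path) {
    stopifnot(is(mesh, "SurfaceMesh"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.10g %.10g %.10g", mesh@vertices[, 1],
                       mesh@vertices[, 2], mesh@vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d", mesh@faces[, 1], mesh@faces[, 2],
                       mesh@faces[, 3]), con)
    invisible(path)
}

#' @rdname writeOBJ
#' @param structureName label for the mesh.
#' @export
readOBJ <- function(path, structureName = NULL) {
    if (is.null(structureName))
        structureName <- sub("\\.[^.]*$", "", basename(path))
    txt <- readLines(path)
    vl <- grep("^v ", txt, value = TRUE)
    fl <- grep("^f ", txt, value = TRUE)
    vtx <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
        as.numeric(x[2:4])))
    fc <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
        as.integer(sub("/.*", "", x[2:4]))))
    new("SurfaceMesh", vertices = vtx, faces = fc,
        structureName = structureName)
}

#' Write / read a binary mask as NIfTI-1
#'
#' Spacing is stored in the NIfTI pixdim header; the origin is stored
#' in the qform/sform translation.
#'
#' @param mask a [VolumeMask-class].
#' @param path output .nii or .nii.gz.
#' @return the path ([writeMaskNifti()]) or a [VolumeMask-class]
#'   ([readMaskNifti()]).
#' @export
writeMaskNifti <- function(mask, path) {
    stopifnot(is(mask, "VolumeMask"))
    img <- RNifti::asNifti(array(as.integer(mask@mask), dim(mask@mask)))
    RNifti::pixdim(img) <- mask@spacing
    xf <- diag(c(mask@spacing, 1))
    xf[1:3, 4] <- mask@origin
    RNifti::qform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' @rdname writeMaskNifti
#' @export
readMaskNifti <- function(path) {
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    new("VolumeMask", mask = array(as.array(img) != 0, dim(img)),
        spacing = abs(diag(xf)[1:3]), origin = xf[1:3, 4])
}

#' Write / read an external signal as tidy CSV
#'
#' Long format: columns phase, patch, component ("S" or "A"), dx, dy,
#' dz (mm).
#'
#' @param signal an [ExternalSignal-class].
#' @param path CSV path.
#' @return the path ([writeSignalCSV()]) or an [ExternalSignal-class]
#'   ([readSignalCSV()]).
#' @export
writeSignalCSV <- function(signal, path) {
    stopifnot(is(signal, "ExternalSignal"))
    J <- dim(signal@S)[3]; N <- dim(signal@S)[1]
    block <- function(arr, label) do.call(rbind, lapply(seq_len(J),
        function(j) data.frame(phase = j, patch = signal@patchIds,
                               component = label, dx = arr[, 1, j],
                               dy = arr[, 2, j], dz = arr[, 3, j])))
    df <- block(signal@S, "S")
    if (length(signal@A)) df <- rbind(df, block(signal@A, "A"))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSignalCSV
#' @export
readSignalCSV <- function(path) {
    df <- read.csv(path)
    ids <- sort(unique(df$patch))
    J <- max(df$phase)
    toArr <- function(lab) {
        sub <- df[df$component == lab, ]
        if (!nrow(sub)) return(array(0, c(0, 0, 0)))
        arr <- array(0, c(length(ids), 3, J))
        for (j in seq_len(J)) {
            pj <- sub[sub$phase == j, ]
            m <- match(ids, pj$patch)
            arr[, , j] <- as.matrix(pj[m, c("dx", "dy", "dz")])
        }
        arr
    }
    new("ExternalSignal", S = toArr("S"), A = toArr("A"),
        patchIds = as.integer(ids))
}

#' Save / load a fitted correlation model
#'
#' Single-file archive holding the full model (mean vector, eigenbasis
#' split, operator B, layout, patch grid, mid-position anatomy) plus a
#' format version string; the round trip is lossless.
#'
#' @param model a [CompositeModel-class].
#' @param path archive path (conventionally .rcm).
#' @return the path ([writeModel()]) or the model ([readModel()]).
#' @export
writeModel <- function(model, path) {
    stopifnot(is(model, "CompositeModel"))
    saveRDS(list(format = "respicor-model-1",
                 package = as.character(packageVersion("respicor")),
                 model = model), path)
    invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
    obj <- readRDS(path)
    if (!identical(obj$format, "respicor-model-1"))
        stop("not a respicor model archive: ", path)
    obj$model
}

#' Write a phantom cycle to a directory
#'
#' Layout: `<structure>_phase<jj>.ply` meshes,
#' `<structure>_phase<jj>_mask.nii.gz` masks, and `cycle.json` with the
#' cycle parameters.
#'
#' @param phantom a [Phantom4D-class].
#' @param dir output directory (created).
#' @param meshFormat "binary" or "ascii" PLY.
#' @return the directory, invisibly.
#' @export
writePhantomDir <- function(phantom, dir, meshFormat = "binary") {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    J <- nPhases(phantom)
    for (s in names(phantom@meshes)) for (j in seq_len(J))
        writePLY(phaseMesh(phantom@meshes[[s]], j),
                 file.path(dir, sprintf("%s_phase%02d.ply", s, j)),
                 format = meshFormat)
    for (s in names(phantom@masks)) for (j in seq_len(J))
        writeMaskNifti(phantom@masks[[s]][[j]],
                       file.path(dir,
                                 sprintf("%s_phase%02d_mask.nii.gz", s, j)))
    cy <- phantom@cycle
    jsonlite::write_json(
        list(cycleId = cy@cycleId, period = cy@period,
             amplitude = cy@amplitude, tumorDiameter = cy@tumorDiameter,
             nPhases = cy@nPhases, times = phantom@times),
        file.path(dir, "cycle.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Read a phantom cycle back from a directory
#'
#' Reads the meshes (and masks, when present) written by
#' [writePhantomDir()].
#'
#' @param dir directory.
#' @return a [Phantom4D-class] (config slot NULL).
#' @export
readPhantomDir <- function(dir) {
    cy <- jsonlite::read_json(file.path(dir, "cycle.json"),
                              simplifyVector = TRUE)
    cycle <- cycleSpec(cy$cycleId, cy$period, cy$amplitude,
                       cy$tumorDiameter, cy$nPhases)
    ply <- list.files(dir, pattern = "_phase[0-9]+\\.ply$")
    structures <- unique(sub("_phase[0-9]+\\.ply$", "", ply))
    meshes <- list()
    for (s in structures) {
        files <- sort(grep(paste0("^", s, "_phase"), ply, value = TRUE))
        ms <- lapply(file.path(dir, files), readPLY, structureName = s)
        meshes[[s]] <- new("PhaseMeshSet", structureName = s,
                           vertices = lapply(ms, meshVertices),
                           faces = meshFaces(ms[[1]]))
    }
    masks <- list()
    nii <- list.files(dir, pattern = "_mask\\.nii(\\.gz)?$")
    for (s in unique(sub("_phase[0-9]+_mask\\.nii(\\.gz)?$", "", nii))) {
        files <- sort(grep(paste0("^", s, "_phase"), nii, value = TRUE))
        masks[[s]] <- lapply(file.path(dir, files), readMaskNifti)
    }
    new("Phantom4D", cycle = cycle, config = NULL, times = cy$times,
        meshes = meshes, masks = masks)
}

#' Write a JSON run manifest beside an output artifact
#'
#' @param path manifest path.
#' @param command character command name.
#' @param params named list of parameters (the seed included).
#' @return the path, invisibly.
#' @export
writeManifest <- function(path, command, params) {
    jsonlite::write_json(
        list(command = command, params = params,
             package = as.character(packageVersion("respicor")),
             rversion = as.character(getRversion()),
             timestamp = format(Sys.time(), tz = "UTC",
                                "%Y-%m-%dT%H:%M:%SZ")),
        path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}
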