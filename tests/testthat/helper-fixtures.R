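## Shared fixtures, generated in code and memoized per session.

.fixtures <- new.env(parent = emptyenv())

## small phantom configuration used by the unit tests (reduced mesh
## density; geometry and gains are the package defaults)
smallConfig <- function(...) phantomConfig(meshVertices = 300L, ...)

## memoized small study over the five standard cycles
smallStudy <- function(cycles = c("1", "2", "3", "4", "5")) {
    key <- paste0("study_", paste(cycles, collapse = ""))
    if (is.null(.fixtures[[key]]))
        .fixtures[[key]] <- generatePhantomStudy(
            smallConfig(), standardCycles()[cycles])
    .fixtures[[key]]
}

## a tiny corresponded two-structure mesh-set pair built from one
## cycle (internal tumor + external surface)
smallCyclePair <- function(id = "1") {
    ph <- smallStudy(id)[[id]]
    list(internal = ph@meshes$tumor, external = ph@meshes$external,
         phantom = ph)
}

## VolumeMask from a logical/0-1 array
maskFrom <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    new("VolumeMask", mask = array(as.logical(arr), dim(arr)),
        spacing = spacing, origin = origin)
}

## random blob mask on a small grid (deterministic given seed)
randomBlob <- function(dim = c(8, 8, 8), p = 0.4, seed = 1,
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    set.seed(seed)
    maskFrom(array(runif(prod(dim)) < p, dim), spacing, origin)
}

## brute-force metric oracles (independent per-voxel / per-pair loops)
oracleCentroid <- function(mask) {
    m <- maskArray(mask); d <- dim(m)
    s <- c(0, 0, 0); n <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
        for (k in seq_len(d[3])) if (m[i, j, k]) {
            s <- s + maskOrigin(mask) + (c(i, j, k) - 1) * maskSpacing(mask)
            n <- n + 1
        }
    s / n
}

oracleDice <- function(A, B) {
    a <- maskArray(A); b <- maskArray(B)
    2 * sum(a & b) / (sum(a) + sum(b))
}

oraclePE <- function(A, B) {
    a <- maskArray(A); b <- maskArray(B)
    (sum(a | b) - sum(a & b)) / sum(a)
}

oracleHausdorff <- function(P, Q) {
    h <- function(X, Y) {
        worst <- 0
        for (i in seq_len(nrow(X))) {
            best <- Inf
            for (j in seq_len(nrow(Y)))
                best <- min(best, sqrt(sum((X[i, ] - Y[j, ])^2)))
            worst <- max(worst, best)
        }
        worst
    }
    max(h(P, Q), h(Q, P))
}
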