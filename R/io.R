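#' @include AllClasses.R network.R
NULL

#' Save a network to Matrix Market + TSV
#'
#' Writes the weight matrix as a Matrix Market coordinate file (1-based
#' indices, real entries; entry `(i, j)` is the weight of the synapse
#' `j -> i`) and the neuron metadata (index, layer, x, y) as a TSV with
#' header.  Synapses depressed to weight zero are preserved as explicit zero
#' entries, so the stored pattern is the adjacency support.
#'
#' @param network a [SpikingNetwork-class].
#' @param basename output path prefix; `<basename>.mtx` and
#'   `<basename>_neurons.tsv` are written.
#' @return The two file paths, invisibly.
#' @importFrom Matrix writeMM sparseMatrix
#' @importFrom utils write.table read.delim
#' @export
saveNetwork <- function(network, basename) {
    stopifnot(is(network, "SpikingNetwork"))
    n <- nNeurons(network)
    m <- Matrix::sparseMatrix(i = network@post, j = network@pre,
                              x = network@weight, dims = c(n, n), repr = "T")
    mtx <- paste0(basename, ".mtx")
    tsv <- paste0(basename, "_neurons.tsv")
    Matrix::writeMM(m, mtx)
    utils::write.table(
        data.frame(index = seq_len(n), layer = network@layer,
                   x = network@positions[, 1], y = network@positions[, 2]),
        tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(mtx, tsv))
}

#' Load a network from Matrix Market + TSV
#'
#' Lossless inverse of [saveNetwork()]: reconstructs adjacency (including
#' explicit zero-weight synapses), weights, positions and layer labels.  The
#' geometry is recovered from the layer labels and position grid.
#'
#' @param basename path prefix used by [saveNetwork()].
#' @return A [SpikingNetwork-class].
#' @importFrom Matrix readMM
#' @export
loadNetwork <- function(basename) {
    mtx <- paste0(basename, ".mtx")
    tsv <- paste0(basename, "_neurons.tsv")
    if (!file.exists(mtx)) stop("missing weight matrix file: ", mtx)
    if (!file.exists(tsv)) stop("missing neuron metadata file: ", tsv)
    header <- readLines(mtx, n = 1)
    if (!grepl("^%%MatrixMarket +matrix +coordinate", header))
        stop("not a Matrix Market coordinate file: ", mtx,
             " (header: ", header, ")")
    m <- methods::as(Matrix::readMM(mtx), "TsparseMatrix")
    meta <- utils::read.delim(tsv)
    if (!identical(names(meta), c("index", "layer", "x", "y")))
        stop("neuron metadata must have columns index, layer, x, y")
    n <- nrow(meta)
    if (any(dim(m) != n))
        stop(sprintf("dimension mismatch: matrix is %d x %d but metadata has %d neurons",
                     nrow(m), ncol(m), n))
    geometry <- geometryConfig(max(meta$layer),
                               sum(meta$layer == meta$layer[1]))
    pre <- m@j + 1L; post <- m@i + 1L
    o <- order(pre, post)
    new("SpikingNetwork", geometry = geometry,
        positions = cbind(x = meta$x, y = meta$y),
        layer = as.integer(meta$layer),
        pre = as.integer(pre[o]), post = as.integer(post[o]),
        weight = as.numeric(m@x[o]), wMax = 1)
}

#' Save a spike raster as TSV
#'
#' Columns `neuron_id` (1-based) and `time_ms` (fixed 4 decimal places).
#'
#' @param raster a [SpikeRaster-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveRaster <- function(raster, path) {
    stopifnot(is(raster, "SpikeRaster"))
    utils::write.table(
        data.frame(neuron_id = raster@neuron,
                   time_ms = sprintf("%.4f", raster@time)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
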