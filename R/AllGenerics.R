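#' @include AllClasses.R
NULL

#' Number of neurons
#' @param x a [SpikingNetwork-class] or [SpikeRaster-class].
#' @return Integer count.
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' Number of layers
#' @param x a [SpikingNetwork-class] or [GeometryConfig-class].
#' @return Integer count.
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' Layer index of each neuron
#' @param x a [SpikingNetwork-class].
#' @return Integer vector, 1-based, left to right.
#' @export
setGeneric("layerOf", function(x) standardGeneric("layerOf"))

#' Neuron positions
#' @param x a [SpikingNetwork-class].
#' @return `n x 2` matrix of unit-square coordinates.
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' Synapse table
#' @param x a [SpikingNetwork-class].
#' @return `data.frame` with columns `pre`, `post`, `weight` and `class`
#'   (feedforward / feedback / recurrent).
#' @export
setGeneric("synapses", function(x) standardGeneric("synapses"))

#' Sparse weight matrix
#'
#' Entry `(i, j)` holds the weight of the synapse from neuron `j` to neuron
#' `i`.  Synapses whose weight has been depressed to zero are kept as
#' explicit zero entries: the adjacency support is the stored pattern, not
#' the non-zero pattern.
#' @param x a [SpikingNetwork-class].
#' @return A `dgCMatrix`.
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname nNeurons
setMethod("nNeurons", "SpikingNetwork", function(x) nrow(x@positions))

#' @rdname nNeurons
setMethod("nNeurons", "SpikeRaster", function(x) x@nNeurons)

#' @rdname nLayers
setMethod("nLayers", "SpikingNetwork", function(x) x@geometry@nLayers)

#' @rdname nLayers
setMethod("nLayers", "GeometryConfig", function(x) x@nLayers)

#' @rdname layerOf
setMethod("layerOf", "SpikingNetwork", function(x) x@layer)

#' @rdname positions
setMethod("positions", "SpikingNetwork", function(x) x@positions)

#' @rdname synapses
setMethod("synapses", "SpikingNetwork", function(x) {
    data.frame(pre = x@pre, post = x@post, weight = x@weight,
               class = classifySynapse(x))
})

#' @rdname weightMatrix
#' @importFrom Matrix sparseMatrix
setMethod("weightMatrix", "SpikingNetwork", function(x) {
    n <- nNeurons(x)
    m <- Matrix::sparseMatrix(i = x@post, j = x@pre, x = x@weight,
                              dims = c(n, n), repr = "T")
    methods::as(m, "CsparseMatrix")
})

setMethod("show", "SpikingNetwork", function(object) {
    cl <- classifySynapse(object)
    cat(sprintf("SpikingNetwork: %d neurons (%d layers x %d), %d synapses\n",
                nNeurons(object), object@geometry@nLayers,
                object@geometry@perLayer, length(object@pre)))
    if (length(cl)) {
        tb <- table(cl)
        cat(sprintf("  feedforward %d | feedback %d | recurrent %d\n",
                    tb[["feedforward"]], tb[["feedback"]], tb[["recurrent"]]))
        cat(sprintf("  mean weight %.4f (range %.4f-%.4f)\n",
                    mean(object@weight), min(object@weight),
                    max(object@weight)))
    }
    invisible(object)
})

setMethod("show", "SpikeRaster", function(object) {
    cat(sprintf("SpikeRaster: %d spikes from %d neurons over %.1f ms\n",
                length(object@neuron), object@nNeurons, object@duration))
    invisible(object)
})

setMethod("show", "ExponentialFit", function(object) {
    cat(sprintf(
        "ExponentialFit: y = %.4g * exp(-x / %.4g)  (R^2 = %.4f, n = %d%s)\n",
        object@amplitude, object@lambda, object@rSquared, object@nPoints,
        if (object@valid) "" else ", INVALID"))
    invisible(object)
})

#' @describeIn SpikeRaster-class number of spike events.
#' @param x a `SpikeRaster`.
#' @export
setMethod("length", "SpikeRaster", function(x) length(x@neuron))

#' Coerce a spike raster to a data frame
#' @param x a [SpikeRaster-class].
#' @param ... ignored.
#' @return `data.frame` with columns `neuron` and `time`.
#' @export
as.data.frame.SpikeRaster <- function(x, ...) {
    data.frame(neuron = x@neuron, time = x@time)
}
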