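#' @include AllClasses.R
NULL

#' Place neurons on the layered lattice
#'
#' Layer `l` of `nLayers` is the vertical column at `x = (l - 0.5)/nLayers`;
#' row `r` of `perLayer` sits at `y = (r - 0.5)/perLayer`.  Global indices run
#' left to right by layer.
#'
#' @param geometry a [GeometryConfig-class].
#' @return List with `positions` (`n x 2` matrix) and `layer` (integer
#'   vector).
#' @examples
#' buildLattice(geometryConfig(2, 1))$positions
#' @export
buildLattice <- function(geometry) {
    stopifnot(is(geometry, "GeometryConfig"))
    validObject(geometry)
    nl <- geometry@nLayers
    pl <- geometry@perLayer
    layer <- rep(seq_len(nl), each = pl)
    row <- rep(seq_len(pl), times = nl)
    pos <- cbind(x = (layer - 0.5) / nl, y = (row - 0.5) / pl)
    list(positions = pos, layer = layer)
}

#' Distance-dependent connection probability
#'
#' `p(d) = k * exp(-d / lambdaC)`, clamped to `[0, 1]`.  Any
#' monotone-decreasing kernel could stand here; the exponential form follows
#' the spatial-growth connectivity convention.
#'
#' @param d distance(s) in side-length units, `>= 0`.
#' @param connectivity a [ConnectivityConfig-class].
#' @return Probabilities in `[0, 1]`, vectorised over `d`.
#' @examples
#' connectionProbability(0, connectivityConfig(k = 0.2))       # 0.2
#' connectionProbability(0.1, connectivityConfig(k = 0.2))     # 0.2 / e
#' @export
connectionProbability <- function(d, connectivity = connectivityConfig()) {
    stopifnot(is(connectivity, "ConnectivityConfig"))
    if (any(d < 0)) stop("distances must be non-negative")
    pmin(1, pmax(0, connectivity@k * exp(-d / connectivity@lambdaC)))
}

#' Generate a spatial spiking network
#'
#' Draws one Bernoulli variable per unordered neuron pair with probability
#' [connectionProbability()] of the pair distance; a success creates both
#' directed synapses with independent uniform initial weights.  Deterministic
#' given `seed`.
#'
#' @param geometry a [GeometryConfig-class].
#' @param connectivity a [ConnectivityConfig-class].
#' @param seed integer RNG seed.
#' @return A [SpikingNetwork-class].
#' @examples
#' net <- generateNetwork(geometryConfig(5, 4), seed = 1)
#' net
#' @export
generateNetwork <- function(geometry = geometryConfig(),
                            connectivity = connectivityConfig(),
                            seed = 1L) {
    stopifnot(is(geometry, "GeometryConfig"),
              is(connectivity, "ConnectivityConfig"))
    validObject(geometry); validObject(connectivity)
    lat <- buildLattice(geometry)
    n <- nrow(lat$positions)

    ## all unordered pairs (i < j), vectorised
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dx <- lat$positions[ij[, 1], 1] - lat$positions[ij[, 2], 1]
    dy <- lat$positions[ij[, 1], 2] - lat$positions[ij[, 2], 2]
    p <- connectionProbability(sqrt(dx * dx + dy * dy), connectivity)

    set.seed(as.integer(seed))
    keep <- stats::runif(length(p)) < p
    a <- ij[keep, 1]; b <- ij[keep, 2]
    pre <- c(a, b); post <- c(b, a)
    w <- stats::runif(length(pre), connectivity@wInitLow,
                      connectivity@wInitHigh)
    o <- order(pre, post)
    new("SpikingNetwork", geometry = geometry, positions = lat$positions,
        layer = lat$layer, pre = as.integer(pre[o]),
        post = as.integer(post[o]), weight = w[o], wMax = 1)
}

#' Classify synapses by training direction
#'
#' A synapse is feedforward when its presynaptic layer lies left of its
#' postsynaptic layer (the training direction), feedback when right of it,
#' and recurrent when both neurons share a layer.
#'
#' @param network a [SpikingNetwork-class].
#' @param pre,post optional neuron indices; when supplied, the single
#'   `pre -> post` synapse direction is classified instead of the network's
#'   full synapse list.
#' @return Factor with levels `feedforward`, `feedback`, `recurrent`.
#' @examples
#' net <- makeFixture("three_layer_mini")
#' table(classifySynapse(net))
#' classifySynapse(net, pre = 1, post = 9)   # layer 1 -> layer 3
#' @export
classifySynapse <- function(network, pre = NULL, post = NULL) {
    stopifnot(is(network, "SpikingNetwork"))
    if (is.null(pre) != is.null(post))
        stop("supply both pre and post, or neither")
    if (is.null(pre)) { pre <- network@pre; post <- network@post }
    n <- nNeurons(network)
    if (any(pre < 1 | pre > n | post < 1 | post > n))
        stop("unknown neuron index")
    lp <- network@layer[pre]; lq <- network@layer[post]
    factor(ifelse(lp < lq, "feedforward",
                  ifelse(lp > lq, "feedback", "recurrent")),
           levels = c("feedforward", "feedback", "recurrent"))
}

#' Remove a connection class from a network
#'
#' Returns a copy with the named class's synapses removed from the support
#' entirely (not merely zeroed).  Idempotent.
#'
#' @param network a [SpikingNetwork-class].
#' @param drop one of `"feedback"`, `"recurrent"`, `"both"`.
#' @return The ablated [SpikingNetwork-class].
#' @export
ablate <- function(network, drop = c("feedback", "recurrent", "both")) {
    drop <- match.arg(drop)
    cl <- classifySynapse(network)
    kill <- if (drop == "both") cl %in% c("feedback", "recurrent")
            else cl == drop
    keep <- !kill
    methods::initialize(network, pre = network@pre[keep],
                        post = network@post[keep],
                        weight = network@weight[keep])
}

## Expected undirected edge count by exhaustive pair enumeration; used for
## generator checks and the monotonicity property.
expectedEdgeCount <- function(geometry, connectivity) {
    lat <- buildLattice(geometry)
    ij <- which(upper.tri(diag(nrow(lat$positions))), arr.ind = TRUE)
    dx <- lat$positions[ij[, 1], 1] - lat$positions[ij[, 2], 1]
    dy <- lat$positions[ij[, 1], 2] - lat$positions[ij[, 2], 2]
    p <- connectionProbability(sqrt(dx * dx + dy * dy), connectivity)
    c(mean = sum(p), sd = sqrt(sum(p * (1 - p))))
}

## Internal: replace the weight vector (used by training wrappers).
setWeights <- function(network, w) {
    methods::initialize(network, weight = w)
}
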