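#' @include AllClasses.R network.R
NULL

#' Deterministic miniature networks for examples and tests
#'
#' * `two_neuron`: two layers of one neuron each, reciprocal synapses with
#'   weights 0.5 — the minimal pre/post pair.
#' * `three_layer_mini`: 3 layers x 3 neurons with full (all-pairs)
#'   adjacency and weights 0.5.
#' * `saturated_chain`: 6 layers x 3 neurons, adjacent-layer and intra-layer
#'   all-pairs adjacency with feedforward weights at the upper bound,
#'   feedback at the lower bound and recurrent at the upper bound — the
#'   fully trained regime.
#'
#' The same name always returns an identical object.
#'
#' @param name fixture name.
#' @return A [SpikingNetwork-class].
#' @examples
#' makeFixture("two_neuron")
#' @export
makeFixture <- function(name = c("two_neuron", "three_layer_mini",
                                 "saturated_chain")) {
    name <- match.arg(name)
    fullPairs <- function(n) {
        ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
        list(pre = c(ij[, 1], ij[, 2]), post = c(ij[, 2], ij[, 1]))
    }
    if (name == "two_neuron") {
        geometry <- geometryConfig(2, 1)
        lat <- buildLattice(geometry)
        return(new("SpikingNetwork", geometry = geometry,
                   positions = lat$positions, layer = lat$layer,
                   pre = c(1L, 2L), post = c(2L, 1L),
                   weight = c(0.5, 0.5), wMax = 1))
    }
    if (name == "three_layer_mini") {
        geometry <- geometryConfig(3, 3)
        lat <- buildLattice(geometry)
        e <- fullPairs(9)
        o <- order(e$pre, e$post)
        return(new("SpikingNetwork", geometry = geometry,
                   positions = lat$positions, layer = lat$layer,
                   pre = as.integer(e$pre[o]), post = as.integer(e$post[o]),
                   weight = rep(0.5, length(o)), wMax = 1))
    }
    ## saturated_chain
    geometry <- geometryConfig(6, 3)
    lat <- buildLattice(geometry)
    n <- 6L * 3L
    ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- abs(lat$layer[ij[, 1]] - lat$layer[ij[, 2]]) <= 1L
    ij <- ij[keep, , drop = FALSE]
    pre <- c(ij[, 1], ij[, 2]); post <- c(ij[, 2], ij[, 1])
    dl <- lat$layer[post] - lat$layer[pre]
    w <- ifelse(dl > 0, 1, ifelse(dl < 0, 0, 1))
    o <- order(pre, post)
    new("SpikingNetwork", geometry = geometry, positions = lat$positions,
        layer = lat$layer, pre = as.integer(pre[o]),
        post = as.integer(post[o]), weight = as.numeric(w[o]), wMax = 1)
}
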