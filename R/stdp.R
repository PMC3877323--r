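#' @include AllClasses.R
NULL

#' STDP weight-change kernel
#'
#' Exponential nearest-spike pair rule as a function of the post-minus-pre
#' spike-time difference `deltaT`:
#' `+aPlus * exp(-deltaT/tauPlus)` for `deltaT > 0`,
#' `-aMinus * exp(+deltaT/tauMinus)` for `deltaT < 0`, and `+aPlus` at
#' `deltaT = 0` (synchronous spikes potentiate both reciprocal synapses:
#' synchronous intra-layer firing is what drives the strong growth of
#' recurrent weights).
#'
#' @param deltaT spike-time difference `t_post - t_pre`, ms (vectorised).
#' @param params a [StdpParams-class].
#' @return Weight change(s), unclipped.
#' @examples
#' stdpKernel(c(20, -20), stdpParams())   # +0.1/e, -0.1/e
#' @export
stdpKernel <- function(deltaT, params = stdpParams()) {
    stopifnot(is(params, "StdpParams"))
    if (any(!is.finite(deltaT))) stop("deltaT must be finite")
    ifelse(deltaT >= 0,
           params@aPlus * exp(-deltaT / params@tauPlus),
           -params@aMinus * exp(deltaT / params@tauMinus))
}

#' Clip a weight into the hard bounds
#'
#' @param w weight(s), finite.
#' @param params a [StdpParams-class] supplying `wMin`, `wMax`.
#' @return `min(max(w, wMin), wMax)`.
#' @export
clipWeight <- function(w, params = stdpParams()) {
    stopifnot(is(params, "StdpParams"))
    if (any(!is.finite(w))) stop("weights must be finite")
    pmin(params@wMax, pmax(params@wMin, w))
}

#' Apply STDP updates for one spiking neuron
#'
#' Implements the on-spike update used inside the simulator, exposed at the R
#' level: when neuron `i` fires at time `t`, every existing incoming synapse
#' `j -> i` whose presynaptic `j` has a recorded last spike is potentiated by
#' `stdpKernel(t - t_j)`, and every outgoing synapse `i -> j` whose
#' postsynaptic `j` has a recorded last spike is depressed by
#' `stdpKernel(t_j - t)`.  Only the most recent partner spike is used
#' (nearest-spike rule) and each updated weight is clipped into
#' `[wMin, wMax]`.
#'
#' @param network a [SpikingNetwork-class].
#' @param i index of the firing neuron.
#' @param t spike time, ms; must not precede any recorded last spike.
#' @param lastSpike numeric vector of most recent spike times (`-Inf` =
#'   never fired).
#' @param params a [StdpParams-class].
#' @return The network with updated weights.
#' @examples
#' net <- makeFixture("two_neuron")
#' net <- applyOnSpike(net, i = 2, t = 10, lastSpike = c(0, -Inf))
#' synapses(net)
#' @export
applyOnSpike <- function(network, i, t, lastSpike, params = stdpParams()) {
    stopifnot(is(network, "SpikingNetwork"), is(params, "StdpParams"))
    i <- as.integer(i)
    if (i < 1L || i > nNeurons(network)) stop("unknown neuron index")
    if (length(lastSpike) != nNeurons(network))
        stop("lastSpike must have one entry per neuron")
    if (any(lastSpike[is.finite(lastSpike)] > t + 1e-9))
        stop("t must not precede recorded last-spike times")
    w <- network@weight

    inc <- which(network@post == i)
    jin <- network@pre[inc]
    has <- is.finite(lastSpike[jin])
    if (any(has)) {
        e <- inc[has]
        w[e] <- clipWeight(w[e] + stdpKernel(t - lastSpike[jin[has]], params),
                           params)
    }
    out <- which(network@pre == i)
    jout <- network@post[out]
    has <- is.finite(lastSpike[jout])
    if (any(has)) {
        e <- out[has]
        w[e] <- clipWeight(w[e] + stdpKernel(lastSpike[jout[has]] - t, params),
                           params)
    }
    setWeights(network, w)
}
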