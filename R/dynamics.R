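#' @include AllClasses.R network.R
NULL

#' Alpha-function conductance kernel
#'
#' `0` for `s < 0` and `(s/tauAlpha) * exp(1 - s/tauAlpha)` for `s >= 0`;
#' the peak value is 1 at `s = tauAlpha`.
#'
#' @param s time since the presynaptic spike, ms (vectorised).
#' @param tauAlpha alpha time constant, ms.
#' @return Unitless conductance factor.
#' @examples
#' alphaKernel(c(0, 2, 4), tauAlpha = 2)   # 0, 1, 2/e
#' @export
alphaKernel <- function(s, tauAlpha = 2) {
    ifelse(s < 0, 0, (s / tauAlpha) * exp(1 - s / tauAlpha))
}

#' One piecewise-constant stimulus segment
#'
#' Describes a constant current `amplitude` (voltage-equivalent mV) delivered
#' to a set of neurons over `[start, end)` ms.  Target neurons may be named
#' directly or as whole layers (resolved against the network at run time).
#'
#' @param start,end segment interval in ms, `start < end`.
#' @param amplitude current amplitude, mV.
#' @param neurons integer neuron indices, or `NULL`.
#' @param layers integer layer indices, or `NULL`.
#' @return A stimulus segment (plain list) for [runSimulation()].
#' @export
stimulusSegment <- function(start, end, amplitude, neurons = NULL,
                            layers = NULL) {
    if (!is.finite(amplitude)) stop("amplitude must be finite")
    if (!(is.finite(start) && is.finite(end) && start < end))
        stop("need finite start < end")
    if (is.null(neurons) && is.null(layers))
        stop("supply target neurons or layers")
    structure(list(start = start, end = end, amplitude = amplitude,
                   neurons = neurons, layers = layers),
              class = "stimulusSegment")
}

resolveSegments <- function(stimulus, network) {
    lapply(stimulus, function(seg) {
        stopifnot(inherits(seg, "stimulusSegment"))
        idx <- seg$neurons
        if (!is.null(seg$layers))
            idx <- c(idx, which(network@layer %in% seg$layers))
        idx <- sort(unique(as.integer(idx)))
        if (any(idx < 1L | idx > nNeurons(network)))
            stop("stimulus segment targets unknown neurons")
        list(neurons = idx - 1L, start = seg$start, end = seg$end,
             amplitude = seg$amplitude)
    })
}

## Incoming/outgoing synapse indices in the 0-based CSR-like layout the C++
## core expects; recomputed per call (cheap relative to integration).
edgeIndex <- function(network) {
    n <- nNeurons(network)
    m <- length(network@pre)
    inOrd <- order(network@post, network@pre)
    outOrd <- order(network@pre, network@post)
    inPtr <- c(0L, cumsum(tabulate(network@post, nbins = n)))
    outPtr <- c(0L, cumsum(tabulate(network@pre, nbins = n)))
    list(in_ptr = as.integer(inPtr), in_idx = as.integer(inOrd - 1L),
         out_ptr = as.integer(outPtr), out_idx = as.integer(outOrd - 1L),
         pre0 = network@pre - 1L, post0 = network@post - 1L, m = m)
}

#' Run a clock-driven simulation
#'
#' Integrates the network for `duration` ms from `state` under a stimulus
#' program, recording every spike.  With `plasticity` supplied, nearest-spike
#' STDP updates are applied at the moment of each spike (before the next
#' step's voltages are computed) and the returned network carries the evolved
#' weights.  Fully deterministic for identical inputs.
#'
#' @param network a [SpikingNetwork-class].
#' @param duration simulated time, ms (> 0).
#' @param stimulus list of [stimulusSegment()] entries (possibly empty).
#' @param state a [SimulationState-class]; defaults to rest.
#' @param neuron,synapse neuron and synapse parameter objects.
#' @param plasticity a [StdpParams-class] to enable STDP, or `NULL` to freeze
#'   weights.
#' @param dt integration step, ms (default 0.1).
#' @param .ei precomputed edge index (internal; callers that run many short
#'   simulations on one network pass it to skip recomputation).
#' @return List with `raster` ([SpikeRaster-class]), `state` (final
#'   [SimulationState-class]) and `network` (input network, with evolved
#'   weights when plastic).
#' @examples
#' net <- makeFixture("two_neuron")
#' out <- runSimulation(net, duration = 20,
#'     stimulus = list(stimulusSegment(0, 5, 80, neurons = 1)))
#' as.data.frame(out$raster)
#' @export
runSimulation <- function(network, duration,
                          stimulus = list(),
                          state = restingState(network, neuron),
                          neuron = neuronParams(),
                          synapse = synapseParams(),
                          plasticity = NULL,
                          dt = 0.1, .ei = NULL) {
    stopifnot(is(network, "SpikingNetwork"), is(neuron, "NeuronParams"),
              is(synapse, "SynapseParams"), is(state, "SimulationState"))
    if (duration <= 0) stop("duration must be positive")
    if (dt <= 0) stop("dt must be positive")
    plastic <- !is.null(plasticity)
    if (plastic) stopifnot(is(plasticity, "StdpParams"))
    sp <- if (plastic) plasticity else stdpParams()
    segs <- resolveSegments(stimulus, network)
    ei <- if (is.null(.ei)) edgeIndex(network) else .ei
    ls <- state@lastSpike
    ls[!is.finite(ls)] <- -1e30

    out <- lif_simulate_cpp(
        n = nNeurons(network),
        edge_pre = ei$pre0, edge_post = ei$post0,
        w = as.numeric(network@weight),
        in_ptr = ei$in_ptr, in_idx = ei$in_idx,
        out_ptr = ei$out_ptr, out_idx = ei$out_idx,
        v = as.numeric(state@v), x = as.numeric(state@x),
        s = as.numeric(state@s), last_spike = as.numeric(ls),
        t0 = state@t, duration = duration, dt = dt,
        tau_m = neuron@tauM, v_rest = neuron@vRest, v_th = neuron@vTh,
        e_ex = neuron@eEx, g = synapse@g, tau_alpha = synapse@tauAlpha,
        stim_neurons = lapply(segs, `[[`, "neurons"),
        stim_start = vapply(segs, `[[`, numeric(1), "start"),
        stim_end = vapply(segs, `[[`, numeric(1), "end"),
        stim_amp = vapply(segs, `[[`, numeric(1), "amplitude"),
        plastic = plastic,
        a_plus = sp@aPlus, a_minus = sp@aMinus,
        tau_plus = sp@tauPlus, tau_minus = sp@tauMinus,
        w_min = sp@wMin, w_max = sp@wMax)

    lastSpike <- out$last_spike
    lastSpike[lastSpike < -1e29] <- -Inf
    newState <- new("SimulationState", v = out$v, x = out$x, s = out$s,
                    lastSpike = lastSpike, t = out$t)
    net <- if (plastic) setWeights(network, out$w) else network
    list(raster = spikeRaster(out$spike_neuron, out$spike_time,
                              nNeurons(network), duration),
         state = newState, network = net)
}
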