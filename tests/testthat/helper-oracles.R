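# Shared helpers: independent oracles and forced-spike drivers.

# Event-driven recomputation of the nearest-spike STDP rule on full spike
# lists, independent of the clock-driven simulator.  `times` is a list of
# per-neuron spike-time vectors; synapses are walked in time order, with all
# spikes at one time treated as synchronous (reciprocal potentiation a_plus).
stdpWalkOracle <- function(network, times, params) {
    w <- network@weight
    last <- rep(-Inf, nNeurons(network))
    ev <- data.frame(neuron = rep(seq_along(times), lengths(times)),
                     time = unlist(times))
    ev <- ev[order(ev$time), , drop = FALSE]
    for (t in unique(ev$time)) {
        F <- ev$neuron[ev$time == t]
        for (i in F) {
            inc <- which(network@post == i)
            for (e in inc) {
                j <- network@pre[e]
                dw <- if (j %in% F) params@aPlus
                      else if (is.finite(last[j]))
                          params@aPlus * exp(-(t - last[j]) / params@tauPlus)
                      else next
                w[e] <- min(params@wMax, max(params@wMin, w[e] + dw))
            }
            out <- which(network@pre == i)
            for (e in out) {
                j <- network@post[e]
                if (j %in% F) next
                if (is.finite(last[j])) {
                    dw <- -params@aMinus *
                        exp(-(t - last[j]) / params@tauMinus)
                    w[e] <- min(params@wMax, max(params@wMin, w[e] + dw))
                }
            }
        }
        last[F] <- t
    }
    w
}

# Force each neuron to spike at the scheduled times (on the dt grid) by
# one-step suprathreshold pulses; g = 0 decouples the voltage dynamics so
# spike times are exact, while plasticity still sees the spikes.
forcedSpikeRun <- function(network, times, params, dt = 0.1) {
    segs <- list()
    for (i in seq_along(times)) {
        for (t in times[[i]]) {
            segs[[length(segs) + 1L]] <-
                stimulusSegment(t - dt, t, 1e5, neurons = i)
        }
    }
    out <- runSimulation(network, duration = max(unlist(times)) + 1,
                         stimulus = segs,
                         synapse = synapseParams(g = 0),
                         plasticity = params, dt = dt)
    sched <- sort(unlist(times))
    got <- sort(out$raster@time)
    stopifnot(length(sched) == length(got), max(abs(sched - got)) < 1e-6)
    out$network
}

# Reduced-size study configuration used across acceptance checks.
scaledConfig <- function(seed = 1L) defaultConfig("scaled", seed = seed)
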