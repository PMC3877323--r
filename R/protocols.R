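#' @include AllClasses.R dynamics.R
NULL

#' Calibrate the training pulse amplitude
#'
#' Finds the smallest amplitude on a grid that makes every neuron of each
#' stimulated layer fire at least once within the pulse duration `tD`, then
#' verifies that at the chosen amplitude a pulse into any layer causes no
#' spikes outside that layer at the network's current weights (the training
#' current must not recruit other layers).  The grid starts at the closed-form
#' single-neuron threshold `(vTh - vRest) / (1 - exp(-tD/tauM))`, below which
#' an isolated neuron cannot reach threshold within the pulse.
#'
#' @param network a [SpikingNetwork-class].
#' @param tD pulse duration, ms.
#' @param neuron,synapse dynamics parameters.
#' @param dt integration step, ms.
#' @param gridStep amplitude grid resolution, mV.
#' @param maxAmp give up above this amplitude.
#' @param checkWindow time simulated past the pulse when checking for
#'   off-layer spikes, ms.
#' @return The calibrated amplitude (mV).
#' @export
calibrateStimulus <- function(network, tD = 5, neuron = neuronParams(),
                              synapse = synapseParams(), dt = 0.1,
                              gridStep = 1, maxAmp = 1000,
                              checkWindow = 20) {
    stopifnot(is(network, "SpikingNetwork"))
    floorAmp <- (neuron@vTh - neuron@vRest) / (1 - exp(-tD / neuron@tauM))
    amp <- ceiling(floorAmp / gridStep) * gridStep
    layers <- seq_len(nLayers(network))
    repeat {
        if (amp > maxAmp)
            stop("stimulus calibration failed: no amplitude <= ", maxAmp,
                 " mV drives every stimulated neuron to fire within tD")
        ok <- TRUE
        for (l in layers) {
            members <- which(network@layer == l)
            out <- runSimulation(network, duration = tD + checkWindow,
                                 stimulus = list(stimulusSegment(0, tD, amp,
                                                                 layers = l)),
                                 neuron = neuron, synapse = synapse, dt = dt)
            sp <- out$raster
            inLayer <- sp@neuron %in% members
            fired <- unique(sp@neuron[inLayer & sp@time <= tD + 1e-9])
            if (length(fired) < length(members)) { ok <- FALSE; break }
            if (any(!inLayer))
                stop(sprintf(paste0(
                    "stimulus calibration failed: amplitude %.1f mV into ",
                    "layer %d recruits %d off-layer spike(s)"),
                    amp, l, sum(!inLayer)))
        }
        if (ok) return(amp)
        amp <- amp + gridStep
    }
}

#' Train one layer pair
#'
#' Simulates a single asynchronous stimulation trial with plasticity on: a
#' pulse into layer `l` for `tD` ms, a gap of `deltaT` ms, the same pulse
#' into layer `l + 1`, then a settling window of at least ten alpha time
#' constants.  Afterwards all membrane and synaptic state (including the
#' spike-time memory) is reset to rest, standing in for the long recovery
#' period between trials; weights persist.
#'
#' @param network a [SpikingNetwork-class].
#' @param pair index `l` of the left layer, `1 <= l <= nLayers - 1`.
#' @param protocol a [TrainingProtocol-class] with a concrete `iS`.
#' @param neuron,synapse,stdp dynamics and plasticity parameters.
#' @param dt integration step, ms.
#' @param .ei precomputed edge index (internal).
#' @return List with `network` (updated weights) and `raster` (the trial's
#'   spikes).
#' @export
trainPair <- function(network, pair, protocol = trainingProtocol(),
                      neuron = neuronParams(), synapse = synapseParams(),
                      stdp = stdpParams(), dt = 0.1, .ei = NULL) {
    stopifnot(is(network, "SpikingNetwork"), is(protocol, "TrainingProtocol"))
    if (is.na(protocol@iS))
        stop("protocol@iS is NA; calibrate first (see calibrateStimulus)")
    l <- as.integer(pair)
    if (l < 1L || l > nLayers(network) - 1L)
        stop("pair must name a left layer between 1 and nLayers - 1")
    tD <- protocol@tD; gap <- protocol@deltaT
    settle <- max(protocol@settle, 10 * synapse@tauAlpha)
    duration <- tD + gap + tD + settle
    stim <- list(
        stimulusSegment(0, tD, protocol@iS, layers = l),
        stimulusSegment(tD + gap, tD + gap + tD, protocol@iS, layers = l + 1L))
    out <- runSimulation(network, duration = duration, stimulus = stim,
                         neuron = neuron, synapse = synapse,
                         plasticity = stdp, dt = dt, .ei = .ei)
    for (ll in c(l, l + 1L)) {
        members <- which(network@layer == ll)
        if (!all(members %in% out$raster@neuron))
            stop(sprintf(paste0("stimulated layer %d failed to spike in ",
                                "full (amplitude %.1f mV miscalibrated)"),
                         ll, protocol@iS))
    }
    list(network = out$network, raster = out$raster)
}

#' Train the whole network
#'
#' Executes `nTrials` sweeps over the adjacent layer pairs
#' `(1,2), (2,3), ..., (nLayers-1, nLayers)` in left-to-right order (one
#' sweep = one trial per pair) and records the mean weight per connection
#' class after every sweep.  When `protocol@iS` is `NA` the amplitude is
#' calibrated once with [calibrateStimulus()] before training.
#'
#' @inheritParams trainPair
#' @param protocol a [TrainingProtocol-class].
#' @return List with `network` (trained), `trajectory` (`data.frame` of
#'   per-sweep class mean weights) and `iS` (the amplitude used).
#' @export
trainNetwork <- function(network, protocol = trainingProtocol(),
                         neuron = neuronParams(), synapse = synapseParams(),
                         stdp = stdpParams(), dt = 0.1) {
    stopifnot(is(network, "SpikingNetwork"), is(protocol, "TrainingProtocol"))
    if (is.na(protocol@iS)) {
        iS <- calibrateStimulus(network, tD = protocol@tD, neuron = neuron,
                                synapse = synapse, dt = dt)
        protocol@iS <- iS
    } else iS <- protocol@iS
    ei <- edgeIndex(network)
    cl <- classifySynapse(network)
    classMeans <- function(net) tapply(net@weight, cl, mean)
    traj <- list(data.frame(sweep = 0L, t(classMeans(network))))
    nPairs <- nLayers(network) - 1L
    if (protocol@nTrials > 0L) {
        for (sweep in seq_len(protocol@nTrials)) {
            for (l in seq_len(nPairs)) {
                network <- trainPair(network, l, protocol, neuron, synapse,
                                     stdp, dt, .ei = ei)$network
            }
            traj[[sweep + 1L]] <- data.frame(sweep = sweep,
                                             t(classMeans(network)))
        }
    }
    trajectory <- do.call(rbind, traj)
    names(trajectory) <- c("sweep", "feedforward", "feedback", "recurrent")
    list(network = network, trajectory = trajectory, iS = iS)
}

#' Test signal propagation in a (trained) network
#'
#' Injects a steady current into the target layer for `tTest` ms with
#' plasticity frozen and counts spikes per layer.  The propagation count `S`
#' is the total number of spikes emitted by all layers to the right of the
#' target during the window.
#'
#' @param network a [SpikingNetwork-class].
#' @param protocol a [TestProtocol-class]; an `NA` amplitude is replaced by
#'   three times the calibrated training amplitude.
#' @param neuron,synapse dynamics parameters.
#' @param dt integration step, ms.
#' @return List with `raster`, `S`, `perLayer` (spike count per layer) and
#'   `iT` (the amplitude used).
#' @export
testPropagation <- function(network, protocol = testProtocol(),
                            neuron = neuronParams(),
                            synapse = synapseParams(), dt = 0.1) {
    stopifnot(is(network, "SpikingNetwork"), is(protocol, "TestProtocol"))
    if (protocol@targetLayer > nLayers(network))
        stop("targetLayer exceeds the number of layers")
    iT <- protocol@iT
    if (is.na(iT))
        iT <- 3 * calibrateStimulus(network, neuron = neuron,
                                    synapse = synapse, dt = dt)
    out <- runSimulation(network, duration = protocol@tTest,
                         stimulus = list(stimulusSegment(0, protocol@tTest,
                                                         iT,
                                                         layers = protocol@targetLayer)),
                         neuron = neuron, synapse = synapse, dt = dt)
    spikeLayers <- network@layer[out$raster@neuron]
    perLayer <- tabulate(spikeLayers, nbins = nLayers(network))
    names(perLayer) <- seq_len(nLayers(network))
    list(raster = out$raster,
         S = sum(perLayer[seq_len(nLayers(network)) > protocol@targetLayer]),
         perLayer = perLayer, iT = iT)
}
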