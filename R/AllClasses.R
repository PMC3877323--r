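#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib stdpnet, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Lattice geometry of the layered network
#'
#' Neurons sit on a two-dimensional lattice inside the unit square, organised
#' as `nLayers` vertical layers of `perLayer` neurons each.  Global neuron
#' indices run left to right by layer, so layer `l` holds neurons
#' `(l-1)*perLayer + 1` to `l*perLayer`.
#'
#' @slot nLayers number of layers (>= 2; the stimulation protocol needs at
#'   least one layer pair).
#' @slot perLayer neurons per layer (>= 1).
#' @slot side side length of the square; all distances are expressed in units
#'   of the side, which is fixed at 1.
#' @export
setClass("GeometryConfig",
    representation(nLayers = "integer", perLayer = "integer", side = "numeric"),
    prototype(nLayers = 50L, perLayer = 20L, side = 1))

setValidity("GeometryConfig", function(object) {
    if (length(object@nLayers) != 1L || is.na(object@nLayers) || object@nLayers < 2L)
        return("nLayers must be a single integer >= 2")
    if (length(object@perLayer) != 1L || is.na(object@perLayer) || object@perLayer < 1L)
        return("perLayer must be a single integer >= 1")
    if (!identical(object@side, 1)) return("side is fixed at 1")
    TRUE
})

#' @param nLayers,perLayer,side see the corresponding slots.
#' @return A validated `GeometryConfig`.
#' @rdname GeometryConfig-class
#' @examples
#' geometryConfig(3, 4)
#' @export
geometryConfig <- function(nLayers = 50, perLayer = 20, side = 1) {
    new("GeometryConfig", nLayers = as.integer(nLayers),
        perLayer = as.integer(perLayer), side = as.numeric(side))
}

#' Distance-dependent connectivity parameters
#'
#' Each unordered pair of neurons at distance `d` (in side-length units) is
#' connected with probability `k * exp(-d / lambdaC)`, clamped to `[0, 1]`.
#' A connected pair receives both directed synapses, each with an independent
#' uniform initial weight on `[wInitLow, wInitHigh]`.
#'
#' @slot k connection-probability scale in `[0, 1]`.
#' @slot lambdaC spatial decay length of the connection probability, in
#'   side-length units (> 0).
#' @slot wInitLow,wInitHigh range of the uniform initial weights,
#'   `0 <= wInitLow < wInitHigh <= 1`.
#' @export
setClass("ConnectivityConfig",
    representation(k = "numeric", lambdaC = "numeric",
                   wInitLow = "numeric", wInitHigh = "numeric"),
    prototype(k = 0.2, lambdaC = 0.1, wInitLow = 0, wInitHigh = 1))

setValidity("ConnectivityConfig", function(object) {
    if (object@k < 0 || object@k > 1) return("k must lie in [0, 1]")
    if (object@lambdaC <= 0) return("lambdaC must be positive")
    if (object@wInitLow < 0 || object@wInitLow >= object@wInitHigh ||
        object@wInitHigh > 1)
        return("initial weights need 0 <= wInitLow < wInitHigh <= 1")
    TRUE
})

#' @param k,lambdaC,wInitLow,wInitHigh see the corresponding slots.
#' @return A validated `ConnectivityConfig`.
#' @rdname ConnectivityConfig-class
#' @examples
#' connectivityConfig(k = 0.2, lambdaC = 0.1)
#' @export
connectivityConfig <- function(k = 0.2, lambdaC = 0.1,
                               wInitLow = 0, wInitHigh = 1) {
    new("ConnectivityConfig", k = k, lambdaC = lambdaC,
        wInitLow = wInitLow, wInitHigh = wInitHigh)
}

#' Integrate-and-fire neuron parameters
#'
#' Membrane dynamics follow
#' `tau_m dV/dt = (V_rest - V) + g_syn(t) (E_ex - V) + I(t)`
#' with currents in voltage-equivalent units (membrane resistance folded in).
#' When `V` reaches `vTh` the neuron spikes and is reset to `vRest`; there is
#' no refractory period.  Defaults follow standard V1-cell modelling
#' conventions.
#'
#' @slot tauM membrane time constant, ms.
#' @slot vRest resting potential, mV.
#' @slot vTh firing threshold, mV.
#' @slot eEx excitatory reversal potential, mV.
#' @export
setClass("NeuronParams",
    representation(tauM = "numeric", vRest = "numeric", vTh = "numeric",
                   eEx = "numeric"),
    prototype(tauM = 20, vRest = -70, vTh = -54, eEx = 0))

setValidity("NeuronParams", function(object) {
    if (object@tauM <= 0) return("tauM must be positive")
    if (!(object@vRest < object@vTh && object@vTh < object@eEx))
        return("need vRest < vTh < eEx")
    TRUE
})

#' @param tauM,vRest,vTh,eEx see the corresponding slots.
#' @return A validated `NeuronParams`.
#' @rdname NeuronParams-class
#' @export
neuronParams <- function(tauM = 20, vRest = -70, vTh = -54, eEx = 0) {
    new("NeuronParams", tauM = tauM, vRest = vRest, vTh = vTh, eEx = eEx)
}

#' Alpha-function synapse parameters
#'
#' Each presynaptic spike launches a conductance transient
#' `(s/tauAlpha) exp(1 - s/tauAlpha)` that peaks at 1 one time constant after
#' the spike; transients from successive spikes superpose.  `g` scales the
#' summed weighted conductance in the membrane equation.
#'
#' @slot g constant synaptic conductance scale (dimensionless, >= 0).
#' @slot tauAlpha alpha-function time constant, ms (> 0).
#' @export
setClass("SynapseParams",
    representation(g = "numeric", tauAlpha = "numeric"),
    prototype(g = 0.06, tauAlpha = 2))

setValidity("SynapseParams", function(object) {
    if (object@g < 0) return("g must be non-negative")
    if (object@tauAlpha <= 0) return("tauAlpha must be positive")
    TRUE
})

#' @param g,tauAlpha see the corresponding slots.
#' @return A validated `SynapseParams`.
#' @rdname SynapseParams-class
#' @export
synapseParams <- function(g = 0.06, tauAlpha = 2) {
    new("SynapseParams", g = g, tauAlpha = tauAlpha)
}

#' STDP rule parameters
#'
#' Nearest-spike pair-based STDP: when the postsynaptic side of a synapse
#' spikes, only the most recent spike of the partner contributes.  The weight
#' change is `+aPlus * exp(-dt/tauPlus)` for post-after-pre lag `dt > 0`,
#' `-aMinus * exp(dt/tauMinus)` for `dt < 0`, and `+aPlus` for synchronous
#' spikes.  Weights are clipped into `[wMin, wMax]` after every update (hard
#' bounds).  The rule is temporally symmetric when `aPlus == aMinus` and
#' `tauPlus == tauMinus`, temporally asymmetric otherwise.
#'
#' @slot aPlus potentiation amplitude per pairing (weight units).
#' @slot aMinus depression amplitude per pairing.
#' @slot tauPlus potentiation time constant, ms.
#' @slot tauMinus depression time constant, ms.
#' @slot wMax,wMin hard bounds on weights (fixed 1 and 0).
#' @export
setClass("StdpParams",
    representation(aPlus = "numeric", aMinus = "numeric", tauPlus = "numeric",
                   tauMinus = "numeric", wMax = "numeric", wMin = "numeric"),
    prototype(aPlus = 0.1, aMinus = 0.1, tauPlus = 20, tauMinus = 20,
              wMax = 1, wMin = 0))

setValidity("StdpParams", function(object) {
    if (object@aPlus < 0 || object@aMinus < 0)
        return("amplitudes must be non-negative")
    if (object@tauPlus <= 0 || object@tauMinus <= 0)
        return("time constants must be positive")
    if (object@wMin >= object@wMax) return("need wMin < wMax")
    TRUE
})

#' @param aPlus,aMinus,tauPlus,tauMinus,wMax,wMin see the corresponding slots.
#' @return A validated `StdpParams`.
#' @rdname StdpParams-class
#' @examples
#' stdpParams()                                  # temporally symmetric
#' stdpParams(aMinus = 0.105, tauMinus = 40)     # temporally asymmetric
#' @export
stdpParams <- function(aPlus = 0.1, aMinus = 0.1, tauPlus = 20,
                       tauMinus = 20, wMax = 1, wMin = 0) {
    new("StdpParams", aPlus = aPlus, aMinus = aMinus, tauPlus = tauPlus,
        tauMinus = tauMinus, wMax = wMax, wMin = wMin)
}

#' Is an STDP rule temporally symmetric?
#'
#' Method for [base::isSymmetric()]: `TRUE` when amplitudes and time
#' constants are equal across the potentiation and depression branches.
#' @param object a [StdpParams-class] object.
#' @param ... ignored.
#' @return Logical scalar.
#' @export
isSymmetric.StdpParams <- function(object, ...) {
    object@aPlus == object@aMinus && object@tauPlus == object@tauMinus
}

#' Paired-layer training protocol
#'
#' One training trial for layer pair `(l, l+1)`: a pulse of amplitude `iS`
#' into layer `l` for `tD` ms, a gap of `deltaT` ms (measured from pulse
#' offset to next onset), the same pulse into layer `l+1`, then a settling
#' window after which all membrane and synaptic state is reset to rest
#' (weights persist).  One sweep trains every adjacent pair left to right;
#' `nTrials` sweeps are run.
#'
#' @slot iS pulse amplitude, voltage-equivalent mV; `NA` means calibrate with
#'   [calibrateStimulus()] (smallest grid amplitude that makes every neuron of
#'   a stimulated layer fire within `tD` without off-layer spikes).
#' @slot tD pulse duration, ms.
#' @slot deltaT inter-stimulus interval (offset-to-onset gap), ms.
#' @slot nTrials number of sweeps over all adjacent pairs.
#' @slot settle quiescence window after the second pulse before the state
#'   reset, ms (defaults to ten alpha time constants).
#' @export
setClass("TrainingProtocol",
    representation(iS = "numeric", tD = "numeric", deltaT = "numeric",
                   nTrials = "integer", settle = "numeric"),
    prototype(iS = NA_real_, tD = 5, deltaT = 0, nTrials = 20L, settle = 20))

setValidity("TrainingProtocol", function(object) {
    if (!is.na(object@iS) && object@iS <= 0) return("iS must be positive")
    if (object@tD <= 0) return("tD must be positive")
    if (object@deltaT < 0) return("deltaT must be non-negative")
    if (object@nTrials < 0L) return("nTrials must be non-negative")
    if (object@settle < 0) return("settle must be non-negative")
    TRUE
})

#' @param iS,tD,deltaT,nTrials,settle see the corresponding slots.
#' @return A validated `TrainingProtocol`.
#' @rdname TrainingProtocol-class
#' @export
trainingProtocol <- function(iS = NA_real_, tD = 5, deltaT = 0, nTrials = 20,
                             settle = 20) {
    new("TrainingProtocol", iS = as.numeric(iS), tD = tD, deltaT = deltaT,
        nTrials = as.integer(nTrials), settle = settle)
}

#' Propagation test protocol
#'
#' A steady current `iT` is injected into `targetLayer` for `tTest` ms with
#' plasticity frozen; the propagation count `S` is the total number of spikes
#' emitted by all layers to the right of the target during the window.
#'
#' @slot iT steady current amplitude, voltage-equivalent mV; `NA` means use
#'   three times the calibrated training amplitude (the smallest integer
#'   multiple at which a fully trained reference network propagates).
#' @slot targetLayer stimulated layer (default 3).
#' @slot tTest test duration, ms.
#' @export
setClass("TestProtocol",
    representation(iT = "numeric", targetLayer = "integer", tTest = "numeric"),
    prototype(iT = NA_real_, targetLayer = 3L, tTest = 200))

setValidity("TestProtocol", function(object) {
    if (!is.na(object@iT) && object@iT <= 0) return("iT must be positive")
    if (object@targetLayer < 1L) return("targetLayer must be >= 1")
    if (object@tTest <= 0) return("tTest must be positive")
    TRUE
})

#' @param iT,targetLayer,tTest see the corresponding slots.
#' @return A validated `TestProtocol`.
#' @rdname TestProtocol-class
#' @export
testProtocol <- function(iT = NA_real_, targetLayer = 3, tTest = 200) {
    new("TestProtocol", iT = as.numeric(iT),
        targetLayer = as.integer(targetLayer), tTest = tTest)
}

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Spatial spiking network
#'
#' The central container evolved by STDP: lattice positions, layer labels and
#' a directed synapse list with bounded weights.  Generated networks have
#' symmetric support as an undirected relation (both directed synapses exist
#' for every connected pair, with independent weights); [ablate()] may remove
#' one direction.  Synapses are stored as a parallel edge list sorted by
#' `(pre, post)`; `NULL`-free accessors are provided ([synapses()],
#' [weightMatrix()], [layerOf()], [positions()]).
#'
#' @slot geometry the [GeometryConfig-class].
#' @slot positions `n x 2` matrix of `(x, y)` coordinates in the unit square.
#' @slot layer integer layer index per neuron (1-based, left to right).
#' @slot pre,post integer presynaptic / postsynaptic neuron per synapse.
#' @slot weight numeric synaptic weight per synapse, in `[0, wMax]`.
#' @slot wMax upper hard bound carried with the network (default 1).
#' @export
setClass("SpikingNetwork",
    representation(geometry = "GeometryConfig", positions = "matrix",
                   layer = "integer", pre = "integer", post = "integer",
                   weight = "numeric", wMax = "numeric"),
    prototype(wMax = 1))

setValidity("SpikingNetwork", function(object) {
    n <- nrow(object@positions)
    if (length(object@layer) != n) return("layer/positions length mismatch")
    m <- length(object@pre)
    if (length(object@post) != m || length(object@weight) != m)
        return("pre/post/weight must have equal length")
    if (m > 0) {
        if (any(object@pre < 1L | object@pre > n | object@post < 1L |
                object@post > n))
            return("synapse endpoints out of range")
        if (any(object@pre == object@post)) return("self-loops are not allowed")
        if (any(object@weight < 0 | object@weight > object@wMax))
            return("weights must lie in [0, wMax]")
    }
    TRUE
})

#' Spike raster
#'
#' Ordered list of spike events `(neuron, time)` produced by a simulation.
#'
#' @slot neuron integer neuron indices (1-based).
#' @slot time spike times in ms, non-decreasing.
#' @slot nNeurons number of neurons in the simulated network.
#' @slot duration length of the simulated window, ms.
#' @export
setClass("SpikeRaster",
    representation(neuron = "integer", time = "numeric", nNeurons = "integer",
                   duration = "numeric"))

setValidity("SpikeRaster", function(object) {
    if (length(object@neuron) != length(object@time))
        return("neuron/time length mismatch")
    if (length(object@time) > 1 && any(diff(object@time) < 0))
        return("spike times must be non-decreasing")
    if (length(object@neuron) &&
        any(object@neuron < 1L | object@neuron > object@nNeurons))
        return("neuron indices out of range")
    TRUE
})

spikeRaster <- function(neuron, time, nNeurons, duration) {
    new("SpikeRaster", neuron = as.integer(neuron), time = as.numeric(time),
        nNeurons = as.integer(nNeurons), duration = duration)
}

#' Simulation state
#'
#' Per-neuron membrane potential, the two alpha-kernel state variables, the
#' time of the most recent spike (`-Inf` when the neuron has never fired) and
#' the current simulation time.
#'
#' @slot v membrane potentials, mV.
#' @slot x,s alpha-kernel auxiliary states (non-negative).
#' @slot lastSpike most recent spike time per neuron, ms (`-Inf` = never).
#' @slot t current time, ms.
#' @export
setClass("SimulationState",
    representation(v = "numeric", x = "numeric", s = "numeric",
                   lastSpike = "numeric", t = "numeric"))

setValidity("SimulationState", function(object) {
    n <- length(object@v)
    if (length(object@x) != n || length(object@s) != n ||
        length(object@lastSpike) != n)
        return("state vectors must have equal length")
    if (any(!is.finite(object@v))) return("membrane potentials must be finite")
    if (any(object@x < 0) || any(object@s < 0))
        return("synaptic state variables must be non-negative")
    if (any(object@lastSpike > object@t + 1e-9))
        return("lastSpike must not exceed the current time")
    TRUE
})

#' Fresh resting state for a network
#'
#' @param network a [SpikingNetwork-class].
#' @param neuron a [NeuronParams-class]; the state starts at `vRest`.
#' @return A [SimulationState-class] at rest with no spike history.
#' @export
restingState <- function(network, neuron = neuronParams()) {
    n <- nNeurons(network)
    new("SimulationState", v = rep(neuron@vRest, n), x = numeric(n),
        s = numeric(n), lastSpike = rep(-Inf, n), t = 0)
}

#' Exponential falloff fit
#'
#' Result of fitting `y = offset + c * exp(-x / lambda)`: by log-linear
#' least squares with `offset = 0` (the default route), or by bounded
#' nonlinear least squares when a floor term is requested.  `valid` is
#' `FALSE` when the data carry no finite decay constant (non-negative
#' log-linear slope).
#'
#' @slot amplitude fitted amplitude `c`.
#' @slot lambda fitted decay constant, in the units of `x` (ms here).
#' @slot offset fitted floor (0 for the plain log-linear fit).
#' @slot rSquared coefficient of determination.
#' @slot nPoints number of points entering the fit.
#' @slot valid logical; `FALSE` flags a degenerate fit.
#' @export
setClass("ExponentialFit",
    representation(amplitude = "numeric", lambda = "numeric",
                   offset = "numeric", rSquared = "numeric",
                   nPoints = "integer", valid = "logical"),
    prototype(offset = 0))
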