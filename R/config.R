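#' @include AllClasses.R
NULL

#' Full run configuration
#'
#' Bundles every parameter object a simulation pipeline needs, one section
#' per module, plus the global seed and integration step.  Child invariants
#' are validated on construction.
#'
#' @slot geometry a [GeometryConfig-class].
#' @slot connectivity a [ConnectivityConfig-class].
#' @slot neuron a [NeuronParams-class].
#' @slot synapse a [SynapseParams-class].
#' @slot stdp a [StdpParams-class].
#' @slot training a [TrainingProtocol-class].
#' @slot testing a [TestProtocol-class].
#' @slot sweep list with `deltaT` (interval grid, ms) and `nSeeds`.
#' @slot seed global RNG seed.
#' @slot dt integration step, ms.
#' @export
setClass("RunConfig",
    representation(geometry = "GeometryConfig",
                   connectivity = "ConnectivityConfig",
                   neuron = "NeuronParams", synapse = "SynapseParams",
                   stdp = "StdpParams", training = "TrainingProtocol",
                   testing = "TestProtocol", sweep = "list",
                   seed = "integer", dt = "numeric"))

setValidity("RunConfig", function(object) {
    if (!setequal(names(object@sweep), c("deltaT", "nSeeds")))
        return("sweep must have exactly the fields deltaT and nSeeds")
    if (any(object@sweep$deltaT < 0)) return("sweep deltaT must be >= 0")
    if (object@sweep$nSeeds < 1) return("sweep nSeeds must be >= 1")
    if (object@dt <= 0) return("dt must be positive")
    TRUE
})

#' @param geometry,connectivity,neuron,synapse,stdp,training,testing,sweep,seed,dt
#'   see the corresponding slots.
#' @return A validated `RunConfig`.
#' @rdname RunConfig-class
#' @export
runConfig <- function(geometry = geometryConfig(),
                      connectivity = connectivityConfig(),
                      neuron = neuronParams(), synapse = synapseParams(),
                      stdp = stdpParams(), training = trainingProtocol(),
                      testing = testProtocol(),
                      sweep = list(deltaT = seq(0, 60, 10), nSeeds = 5L),
                      seed = 1L, dt = 0.1) {
    new("RunConfig", geometry = geometry, connectivity = connectivity,
        neuron = neuron, synapse = synapse, stdp = stdp, training = training,
        testing = testing, sweep = sweep, seed = as.integer(seed), dt = dt)
}

#' Default study configurations
#'
#' `"full"` is the reference geometry (50 layers x 20 neurons); `"scaled"`
#' is a reduced 20 x 10 lattice with the same connectivity kernel, used for
#' fast sweeps.
#'
#' @param lattice `"full"` or `"scaled"`.
#' @param seed global seed.
#' @return A [RunConfig-class].
#' @export
defaultConfig <- function(lattice = c("full", "scaled"), seed = 1L) {
    lattice <- match.arg(lattice)
    if (lattice == "full")
        runConfig(seed = seed)
    else
        runConfig(geometry = geometryConfig(20, 10),
                  sweep = list(deltaT = seq(0, 60, 10), nSeeds = 3L),
                  seed = seed)
}

## section -> (constructor, file-key -> argument map)
configSchema <- function() {
    list(
        geometry = list(fn = geometryConfig,
            keys = c(n_layers = "nLayers", per_layer = "perLayer",
                     side = "side")),
        connectivity = list(fn = connectivityConfig,
            keys = c(k = "k", lambda_c = "lambdaC", w_init_low = "wInitLow",
                     w_init_high = "wInitHigh")),
        neuron = list(fn = neuronParams,
            keys = c(tau_m = "tauM", v_rest = "vRest", v_th = "vTh",
                     e_ex = "eEx")),
        synapse = list(fn = synapseParams,
            keys = c(g = "g", tau_alpha = "tauAlpha")),
        stdp = list(fn = stdpParams,
            keys = c(a_plus = "aPlus", a_minus = "aMinus",
                     tau_plus = "tauPlus", tau_minus = "tauMinus",
                     w_max = "wMax", w_min = "wMin")),
        training = list(fn = trainingProtocol,
            keys = c(i_s = "iS", t_d = "tD", delta_t = "deltaT",
                     n_trials = "nTrials", settle = "settle")),
        testing = list(fn = testProtocol,
            keys = c(i_t = "iT", target_layer = "targetLayer",
                     t_test = "tTest")))
}

#' Load a run configuration from file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration with one section per
#' module; missing sections and fields take their defaults, unknown keys are
#' rejected with the offending key path, and every child invariant is
#' validated (violations name the key, e.g. `stdp.tau_plus`).
#'
#' @param path readable configuration file.
#' @return A validated [RunConfig-class].
#' @seealso [writeConfig()] for the lossless inverse.
#' @export
loadConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(raw)) raw <- list()
    schema <- configSchema()
    known <- c(names(schema), "sweep", "seed", "dt")
    bad <- setdiff(names(raw), known)
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))

    args <- list()
    for (sec in names(schema)) {
        spec <- schema[[sec]]
        given <- raw[[sec]]
        if (is.null(given)) given <- list()
        bad <- setdiff(names(given), names(spec$keys))
        if (length(bad))
            stop("unknown config key(s): ",
                 paste(paste0(sec, ".", bad), collapse = ", "))
        callArgs <- stats::setNames(given, spec$keys[names(given)])
        callArgs <- lapply(callArgs, function(v) if (is.null(v)) NA_real_ else v)
        obj <- tryCatch(do.call(spec$fn, callArgs), error = function(e)
            stop("invalid section '", sec, "': ", conditionMessage(e),
                 call. = FALSE))
        args[[sec]] <- obj
    }
    sweep <- raw$sweep
    if (is.null(sweep)) sweep <- list(delta_t = seq(0, 60, 10), n_seeds = 5)
    bad <- setdiff(names(sweep), c("delta_t", "n_seeds"))
    if (length(bad))
        stop("unknown config key(s): ",
             paste(paste0("sweep.", bad), collapse = ", "))
    args$sweep <- list(deltaT = as.numeric(sweep$delta_t %||% seq(0, 60, 10)),
                       nSeeds = as.integer(sweep$n_seeds %||% 5))
    args$seed <- as.integer(raw$seed %||% 1L)
    args$dt <- as.numeric(raw$dt %||% 0.1)
    do.call(runConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

configToList <- function(config) {
    schema <- configSchema()
    out <- list()
    for (sec in names(schema)) {
        obj <- methods::slot(config, sec)
        keys <- schema[[sec]]$keys
        vals <- lapply(unname(keys), function(sl) {
            v <- methods::slot(obj, sl)
            if (length(v) == 1 && is.na(v)) NULL else v
        })
        names(vals) <- names(keys)
        out[[sec]] <- vals[!vapply(vals, is.null, logical(1))]
    }
    out$sweep <- list(delta_t = config@sweep$deltaT,
                      n_seeds = config@sweep$nSeeds)
    out$seed <- config@seed
    out$dt <- config@dt
    out
}

#' Write a run configuration to file
#'
#' Serialises a [RunConfig-class] as YAML or JSON (by extension); a
#' load-dump-load round trip is the identity.  Used to echo the exact
#' configuration alongside run outputs.
#'
#' @param config a [RunConfig-class].
#' @param path output file (`.yml`, `.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
    stopifnot(is(config, "RunConfig"))
    lst <- configToList(config)
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::write_yaml(lst, path)
    else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    invisible(path)
}
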