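#' @include AllClasses.R network.R protocols.R
NULL

#' Weight-distribution summary per connection class
#'
#' For each connection class (feedforward, feedback, recurrent): the mean
#' weight, a fixed-bin histogram over `[0, wMax]`, and the fractions of
#' weights within `tol` of either hard bound (saturated high / saturated
#' low).  Empty classes report `NA` fractions rather than zero.
#'
#' @param network a non-empty [SpikingNetwork-class].
#' @param tol saturation tolerance in weight units (default 0.01).
#' @param bins number of histogram bins (default 20).
#' @return List with `table` (`data.frame`: class, n, mean, fracHigh,
#'   fracLow), `counts` (bins x class matrix) and `breaks`.
#' @examples
#' summarizeWeights(makeFixture("saturated_chain"))$table
#' @export
summarizeWeights <- function(network, tol = 0.01, bins = 20) {
    stopifnot(is(network, "SpikingNetwork"))
    if (length(network@weight) == 0) stop("network has no synapses")
    cl <- classifySynapse(network)
    breaks <- seq(0, network@wMax, length.out = bins + 1)
    lev <- levels(cl)
    counts <- matrix(0L, nrow = bins, ncol = length(lev),
                     dimnames = list(NULL, lev))
    tab <- data.frame(class = lev, n = 0L, mean = NA_real_,
                      fracHigh = NA_real_, fracLow = NA_real_)
    for (i in seq_along(lev)) {
        w <- network@weight[cl == lev[i]]
        tab$n[i] <- length(w)
        if (length(w)) {
            tab$mean[i] <- mean(w)
            tab$fracHigh[i] <- mean(w >= network@wMax - tol)
            tab$fracLow[i] <- mean(w <= tol)
            counts[, i] <- as.integer(
                table(cut(w, breaks, include.lowest = TRUE)))
        }
    }
    list(table = tab, counts = counts, breaks = breaks)
}

#' Structural modification of a connection class
#'
#' The class-mean weight change relative to the initial mean of 0.5:
#' `mean - 0.5` for the feedforward class (potentiation direction) and
#' `0.5 - mean` for the feedback class (depression direction); both are
#' non-negative in the trained regime.
#'
#' @param network a [SpikingNetwork-class].
#' @param class `"feedforward"` or `"feedback"`.
#' @param initialMean reference initial mean weight (0.5 for uniform
#'   `[0, 1]` initial weights).
#' @return The modification amount (weight units).
#' @export
deltaG <- function(network, class = c("feedforward", "feedback"),
                   initialMean = 0.5) {
    class <- match.arg(class)
    cl <- classifySynapse(network)
    w <- network@weight[cl == class]
    if (!length(w)) stop("class '", class, "' is empty")
    if (class == "feedforward") mean(w) - initialMean
    else initialMean - mean(w)
}

#' Per-pairing cumulative shift, estimated from interior synapses
#'
#' Under the additive nearest-spike rule the training protocol moves every
#' paired synapse of a class by the same cumulative amount `c` (the dynamics
#' are deterministic and trials repeat identically), so any modified synapse
#' that ends strictly inside the hard bounds carries `c` exactly; the median
#' over interior synapses recovers it robustly.  When every modified synapse
#' has been clipped at a bound the amount is censored (`NA` estimate) —
#' unlike the raw class-mean modification [deltaG()], which the bounds flatten.
#'
#' @param trained the trained [SpikingNetwork-class].
#' @param initial the same network before training (same synapse list).
#' @param branch `"potentiation"` (feedforward weights, upward shifts) or
#'   `"depression"` (feedback weights, downward shifts).
#' @param tol shifts smaller than this count as unmodified; weights within
#'   `tol` of the relevant bound count as clipped.
#' @return List with `estimate` (median interior shift; `NA` when censored),
#'   `nInterior`, `nModified` and `censored`.
#' @export
pairingShift <- function(trained, initial,
                         branch = c("potentiation", "depression"),
                         tol = 1e-6) {
    branch <- match.arg(branch)
    stopifnot(is(trained, "SpikingNetwork"), is(initial, "SpikingNetwork"))
    if (length(trained@weight) != length(initial@weight) ||
        !identical(trained@pre, initial@pre) ||
        !identical(trained@post, initial@post))
        stop("trained and initial networks must share the same synapse list")
    cl <- classifySynapse(trained)
    if (branch == "potentiation") {
        sel <- cl == "feedforward"
        dw <- trained@weight[sel] - initial@weight[sel]
        modified <- dw > tol
        interior <- modified & trained@weight[sel] < trained@wMax - tol
        est <- if (any(interior)) stats::median(dw[interior]) else NA_real_
    } else {
        sel <- cl == "feedback"
        dw <- initial@weight[sel] - trained@weight[sel]
        modified <- dw > tol
        interior <- modified & trained@weight[sel] > tol
        est <- if (any(interior)) stats::median(dw[interior]) else NA_real_
    }
    list(estimate = est, nInterior = sum(interior),
         nModified = sum(modified), censored = !any(interior))
}

#' Fit an exponential falloff
#'
#' The default route fits `y = c * exp(-x / lambda)` by ordinary least
#' squares on `(x, log y)`; `lambda = -1/slope`, `amplitude =
#' exp(intercept)`.  Exact on noiseless exponential samples.  Non-positive
#' `y` values are dropped with a warning; fewer than 3 surviving points is an
#' error.  A non-negative slope (constant or rising data) yields an object
#' flagged invalid with `lambda = Inf`.
#'
#' With `offset = TRUE` the refinement `y = y0 + c * exp(-x / lambda)` is
#' fitted by bounded nonlinear least squares (port algorithm, starts taken
#' from the range of `y` and the log-linear slope of the elevated part),
#' needing at least 4 points.  This accommodates responses that decay onto a
#' floor rather than onto zero, such as spike counts carrying an
#' interval-independent component.
#'
#' @param x predictor values (e.g. inter-stimulus intervals, ms).
#' @param y response values (positive, unless `offset = TRUE`).
#' @param offset fit an additive floor term as well.
#' @return An [ExponentialFit-class].
#' @examples
#' f <- fitExponential(seq(0, 60, 10), 0.4 * exp(-seq(0, 60, 10) / 20))
#' c(f@amplitude, f@lambda)   # 0.4, 20
#' @export
fitExponential <- function(x, y, offset = FALSE) {
    if (length(x) != length(y)) stop("x and y lengths differ")
    if (offset) return(fitExponentialOffset(x, y))
    keep <- is.finite(y) & y > 0 & is.finite(x)
    if (any(!keep))
        warning(sum(!keep), " non-positive or non-finite point(s) dropped")
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3) stop("exponential fit failure: fewer than 3 usable points")
    fit <- stats::lm(log(y) ~ x)
    slope <- unname(stats::coef(fit)[2])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (slope >= 0)
        return(new("ExponentialFit", amplitude = exp(unname(stats::coef(fit)[1])),
                   lambda = Inf, rSquared = r2, nPoints = length(x),
                   valid = FALSE))
    new("ExponentialFit", amplitude = exp(unname(stats::coef(fit)[1])),
        lambda = -1 / slope, rSquared = r2, nPoints = length(x),
        valid = TRUE)
}

fitExponentialOffset <- function(x, y) {
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 4)
        stop("exponential fit failure: fewer than 4 usable points for an offset fit")
    o <- order(x); x <- x[o]; y <- y[o]
    y0 <- min(y)
    c0 <- max(max(y) - y0, 1e-8)
    elev <- y - y0 + 0.05 * c0
    lam0 <- tryCatch({
        f0 <- stats::lm(log(elev) ~ x)
        sl <- unname(stats::coef(f0)[2])
        if (sl < 0) -1 / sl else diff(range(x)) / 2
    }, error = function(e) diff(range(x)) / 2)
    dat <- data.frame(x = x, y = y)
    fit <- tryCatch(
        stats::nls(y ~ y0 + c * exp(-x / lambda), data = dat,
                   start = list(y0 = y0, c = c0, lambda = lam0),
                   algorithm = "port",
                   lower = c(y0 = -Inf, c = 1e-12, lambda = 1e-6),
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = TRUE)),
        error = function(e) NULL)
    if (is.null(fit))
        return(new("ExponentialFit", amplitude = c0, lambda = Inf,
                   offset = y0, rSquared = 0, nPoints = length(x),
                   valid = FALSE))
    cf <- stats::coef(fit)
    ss <- sum(stats::residuals(fit)^2)
    sst <- sum((y - mean(y))^2)
    new("ExponentialFit", amplitude = unname(cf["c"]),
        lambda = unname(cf["lambda"]), offset = unname(cf["y0"]),
        rSquared = if (sst > 0) 1 - ss / sst else NA_real_,
        nPoints = length(x), valid = TRUE)
}

#' Sweep the inter-stimulus interval
#'
#' For each interval and seed: generate a network, calibrate the stimulus
#' once, train with 20-trial sweeps (or as configured), summarise the
#' structure and run the propagation test.  The untrained network's
#' propagation count is recorded as the baseline `S0`.
#'
#' @param config a [RunConfig-class] (see [runConfig()]).
#' @param deltaT intervals to sweep, ms (at least 3).
#' @param nSeeds independent network realisations per interval.
#' @param testFactor multiple of the calibrated training amplitude used for
#'   the propagation test when `config@testing@iT` is `NA` (default 3).
#' @param refInterval reference interval, ms, far beyond the STDP window;
#'   one extra training per seed at this interval measures the
#'   interval-independent component of the propagation count (recurrent
#'   potentiation), reported as `S_ref`.  `NULL` skips it.
#' @return `data.frame` with one row per `(deltaT, seed)`: raw modifications
#'   `dG_pot`/`dG_dep`, interior per-pairing shifts `c_pot`/`c_dep` (`NA`
#'   when censored), saturation fractions, propagation count `S`, untrained
#'   baseline `S0` and (when requested) the reference floor `S_ref`.
#' @export
sweepInterval <- function(config, deltaT = config@sweep$deltaT,
                          nSeeds = config@sweep$nSeeds,
                          refInterval = 200, testFactor = 3) {
    stopifnot(is(config, "RunConfig"))
    if (length(deltaT) < 3)
        stop("need at least 3 intervals to characterise a falloff")
    rows <- list()
    for (si in seq_len(nSeeds)) {
        seed <- config@seed + si - 1L
        net0 <- generateNetwork(config@geometry, config@connectivity, seed)
        iS <- config@training@iS
        if (is.na(iS))
            iS <- calibrateStimulus(net0, tD = config@training@tD,
                                    neuron = config@neuron,
                                    synapse = config@synapse, dt = config@dt)
        testProt <- config@testing
        if (is.na(testProt@iT)) testProt@iT <- testFactor * iS
        S0 <- testPropagation(net0, testProt, config@neuron, config@synapse,
                              config@dt)$S
        cl0 <- classifySynapse(net0)
        ffMean0 <- mean(net0@weight[cl0 == "feedforward"])
        fbMean0 <- mean(net0@weight[cl0 == "feedback"])
        Sref <- NA_real_
        if (!is.null(refInterval)) {
            prot <- config@training
            prot@iS <- iS; prot@deltaT <- refInterval
            refNet <- trainNetwork(net0, prot, config@neuron, config@synapse,
                                   config@stdp, config@dt)$network
            Sref <- testPropagation(refNet, testProt, config@neuron,
                                    config@synapse, config@dt)$S
        }
        for (dT in deltaT) {
            prot <- config@training
            prot@iS <- iS; prot@deltaT <- dT
            tr <- trainNetwork(net0, prot, config@neuron, config@synapse,
                               config@stdp, config@dt)
            sw <- summarizeWeights(tr$network)$table
            cp <- pairingShift(tr$network, net0, "potentiation")
            cd <- pairingShift(tr$network, net0, "depression")
            tp <- testPropagation(tr$network, testProt, config@neuron,
                                  config@synapse, config@dt)
            rows[[length(rows) + 1L]] <- data.frame(
                delta_t = dT, seed = seed,
                dG_pot = deltaG(tr$network, "feedforward", ffMean0),
                dG_dep = deltaG(tr$network, "feedback", fbMean0),
                c_pot = cp$estimate, c_dep = cd$estimate,
                sat_high_ff = sw$fracHigh[sw$class == "feedforward"],
                sat_low_fb = sw$fracLow[sw$class == "feedback"],
                mean_rec = sw$mean[sw$class == "recurrent"],
                S = tp$S, S0 = S0, S_ref = Sref, iS = iS,
                iT = testProt@iT)
        }
    }
    do.call(rbind, rows)
}

aggregateSweep <- function(tab, column) {
    agg <- stats::aggregate(tab[[column]], by = list(delta_t = tab$delta_t),
                            FUN = function(v) mean(v, na.rm = TRUE))
    names(agg)[2] <- "y"
    agg$y[is.nan(agg$y)] <- NA_real_
    agg
}

#' Structural falloff of the per-pairing shift with the interval
#'
#' Aggregates the interior per-pairing shift over seeds at each interval and
#' fits its exponential falloff.  Intervals censored by the hard bounds (no
#' interior synapse in any seed) are excluded from the fit.
#'
#' @param tab output of [sweepInterval()].
#' @param branch `"potentiation"` or `"depression"`.
#' @return An [ExponentialFit-class]; its `lambda` estimates the matching
#'   STDP time constant (ms).
#' @export
structuralFalloff <- function(tab,
                              branch = c("potentiation", "depression")) {
    branch <- match.arg(branch)
    col <- if (branch == "potentiation") "c_pot" else "c_dep"
    agg <- aggregateSweep(tab, col)
    keep <- !is.na(agg$y)
    fitExponential(agg$delta_t[keep], agg$y[keep])
}

#' Dynamical falloff of the propagation count with the interval
#'
#' Fits the exponential falloff of the excess propagation count.  The
#' recurrent weights potentiate by an amount independent of the interval,
#' which lifts the count uniformly; fitting the raw count would absorb that
#' floor into a biased decay constant.  When the sweep carries the measured
#' reference floor `S_ref` (a training at an interval far beyond the STDP
#' window), `S - S_ref` is fitted log-linearly; otherwise the floor is
#' estimated as a free offset by bounded nonlinear least squares.  Intervals
#' whose structural modification is bound-censored (see [pairingShift()])
#' are excluded: the spike count cannot be un-censored there.
#'
#' Spike counts fluctuate by a few spikes from realisation to realisation
#' (the propagation pattern is sensitive to the realised connectivity), so
#' intervals whose mean excess has decayed into that floor carry no decay
#' information: intervals below `minFraction` of the peak mean excess are
#' excluded from the fit.
#'
#' @param tab output of [sweepInterval()].
#' @param minFraction smallest usable mean excess, as a fraction of the
#'   peak (default 0.1).
#' @return An [ExponentialFit-class]; its `lambda` estimates the STDP
#'   potentiation time constant (ms).
#' @export
dynamicalFalloff <- function(tab, minFraction = 0.1) {
    haveRef <- "S_ref" %in% names(tab) && !all(is.na(tab$S_ref))
    tab$S_excess <- tab$S - if (haveRef) tab$S_ref else tab$S0
    agg <- aggregateSweep(tab, "S_excess")
    cens <- aggregateSweep(tab, "c_pot")
    keep <- !is.na(cens$y)
    if (!haveRef)
        return(fitExponential(agg$delta_t[keep], agg$y[keep], offset = TRUE))
    keep <- keep & agg$y > minFraction * max(agg$y)
    if (sum(keep) < 3)
        stop("insufficient propagation signal above the noise floor (",
             sum(keep), " interval(s) usable)")
    fitExponential(agg$delta_t[keep], agg$y[keep])
}

#' Relation report: STDP time constants vs structure vs dynamics
#'
#' Runs interval sweeps for several STDP potentiation time constants,
#' extracts the structural falloff constants (both branches) and the
#' dynamical falloff constant at each setting, fits the line
#' `tauDyn ~ tauPlus`, and estimates the linear coefficient `kappa` of the
#' excess propagation count against the structural modification at one or
#' more test amplitudes.
#'
#' @param config a [RunConfig-class]; its `stdp` slot supplies amplitudes and
#'   the depression time constant for every setting.
#' @param tauPlus potentiation time constants to sweep, ms (>= 3 values for
#'   the slope fit).
#' @param tauMinus depression time constants, recycled along `tauPlus`.
#' @param deltaT intervals per sweep, ms; denser at small intervals so that
#'   fast kernels still contribute several points above the noise floor.
#' @param nSeeds seeds per sweep.
#' @param testFactor test amplitude for the dynamical-falloff sweeps, as a
#'   multiple of the calibrated training amplitude.  The default (9) sits in
#'   the linear-response regime identified by the `kappa` analysis: at
#'   weaker drive the count responds as a thresholded (convex) function of
#'   the structural modification, which distorts the fitted decay constant
#'   (compressing it for fast kernels and inflating it for slow ones).
#' @param tTest counting window for the relation sweeps, ms; longer than the
#'   protocol default so that count fluctuations are small relative to the
#'   excess being fitted.
#' @param iTFactors test amplitudes for the `kappa` fit, as multiples of the
#'   calibrated training amplitude; `kappa` is measured on the sweep whose
#'   `tauPlus` is closest to `config@stdp@tauPlus`.
#' @return A `RelationReport` list: `structure` (per-setting falloff
#'   constants), `slopeDyn` (slope of `tauDyn` vs `tauPlus`), `kappa`
#'   (`data.frame` of `iT`, `kappa`), `sweeps` (raw sweep tables).
#' @export
relationReport <- function(config, tauPlus = c(10, 20, 40),
                           tauMinus = tauPlus,
                           deltaT = c(0, 5, 10, 15, 20, 30, 40, 50),
                           nSeeds = config@sweep$nSeeds,
                           testFactor = 9, tTest = 500,
                           iTFactors = c(3, 6)) {
    stopifnot(is(config, "RunConfig"))
    if (length(tauPlus) < 3) stop("need >= 3 tauPlus values for the slope fit")
    tauMinus <- rep_len(tauMinus, length(tauPlus))
    sweeps <- vector("list", length(tauPlus))
    res <- data.frame(tauPlus = tauPlus, tauMinus = tauMinus,
                      tauStructPot = NA_real_, tauStructDep = NA_real_,
                      tauDyn = NA_real_)
    for (i in seq_along(tauPlus)) {
        cfg <- config
        cfg@stdp@tauPlus <- tauPlus[i]
        cfg@stdp@tauMinus <- tauMinus[i]
        cfg@testing@tTest <- tTest
        tab <- sweepInterval(cfg, deltaT, nSeeds, testFactor = testFactor)
        sweeps[[i]] <- tab
        res$tauStructPot[i] <- structuralFalloff(tab, "potentiation")@lambda
        res$tauStructDep[i] <- structuralFalloff(tab, "depression")@lambda
        fd <- tryCatch(dynamicalFalloff(tab), error = function(e) NULL)
        res$tauDyn[i] <- if (!is.null(fd) && fd@valid) fd@lambda else NA_real_
    }
    slopeDyn <- if (sum(!is.na(res$tauDyn)) >= 3)
        unname(stats::coef(stats::lm(tauDyn ~ tauPlus, data = res))[2])
    else NA_real_

    ## kappa(iT): S - S0 against dG_pot across intervals, per test amplitude
    ref <- which.min(abs(tauPlus - config@stdp@tauPlus))
    refTab <- sweeps[[ref]]
    kap <- data.frame(iT = numeric(0), kappa = numeric(0))
    if (length(iTFactors)) {
        cfg <- config
        cfg@stdp@tauPlus <- tauPlus[ref]; cfg@stdp@tauMinus <- tauMinus[ref]
        kap <- kappaVsAmplitude(cfg, iTFactors, deltaT, nSeeds)
    }
    structure(list(structure = res, slopeDyn = slopeDyn, kappa = kap,
                   sweeps = sweeps, tauPlus = tauPlus, tauMinus = tauMinus),
              class = "RelationReport")
}

## kappa at several test amplitudes: retrain once per (seed, interval) and
## test each network at every amplitude.
kappaVsAmplitude <- function(config, iTFactors, deltaT, nSeeds) {
    rows <- list()
    for (si in seq_len(nSeeds)) {
        seed <- config@seed + si - 1L
        net0 <- generateNetwork(config@geometry, config@connectivity, seed)
        iS <- config@training@iS
        if (is.na(iS))
            iS <- calibrateStimulus(net0, tD = config@training@tD,
                                    neuron = config@neuron,
                                    synapse = config@synapse, dt = config@dt)
        S0 <- vapply(iTFactors, function(f) {
            tp <- config@testing; tp@iT <- f * iS
            testPropagation(net0, tp, config@neuron, config@synapse,
                            config@dt)$S
        }, numeric(1))
        for (dT in deltaT) {
            prot <- config@training
            prot@iS <- iS; prot@deltaT <- dT
            tr <- trainNetwork(net0, prot, config@neuron, config@synapse,
                               config@stdp, config@dt)
            dg <- deltaG(tr$network, "feedforward")
            for (q in seq_along(iTFactors)) {
                tp <- config@testing; tp@iT <- iTFactors[q] * iS
                S <- testPropagation(tr$network, tp, config@neuron,
                                     config@synapse, config@dt)$S
                rows[[length(rows) + 1L]] <- data.frame(
                    seed = seed, delta_t = dT, iT = tp@iT, dG = dg,
                    S_excess = S - S0[q])
            }
        }
    }
    tab <- do.call(rbind, rows)
    out <- lapply(split(tab, tab$iT), function(d) {
        data.frame(iT = d$iT[1],
                   kappa = unname(stats::coef(stats::lm(S_excess ~ dG,
                                                        data = d))[2]))
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.RelationReport <- function(x, ...) {
    cat("RelationReport\n")
    print(x$structure, row.names = FALSE)
    cat(sprintf("slope of tauDyn vs tauPlus: %.3f\n", x$slopeDyn))
    if (nrow(x$kappa)) {
        cat("kappa (S excess per unit structural modification):\n")
        print(x$kappa, row.names = FALSE)
    }
    invisible(x)
}
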