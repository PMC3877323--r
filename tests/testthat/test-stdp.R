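test_that("the pair kernel is exponential in the spike-time difference", {
    p <- stdpParams(aPlus = 0.1, aMinus = 0.1, tauPlus = 20, tauMinus = 20)
    expect_equal(stdpKernel(20, p), 0.1 * exp(-1))
    expect_equal(stdpKernel(-20, p), -0.1 * exp(-1))
    expect_equal(stdpKernel(0, p), 0.1)          # synchrony potentiates
    expect_lt(abs(stdpKernel(1e4, p)), 1e-12)
    expect_lt(abs(stdpKernel(-1e4, p)), 1e-12)
    expect_error(stdpKernel(NaN, p), "finite")

    pa <- stdpParams(aPlus = 0.1, aMinus = 0.105, tauPlus = 20,
                     tauMinus = 40)
    expect_equal(stdpKernel(-40, pa), -0.105 * exp(-1))
    expect_false(isSymmetric(pa))
    expect_true(isSymmetric(p))
})

test_that("weights are clipped into the hard bounds", {
    p <- stdpParams()
    expect_equal(clipWeight(1.2, p), 1)
    expect_equal(clipWeight(-0.1, p), 0)
    expect_equal(clipWeight(0.5, p), 0.5)
    expect_error(clipWeight(NA_real_, p), "finite")
})

test_that("an on-spike update modifies both directed synapses of a pair", {
    net <- makeFixture("two_neuron")          # edges (1->2), (2->1), w = 0.5
    p <- stdpParams(aPlus = 0.1, aMinus = 0.1, tauPlus = 20, tauMinus = 20)

    # pre 1 fired at 0, post 2 fires at 10: 1->2 potentiated, 2->1 depressed
    up <- applyOnSpike(net, 2, 10, c(0, -Inf), p)
    expect_equal(up@weight[1], 0.5 + 0.1 * exp(-0.5), tolerance = 1e-12)
    expect_equal(up@weight[2], 0.5 - 0.1 * exp(-0.5), tolerance = 1e-12)

    # symmetric rule: potentiation equals depression in magnitude
    expect_equal(up@weight[1] - 0.5, 0.5 - up@weight[2], tolerance = 1e-12)

    # saturation: a change past the bound lands exactly on the bound
    hi <- stdpnet:::setWeights(net, c(0.999, 0.5))
    up <- applyOnSpike(hi, 2, 5, c(0, -Inf), p)
    expect_identical(up@weight[1], 1)

    # a partner that never fired leaves the weight untouched
    up <- applyOnSpike(net, 2, 10, c(-Inf, -Inf), p)
    expect_identical(up@weight, net@weight)

    expect_error(applyOnSpike(net, 2, 10, c(50, -Inf), p), "precede")
    expect_error(applyOnSpike(net, 9, 10, c(0, -Inf), p), "unknown")
})

test_that("incremental on-spike updates match the full-walk oracle", {
    net <- makeFixture("two_neuron")
    p <- stdpParams(aPlus = 0.07, aMinus = 0.08, tauPlus = 15, tauMinus = 30)
    set.seed(11)
    for (rep in 1:8) {
        grid <- seq(0.5, 100, by = 0.1)
        times <- list(sort(sample(grid, sample(3:20, 1))),
                      sort(sample(grid, sample(3:20, 1))))
        if (rep %% 2 == 0) {
            # force some exact collisions to exercise the synchrony rule
            times[[2]][1:2] <- times[[1]][1:2]
            times[[2]] <- sort(unique(times[[2]]))
        }
        sim <- forcedSpikeRun(net, times, p)
        oracle <- stdpWalkOracle(net, times, p)
        expect_equal(sim@weight, oracle, tolerance = 1e-9)
    }
})

test_that("weights stay inside the bounds under arbitrary update sequences", {
    net <- makeFixture("three_layer_mini")
    p <- stdpParams(aPlus = 0.4, aMinus = 0.5, tauPlus = 10, tauMinus = 25)
    set.seed(99)
    for (rep in 1:5) {
        times <- lapply(1:9, function(i) sort(sample(seq(0.5, 50, 0.1),
                                                     sample(2:10, 1))))
        out <- forcedSpikeRun(net, times, p)
        expect_true(all(out@weight >= 0 & out@weight <= 1))
    }
})
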