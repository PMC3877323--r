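test_that("alpha kernel has the normalised rise-and-decay shape", {
    expect_equal(alphaKernel(0, 2), 0)
    expect_equal(alphaKernel(2, 2), 1)
    expect_equal(alphaKernel(4, 2), 2 * exp(-1))
    expect_equal(alphaKernel(-1, 2), 0)
    expect_equal(alphaKernel(1.5, 1.5), 1)  # peak at tauAlpha for any tau
})

test_that("rest is a fixed point and decay is monotone toward rest", {
    net <- makeFixture("two_neuron")
    out <- runSimulation(net, duration = 50)
    expect_length(out$raster, 0)
    expect_equal(out$state@v, rep(-70, 2))

    # start off-rest with no input: approach v_rest from above, monotonically
    s0 <- new("SimulationState", v = c(-58, -70), x = numeric(2),
              s = numeric(2), lastSpike = rep(-Inf, 2), t = 0)
    v5 <- runSimulation(net, 5, state = s0)$state@v[1]
    v15 <- runSimulation(net, 15, state = s0)$state@v[1]
    expect_true(-70 < v15 && v15 < v5 && v5 < -58)
    expect_equal(v5, -70 + 12 * exp(-5 / 20), tolerance = 1e-10)
})

test_that("subthreshold response matches the closed-form linear ODE", {
    # no synapses: tau dV/dt = (v_rest - V) + I, V(t) = v_rest + I(1 - e^(-t/tau))
    net <- generateNetwork(geometryConfig(2, 1), connectivityConfig(k = 0),
                           seed = 1)
    I <- 10; tEnd <- 50
    out <- runSimulation(net, tEnd,
                         stimulus = list(stimulusSegment(0, tEnd, I,
                                                         neurons = 1)))
    expected <- -70 + I * (1 - exp(-tEnd / 20))
    expect_lt(abs(out$state@v[1] - expected) / abs(expected), 0.001)
    expect_length(out$raster, 0)   # -60 stays below threshold
})

test_that("threshold crossing records a spike and resets to rest", {
    net <- generateNetwork(geometryConfig(2, 1), connectivityConfig(k = 0),
                           seed = 1)
    # run exactly to the crossing step so the reset is observable
    out <- runSimulation(net, 4.5,
                         stimulus = list(stimulusSegment(0, 5, 80,
                                                         neurons = 1)))
    df <- as.data.frame(out$raster)
    expect_equal(unique(df$neuron), 1L)
    # analytic crossing: 80(1 - e^(-t/20)) = 16  =>  t = 20 log(5/4) = 4.46
    tCross <- 20 * log(80 / 64)
    expect_lt(abs(df$time[1] - tCross), 0.1 + 1e-9)
    expect_equal(out$state@v[1], -70)   # reset to rest at the spike
})

test_that("halving the step moves spike times by less than one step", {
    net <- makeFixture("two_neuron")
    stim <- list(stimulusSegment(0, 30, 25, neurons = 1))
    t1 <- as.data.frame(runSimulation(net, 30, stimulus = stim,
                                      dt = 0.1)$raster)$time
    t2 <- as.data.frame(runSimulation(net, 30, stimulus = stim,
                                      dt = 0.05)$raster)$time
    expect_equal(length(t1), length(t2))
    expect_true(all(abs(t1 - t2) < 0.1 + 1e-9))
})

test_that("excitatory input cannot push the potential past its reversal", {
    # huge conductance, threshold just under E_ex = 0: V converges below 0
    net <- makeFixture("two_neuron")
    np <- neuronParams(vTh = -0.5)
    out <- runSimulation(net, 100,
                         stimulus = list(stimulusSegment(0, 100, 80,
                                                         neurons = 1)),
                         neuron = np, synapse = synapseParams(g = 100))
    expect_true(all(as.data.frame(out$raster)$neuron == 1))
    expect_lt(max(out$state@v), 0)
})

test_that("a presynaptic spike through a strong synapse drives the post", {
    net <- makeFixture("two_neuron")
    net <- stdpnet:::setWeights(net, c(1, 0.5))       # strengthen 1 -> 2
    out <- runSimulation(net, 40,
                         stimulus = list(stimulusSegment(0, 5, 80,
                                                         neurons = 1)),
                         synapse = synapseParams(g = 5))
    df <- as.data.frame(out$raster)
    expect_true(2 %in% df$neuron)
    expect_gt(min(df$time[df$neuron == 2]), min(df$time[df$neuron == 1]))
})

test_that("identical configurations reproduce identical rasters", {
    net <- generateNetwork(geometryConfig(6, 4), seed = 5)
    stim <- list(stimulusSegment(0, 5, 80, layers = 1))
    r1 <- runSimulation(net, 60, stimulus = stim, plasticity = stdpParams())
    r2 <- runSimulation(net, 60, stimulus = stim, plasticity = stdpParams())
    expect_identical(as.data.frame(r1$raster), as.data.frame(r2$raster))
    expect_identical(r1$network@weight, r2$network@weight)
})

test_that("non-finite state aborts with a diagnostic", {
    net <- makeFixture("two_neuron")
    expect_error(
        runSimulation(net, 1, stimulus = list(stimulusSegment(0, 1, Inf,
                                                              neurons = 1))),
        "amplitude must be finite")
    expect_error(runSimulation(net, -5), "duration")
})
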