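test_that("weight summaries report means, histograms and saturation", {
    net <- generateNetwork(geometryConfig(10, 8), seed = 12)
    sw <- summarizeWeights(net, tol = 0.01, bins = 20)
    expect_equal(sum(sw$counts), length(net@weight))
    for (i in 1:3) {
        row <- sw$table[i, ]
        if (row$n > 200) {                       # uniform initial weights
            expect_lt(abs(row$mean - 0.5), 0.05)
            expect_lt(abs(row$fracHigh - 0.01), 0.02)
            expect_lt(abs(row$fracLow - 0.01), 0.02)
        }
    }

    chain <- makeFixture("saturated_chain")
    tb <- summarizeWeights(chain)$table
    expect_equal(tb$fracHigh[tb$class == "feedforward"], 1)
    expect_equal(tb$fracLow[tb$class == "feedback"], 1)

    # an empty class reports NA fractions, not zero
    two <- makeFixture("two_neuron")
    tb <- summarizeWeights(two)$table
    expect_true(is.na(tb$fracHigh[tb$class == "recurrent"]))
})

test_that("structural modification is measured against the initial mean", {
    net <- generateNetwork(geometryConfig(10, 8), seed = 12)
    cl <- classifySynapse(net)
    expect_equal(deltaG(net, "feedforward"),
                 mean(net@weight[cl == "feedforward"]) - 0.5)
    expect_equal(deltaG(net, "feedback",
                        initialMean = mean(net@weight[cl == "feedback"])), 0)

    chain <- makeFixture("saturated_chain")
    expect_equal(deltaG(chain, "feedforward"), 0.5)
    expect_equal(deltaG(chain, "feedback"), 0.5)

    noFb <- ablate(makeFixture("two_neuron"), "feedback")
    expect_error(deltaG(noFb, "feedback"), "empty")
})

test_that("interior synapses recover the per-pairing shift exactly", {
    net <- generateNetwork(geometryConfig(10, 8), seed = 3)
    cl <- classifySynapse(net)
    shift <- 0.2
    w <- net@weight
    w[cl == "feedforward"] <- pmin(1, w[cl == "feedforward"] + shift)
    w[cl == "feedback"] <- pmax(0, w[cl == "feedback"] - shift)
    trained <- stdpnet:::setWeights(net, w)

    cp <- pairingShift(trained, net, "potentiation")
    cd <- pairingShift(trained, net, "depression")
    expect_equal(cp$estimate, shift, tolerance = 1e-12)
    expect_equal(cd$estimate, shift, tolerance = 1e-12)
    expect_false(cp$censored)

    # a shift past the whole range leaves no interior witness: censored
    w2 <- net@weight
    w2[cl == "feedforward"] <- 1
    sat <- stdpnet:::setWeights(net, w2)
    cs <- pairingShift(sat, net, "potentiation")
    expect_true(cs$censored)
    expect_true(is.na(cs$estimate))
})

test_that("noiseless exponential samples are fitted exactly", {
    x <- seq(0, 60, 10)
    f <- fitExponential(x, 0.4 * exp(-x / 20))
    expect_equal(f@amplitude, 0.4, tolerance = 1e-12)
    expect_equal(f@lambda, 20, tolerance = 1e-12)
    expect_equal(f@rSquared, 1)
    expect_true(f@valid)

    fo <- fitExponential(x, 5 + 3 * exp(-x / 15), offset = TRUE)
    expect_equal(fo@lambda, 15, tolerance = 1e-6)
    expect_equal(fo@offset, 5, tolerance = 1e-6)
    expect_equal(fo@amplitude, 3, tolerance = 1e-6)
})

test_that("degenerate fits are flagged or rejected", {
    x <- seq(0, 60, 10)
    const <- fitExponential(x, rep(2, 7))
    expect_false(const@valid)
    expect_equal(const@lambda, Inf)

    expect_warning(f <- fitExponential(x, c(1, 0.5, 0.25, 0, -1, 0.1, 0.05)),
                   "dropped")
    expect_equal(f@nPoints, 5L)
    expect_error(fitExponential(c(1, 2), c(1, 2)), "fewer than 3")
    expect_error(suppressWarnings(fitExponential(x, c(1, 0.5, rep(0, 5)))),
                 "fewer than 3")
})

test_that("lognormal measurement noise leaves the decay constant within 10%", {
    x <- seq(0, 60, 10)
    set.seed(2024)
    lam <- replicate(100, {
        y <- 0.4 * exp(-x / 20) * rlnorm(7, 0, 0.05)
        fitExponential(x, y)@lambda
    })
    expect_lt(max(abs(lam - 20) / 20), 0.10)
    expect_lt(abs(median(lam) - 20) / 20, 0.02)
})

test_that("interval sweeps aggregate structure and propagation per seed", {
    cfg <- runConfig(geometry = geometryConfig(6, 8),
                     connectivity = connectivityConfig(k = 0.4,
                                                       lambdaC = 0.15),
                     training = trainingProtocol(nTrials = 5),
                     sweep = list(deltaT = c(0, 30, 60), nSeeds = 1L))
    expect_error(sweepInterval(cfg, deltaT = 0), "at least 3")

    tab <- sweepInterval(cfg, refInterval = NULL)
    expect_equal(nrow(tab), 3)
    expect_true(all(diff(tab$dG_pot) < 0))       # falloff with the interval
    expect_true(all(diff(tab$c_pot) < 0))
    expect_true(all(tab$S >= 0))
    # symmetric rule: potentiation and depression shifts agree per interval
    expect_equal(tab$c_pot, tab$c_dep, tolerance = 0.05)
})
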