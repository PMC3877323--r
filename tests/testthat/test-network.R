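test_that("lattice placement follows the closed form", {
    lat <- buildLattice(geometryConfig(2, 1))
    expect_equal(unname(lat$positions),
                 rbind(c(0.25, 0.5), c(0.75, 0.5)))

    lat <- buildLattice(geometryConfig(50, 20))
    expect_equal(which(lat$layer == 3), 41:60)
    d <- as.matrix(dist(lat$positions))
    expect_true(all(d <= sqrt(2)))

    expect_error(geometryConfig(1, 5), "nLayers")
})

test_that("connection probability is the clamped exponential kernel", {
    cfg <- connectivityConfig(k = 0.2, lambdaC = 0.1)
    expect_equal(connectionProbability(0, cfg), 0.2)
    expect_equal(connectionProbability(0.1, cfg), 0.2 * exp(-1))
    expect_lt(connectionProbability(50, cfg), 1e-10)
    expect_error(connectionProbability(-0.1, cfg), "non-negative")
    expect_equal(connectionProbability(0, connectivityConfig(k = 1)), 1)
})

test_that("generated networks match the pair-enumeration oracle", {
    geo <- geometryConfig(50, 20)
    cfg <- connectivityConfig(k = 0.2, lambdaC = 0.1)
    net <- generateNetwork(geo, cfg, seed = 42)

    # oracle: expected undirected edge count by direct summation over pairs
    lat <- buildLattice(geo)
    ij <- which(upper.tri(diag(nrow(lat$positions))), arr.ind = TRUE)
    d <- sqrt((lat$positions[ij[, 1], 1] - lat$positions[ij[, 2], 1])^2 +
              (lat$positions[ij[, 1], 2] - lat$positions[ij[, 2], 2])^2)
    p <- pmin(1, 0.2 * exp(-d / 0.1))
    mu <- sum(p); sdev <- sqrt(sum(p * (1 - p)))
    realized <- length(net@pre) / 2     # both directions stored
    expect_lt(abs(realized - mu), 3 * sdev)

    # reciprocal support, no self-loops, bounded weights
    key <- paste(net@pre, net@post)
    rev <- paste(net@post, net@pre)
    expect_true(all(rev %in% key))
    expect_true(all(net@pre != net@post))
    expect_true(all(net@weight >= 0 & net@weight <= 1))
})

test_that("generation is deterministic given the seed and empty at k = 0", {
    geo <- geometryConfig(6, 4)
    n1 <- generateNetwork(geo, seed = 7)
    n2 <- generateNetwork(geo, seed = 7)
    expect_identical(n1@pre, n2@pre)
    expect_identical(n1@weight, n2@weight)
    expect_false(identical(generateNetwork(geo, seed = 8)@weight, n1@weight))

    empty <- generateNetwork(geo, connectivityConfig(k = 0), seed = 1)
    expect_length(empty@pre, 0)
})

test_that("expected edge count is monotone in k and lambdaC (oracle sum)", {
    lat <- buildLattice(geometryConfig(10, 5))
    ij <- which(upper.tri(diag(50)), arr.ind = TRUE)
    d <- sqrt((lat$positions[ij[, 1], 1] - lat$positions[ij[, 2], 1])^2 +
              (lat$positions[ij[, 1], 2] - lat$positions[ij[, 2], 2])^2)
    total <- function(k, l) sum(connectionProbability(d, connectivityConfig(k = k, lambdaC = l)))
    ks <- seq(0.05, 1, length.out = 6)
    expect_true(all(diff(sapply(ks, total, l = 0.1)) >= 0))
    ls <- seq(0.02, 0.5, length.out = 6)
    expect_true(all(diff(sapply(ls, function(l) total(0.2, l))) >= 0))
})

test_that("synapse classification partitions by training direction", {
    net <- makeFixture("three_layer_mini")
    cl <- classifySynapse(net)
    expect_equal(sum(table(cl)), length(net@pre))

    # layer arithmetic: 3 layers x 3 neurons, neuron 4 is in layer 2
    expect_equal(as.character(classifySynapse(net, pre = 1, post = 4)),
                 "feedforward")
    expect_equal(as.character(classifySynapse(net, pre = 4, post = 1)),
                 "feedback")
    expect_equal(as.character(classifySynapse(net, pre = 1, post = 2)),
                 "recurrent")
    expect_error(classifySynapse(net, pre = 1, post = 99), "unknown neuron")

    # reciprocal support makes the directed class counts mirror each other
    big <- generateNetwork(geometryConfig(10, 6), seed = 3)
    tb <- table(classifySynapse(big))
    expect_equal(unname(tb["feedforward"]), unname(tb["feedback"]))
})

test_that("ablation removes exactly the named class and is idempotent", {
    net <- makeFixture("saturated_chain")
    nfb <- sum(classifySynapse(net) == "feedback")
    expect_gt(nfb, 0)

    noFb <- ablate(net, "feedback")
    tb <- table(classifySynapse(noFb))
    expect_equal(unname(tb["feedback"]), 0L)
    expect_equal(unname(tb["feedforward"]),
                 unname(table(classifySynapse(net))["feedforward"]))
    expect_identical(ablate(noFb, "feedback"), noFb)

    none <- ablate(net, "both")
    expect_true(all(classifySynapse(none) == "feedforward"))
    expect_error(ablate(net, "sideways"))
})
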