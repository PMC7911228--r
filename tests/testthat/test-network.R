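test_that("the two-layer builder wires 784 inputs and 7840 plastic synapses", {
  net <- buildTwoLayer()
  expect_equal(net@nIn, 784L)
  expect_equal(net@nOut, 10L)
  expect_equal(dim(net@weights), c(784L, 10L))
  expect_equal(length(net@noiseTargets), 784L)  # one generator per input
  expect_true(all(net@weights >= 0.3 & net@weights <= 0.7))
})

test_that("the three-layer builder wires a 576-neuron memory layer", {
  net <- buildThreeLayer()
  expect_equal(net@nIn, 576L)                       # 4 * 12 * 12
  expect_equal(length(net@noiseTargets), 115L)      # round(0.2 * 576)
  net120 <- buildThreeLayer(nNoise = 120)
  expect_equal(length(net120@noiseTargets), 120L)
  net0 <- buildThreeLayer(noiseFraction = 0)
  expect_length(net0@noiseTargets, 0)               # condition (a) topology
  expect_equal(length(encodeForNetwork(net, matrix(100, 28, 28))), 576L)
})

test_that("all-zero weights yield the no-spike fallback label", {
  net <- buildTwoLayer(stdp = STDPParams(wMin = 0, wMax = 1))
  net@weights[] <- 0
  img <- withr::with_seed(5, matrix(runif(784, 0, 255), 28, 28))
  p <- present(net, encodeForNetwork(net, img))
  expect_true(p$noSpike)
  expect_equal(p$label, 0L)
  expect_equal(sum(p$perOutputSpikeCounts), 0)
})

test_that("a single output saturated from bright pixels wins the decoding", {
  net <- buildTwoLayer(imageShape = c(2, 2), nOut = 3, synCurrent = 50000)
  net@weights[] <- 0
  net@weights[c(1, 3), 2] <- 1    # output 1 (label 1) driven by row-1 pixels
  img <- matrix(0, 2, 2); img[1, ] <- 255
  p <- present(net, encodeForNetwork(net, img))
  expect_false(p$noSpike)
  expect_equal(p$label, 1L)
  expect_lt(p$firstSpikeTimes[2], min(p$firstSpikeTimes[-2]))
})

test_that("every input spike delivers exactly one pulse per outgoing synapse", {
  net <- buildTwoLayer()
  img <- withr::with_seed(6, matrix(runif(784, 0, 255), 28, 28))
  p <- present(net, encodeForNetwork(net, img), details = TRUE)
  expect_equal(nrow(p$inputSpikes), 784)            # one relay spike per pixel
  expect_equal(sum(p$events$nInputs), nrow(p$inputSpikes))
  # pulses = spikes x fan-out, scheduled at distinct event times
  expect_equal(sum(p$events$nInputs) * net@nOut, 784 * 10)
  expect_true(!is.unsorted(p$events$times))
})

test_that("presentations are deterministic for identical networks", {
  net <- buildTwoLayer(seed = 3)
  img <- generateDigits(1, seed = 1)@images[, , 1]
  e <- encodeForNetwork(net, img)
  expect_identical(present(net, e), present(net, e))
  expect_error(present(net, e[-1]), "784")
})

test_that("zero training iterations leave the weights unchanged", {
  net <- buildTwoLayer(imageShape = c(2, 2), nOut = 2)
  toy <- toyPatterns()
  fit <- trainNetwork(net, toy$images, toy$labels, 0)
  expect_identical(fit$network@weights, net@weights)
  expect_equal(nrow(fit$log), 0)
  expect_error(trainNetwork(net, list(), integer(0), 1), "empty")
})

test_that("two orthogonal patterns are learned to 100% in 20 iterations", {
  toy <- toyPatterns()
  net <- buildTwoLayer(imageShape = c(2, 2), nOut = 2, synCurrent = 50000,
                       stdp = STDPParams(aPlus = 0.02, rewardMismatched = -1),
                       seed = 0)
  fit <- trainNetwork(net, toy$images, toy$labels, 20, evalTest = "none")
  expect_equal(evaluateAccuracy(fit$network, toy$images, toy$labels), 1)
  expect_equal(tail(fit$log$trainAcc, 1), 1)
})

test_that("training with a fixed seed reproduces the accuracy log", {
  d <- generateDigits(20, seed = 2)
  run <- function() {
    net <- buildTwoLayer(seed = 5)
    trainNetwork(net, d@images, d@labels, 2, evalTest = "none")
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$log, f2$log)
  expect_identical(f1$network@weights, f2$network@weights)
})

test_that("weight tables round-trip the weight matrix", {
  net <- buildTwoLayer(imageShape = c(2, 2), nOut = 2)
  tab <- weightsToTable(net)
  expect_equal(nrow(tab), 8)
  expect_equal(matrix(tab$weight, 4, 2), net@weights)
})
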