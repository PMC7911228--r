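test_that("the STDP window matches its printed piecewise exponential", {
  p <- STDPParams(aPlus = 0.005, aMinus = 0.00525, tauPlus = 20, tauMinus = 20)
  expect_equal(stdpWindow(20, p), 0.005 / exp(1))
  expect_equal(stdpWindow(-20, p), -0.00525 / exp(1))
  expect_equal(stdpWindow(0, p), 0)                 # no causal order
  expect_equal(stdpWindow(1e6, p), 0, tolerance = 1e-12)
  expect_equal(stdpWindow(-1e6, p), 0, tolerance = 1e-12)
  dts <- seq(-50, 50, by = 0.5)
  w <- stdpWindow(dts, p)
  expect_true(all(w[dts > 0] > 0))                  # LTP iff causal
  expect_true(all(w[dts < 0] < 0))                  # LTD iff anticausal
})

test_that("anticausal/causal magnitude ratio follows the amplitude ratio", {
  p <- STDPParams(aPlus = 0.004, aMinus = 0.007, tauPlus = 20, tauMinus = 20)
  dts <- c(1, 5, 12.5, 30)
  expect_equal(abs(stdpWindow(-dts, p)) / abs(stdpWindow(dts, p)),
               rep(p@aMinus / p@aPlus, length(dts)))
  p2 <- STDPParams(aPlus = 0.004, aMinus = 0.007, tauPlus = 15, tauMinus = 25)
  expect_equal(abs(stdpWindow(-dts, p2)) / abs(stdpWindow(dts, p2)),
               (p2@aMinus / p2@aPlus) * exp(dts / p2@tauPlus - dts / p2@tauMinus))
})

test_that("pair sums match hand-computed single- and two-pair values", {
  p <- STDPParams()
  expect_equal(pairWeightChange(numeric(0), c(1, 2, 3), p), 0)
  expect_equal(pairWeightChange(10, 15, p), 0.005 * exp(-0.25))
  expect_equal(pairWeightChange(c(10, 30), 15, p),
               0.005 * exp(-0.25) - 0.00525 * exp(-0.75))
})

test_that("pair sums equal the brute-force double loop on random trains", {
  p <- STDPParams(aPlus = 0.006, aMinus = 0.004, tauPlus = 18, tauMinus = 31)
  withr::with_seed(123, {
    for (k in 1:30) {
      pre <- sort(runif(sample(0:8, 1), 0, 60))
      post <- sort(runif(sample(0:8, 1), 0, 60))
      expect_equal(pairWeightChange(pre, post, p),
                   bruteForcePairSum(pre, post, p), tolerance = 1e-13)
    }
  })
})

test_that("pair sums are additive over disjoint pre spike sets", {
  p <- STDPParams()
  withr::with_seed(77, {
    for (k in 1:10) {
      pre1 <- runif(4, 0, 30); pre2 <- runif(5, 30.1, 60)
      post <- runif(6, 0, 60)
      expect_equal(pairWeightChange(c(pre1, pre2), post, p),
                   pairWeightChange(pre1, post, p) +
                     pairWeightChange(pre2, post, p), tolerance = 1e-12)
    }
  })
})

test_that("supervised updates follow the match/mismatch rule", {
  p <- STDPParams(rewardMatched = 1, rewardMismatched = -1)
  w0 <- matrix(0.5, 1, 2)
  # no output spiked: weights unchanged
  expect_equal(supervisedUpdate(w0, list(5), list(numeric(0), numeric(0)), 0, p), w0)
  # only the true-label neuron spiked, causal pair: its weight increases
  w1 <- supervisedUpdate(w0, list(5), list(9, numeric(0)), 0, p)
  expect_equal(w1[1, 1], 0.5 + 0.005 * exp(-4 / 20))
  expect_equal(w1[1, 2], 0.5)
  # only a wrong neuron spiked: its weight decreases by the pair-sum magnitude
  w2 <- supervisedUpdate(w0, list(5), list(numeric(0), 9), 0, p)
  expect_equal(w2[1, 1], 0.5)
  expect_equal(w2[1, 2], 0.5 - 0.005 * exp(-4 / 20))
  # mismatch uses the magnitude even when the pair sum is negative (anticausal)
  w3 <- supervisedUpdate(w0, list(9), list(numeric(0), 5), 0, p)
  expect_equal(w3[1, 2], 0.5 - 0.00525 * exp(-4 / 20))
  expect_error(supervisedUpdate(w0, list(5), list(9, numeric(0)), 2, p),
               "trueLabel")
})

test_that("weights stay inside the hard bounds under random update sequences", {
  p <- STDPParams(aPlus = 0.3, aMinus = 0.4, rewardMismatched = -1)
  w <- matrix(0.5, 3, 2)
  withr::with_seed(9, {
    for (k in 1:40) {
      pre <- lapply(1:3, function(i) sort(runif(3, 0, 20)))
      post <- lapply(1:2, function(i) sort(runif(2, 0, 20)))
      w <- supervisedUpdate(w, pre, post, sample(0:1, 1), p)
      expect_true(all(w >= p@wMin & w <= p@wMax))
    }
  })
})

test_that("repeated matched causal presentations drive weights toward w_max", {
  p <- STDPParams(aPlus = 0.05)
  w <- matrix(0.3, 2, 1)
  path <- numeric(30)
  for (k in 1:30) {
    w <- supervisedUpdate(w, list(1, 2), list(c(4, 8)), 0, p)
    path[k] <- mean(w)
  }
  expect_true(all(diff(path) >= 0))
  expect_equal(path[30], 1)  # saturated at w_max
})
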