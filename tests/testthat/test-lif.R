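test_that("resting membrane is a fixed point and negative drive settles below rest", {
  p <- LIFParams()
  s <- simulateNeuron(p, I = 0, duration = 50, dt = 0.1, u0 = -70)
  expect_equal(s$u, rep(-70, length(s$u)))
  expect_length(s$spikes, 0)
  sNeg <- simulateNeuron(p, I = -100, duration = 300, dt = 0.1)
  expect_length(sNeg$spikes, 0)
  expect_equal(tail(sNeg$u, 1), -74, tolerance = 1e-6)
})

test_that("constant 400 pA fires at the closed-form time-to-threshold", {
  p <- LIFParams()
  tStar <- p@tauM * log(16 / 1)       # tau ln((u_inf - E_L)/(u_inf - V_th))
  expect_equal(timeToThreshold(p, -70, 400), tStar)
  for (dt in c(0.1, 0.02, 0.005)) {
    s <- simulateNeuron(p, I = 400, duration = 40, dt = dt)
    expect_gt(length(s$spikes), 0)
    # spike lands on the first step boundary at or after t*
    expect_equal(s$spikes[1], dt * ceiling(tStar / dt), tolerance = 1e-9)
  }
})

test_that("exactly rheobase current (375 pA) never fires over 1000 ms", {
  p <- LIFParams()
  expect_equal(steadyStatePotential(p, 375), p@vTh)
  s <- simulateNeuron(p, I = 375, duration = 1000, dt = 0.1)
  expect_length(s$spikes, 0)
})

test_that("rheobase formula gives 375 pA for defaults and scales with C_m", {
  expect_equal(rheobase(LIFParams()), 375)
  expect_equal(rheobase(LIFParams(cM = 500)), 750)
})

test_that("closed-form potential has the right limits and value", {
  p <- LIFParams()
  expect_equal(closedFormPotential(p, -62.5, 120, 0), -62.5)
  expect_equal(closedFormPotential(p, -60, 0, 1e6), -70)
  expect_equal(closedFormPotential(p, -70, 400, 10), -70 + 16 * (1 - exp(-1)))
})

test_that("stepped trajectory equals the closed form at every boundary", {
  p <- LIFParams()
  cases <- withr::with_seed(42, data.frame(
    u0 = runif(20, -75, -58), I = runif(20, -200, 350),
    dt = sample(c(0.01, 0.05, 0.1, 0.5, 1), 20, replace = TRUE)))
  for (k in seq_len(nrow(cases))) {
    s <- simulateNeuron(p, cases$I[k], duration = 20, dt = cases$dt[k],
                        u0 = cases$u0[k])
    expect_length(s$spikes, 0)
    expect_equal(s$u, closedFormPotential(p, cases$u0[k], cases$I[k], s$times),
                 tolerance = 1e-9)
  }
})

test_that("no two spikes are closer than the refractory period", {
  p <- LIFParams()
  s <- simulateNeuron(p, I = 900, duration = 300, dt = 0.1)
  expect_gt(length(s$spikes), 5)
  expect_true(all(diff(s$spikes) >= p@tRef))
})

test_that("stronger suprathreshold currents fire earlier", {
  p <- LIFParams()
  currents <- withr::with_seed(7, sort(runif(8, 380, 2000)))
  first <- vapply(currents, function(I)
    simulateNeuron(p, I, duration = 200, dt = 0.1)$spikes[1], numeric(1))
  expect_true(all(diff(first) <= 0))
  tts <- vapply(currents, function(I) timeToThreshold(p, -70, I), numeric(1))
  expect_true(all(diff(tts) < 0))
})

test_that("identical inputs give bitwise-identical spike trains", {
  p <- LIFParams()
  I <- withr::with_seed(3, runif(2000, 300, 500))
  s1 <- simulateNeuron(p, I, duration = 200, dt = 0.1)
  s2 <- simulateNeuron(p, I, duration = 200, dt = 0.1)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$u, s2$u)
})

test_that("stepNeuron rejects nonpositive dt and clamps during refractoriness", {
  p <- LIFParams()
  st <- newNeuronState(p)
  expect_error(stepNeuron(st, p, 0, dt = 0, now = 0), "dt")
  expect_error(stepNeuron(st, p, 0, dt = -0.1, now = 0), "dt")
  st$refractoryUntil <- 5
  st$u <- p@vReset
  st2 <- stepNeuron(st, p, 2000, dt = 0.1, now = 1)
  expect_equal(st2$u, p@vReset)
  expect_length(st2$spikes, 0)
})

test_that("parameter invariants are enforced and R is derived correctly", {
  expect_equal(membraneResistance(LIFParams()), 40)
  expect_error(LIFParams(tauM = -1), "tauM")
  expect_error(LIFParams(eL = -55, vTh = -55), "eL")
  expect_error(LIFParams(vReset = -50), "vReset")
})

test_that("LIF parameters load from a Table-style YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("EL: -65.0", "Vth: -50.0", "Vreset: -65.0",
               "Cm: 200.0", "tau_m: 8.0"), path)
  p <- lifParamsFromConfig(path)
  expect_equal(p@eL, -65)
  expect_equal(p@vTh, -50)
  expect_equal(p@cM, 200)
  expect_equal(p@tauM, 8)
  expect_equal(p@tRef, 2)  # default kept for missing keys
})
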