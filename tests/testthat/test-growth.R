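test_that("a causal pair of adjacent spikes grows exactly one directed synapse", {
  geo <- memoryGeometry()
  empty <- matrix(FALSE, 576, 576)
  rule <- GrowthRule(coincidenceWindow = 10, coincidenceThreshold = 1)
  # neurons 1 and 2 sit at grid (1,1) and (2,1): Chebyshev neighbours
  g <- growStep(data.frame(neuron = c(1L, 2L), time = c(5, 7)), empty, rule, geo)
  expect_equal(g$new, data.frame(pre = 1L, post = 2L))
  expect_equal(sum(g$synapses), 1)
  # reversed order grows the reverse synapse: causal order is respected
  g2 <- growStep(data.frame(neuron = c(1L, 2L), time = c(7, 5)), empty, rule, geo)
  expect_equal(g2$new, data.frame(pre = 2L, post = 1L))
  # simultaneous spikes never count
  g3 <- growStep(data.frame(neuron = c(1L, 2L), time = c(5, 5)), empty, rule, geo)
  expect_equal(sum(g3$synapses), 0)
  # silence grows nothing
  g4 <- growStep(data.frame(neuron = integer(0), time = numeric(0)), empty, rule, geo)
  expect_equal(sum(g4$synapses), 0)
})

test_that("coincidence counts accumulate across presentations", {
  geo <- memoryGeometry()
  empty <- matrix(FALSE, 576, 576)
  rule <- GrowthRule(coincidenceThreshold = 2)
  sp <- data.frame(neuron = c(1L, 2L), time = c(5, 7))
  g1 <- growStep(sp, empty, rule, geo)
  expect_equal(sum(g1$synapses), 0)          # one pair < threshold
  g2 <- growStep(sp, g1$synapses, rule, geo, counts = g1$counts)
  expect_equal(g2$new, data.frame(pre = 1L, post = 2L))
})

test_that("spikes outside the neighbourhood radius never grow synapses", {
  geo <- memoryGeometry()
  rule <- GrowthRule(coincidenceThreshold = 1, neighborhoodRadius = 3)
  # neurons 1 (grid 1,1) and 61 (grid 1,6): Chebyshev distance 5 > 3
  expect_equal(geo$gCol[61], 6)
  g <- growStep(data.frame(neuron = c(1L, 61L), time = c(5, 7)),
                matrix(FALSE, 576, 576), rule, geo)
  expect_equal(sum(g$synapses), 0)
})

test_that("growth is monotone: the synapse set only ever grows", {
  geo <- memoryGeometry()
  rule <- GrowthRule(coincidenceThreshold = 1)
  syn <- matrix(FALSE, 576, 576)
  counts <- NULL
  prevCount <- 0
  withr::with_seed(31, {
    for (k in 1:8) {
      sp <- data.frame(neuron = sample(576, 40), time = runif(40, 0, 15))
      old <- syn
      g <- growStep(sp, syn, rule, geo, counts = counts)
      syn <- g$synapses; counts <- g$counts
      expect_true(all(syn[old]))             # nothing removed
      expect_gte(sum(syn), prevCount)
      prevCount <- sum(syn)
    }
  })
})

test_that("growth is equivariant under relabeling of grid coordinates", {
  geoA <- data.frame(neuron = 1:9, gRow = rep(1:3, 3), gCol = rep(1:3, each = 3))
  perm <- withr::with_seed(8, sample(9))
  geoB <- geoA; geoB$neuron <- perm
  rule <- GrowthRule(coincidenceThreshold = 1, neighborhoodRadius = 1)
  sp <- data.frame(neuron = c(1L, 2L, 5L, 9L), time = c(1, 3, 4, 20))
  spB <- data.frame(neuron = perm[sp$neuron], time = sp$time)
  gA <- growStep(sp, matrix(FALSE, 9, 9), rule, geoA)
  gB <- growStep(spB, matrix(FALSE, 9, 9), rule, geoB)
  mapped <- cbind(perm[gA$new$pre], perm[gA$new$post])
  got <- cbind(gB$new$pre, gB$new$post)
  expect_setequal(paste(mapped[, 1], mapped[, 2]), paste(got[, 1], got[, 2]))
})

test_that("growth runs are reproducible and respect their wiring", {
  d <- generateDigits(5, seed = 0)
  r1 <- runGrowthExperiment("c", d, nPresentations = 5, seed = 4)
  r2 <- runGrowthExperiment("c", d, nPresentations = 5, seed = 4)
  expect_identical(r1@synapseMap, r2@synapseMap)
  expect_identical(r1@noiseMap, r2@noiseMap)
  expect_equal(r1@nSynapses, nrow(r1@synapseMap))
  # with no generators attached, the noise-only condition is fully silent
  rb0 <- runGrowthExperiment("b", NULL, nPresentations = 5, seed = 4, nNoise = 0)
  expect_equal(rb0@nSynapses, 0L)
  # in the noise-only condition every grown synapse joins two noisy neurons
  rb <- runGrowthExperiment("b", NULL, nPresentations = 10, seed = 4)
  expect_true(all(rb@synapseMap$pre %in% rb@noiseMap))
  expect_true(all(rb@synapseMap$post %in% rb@noiseMap))
  expect_error(runGrowthExperiment("a", NULL, nPresentations = 2), "dataset")
})

test_that("growth reports export consistent dot-map tables", {
  d <- generateDigits(5, seed = 0)
  r <- runGrowthExperiment("a", d, nPresentations = 3, seed = 1)
  tabs <- growthReportTables(r)
  expect_equal(nrow(tabs$neurons), 576)
  expect_equal(sum(tabs$neurons$noisy), length(r@noiseMap))
  expect_equal(sum(tabs$neurons$incidentSynapses), 2 * r@nSynapses)
  expect_true(all(r@synapseMap$preRow >= 1 & r@synapseMap$preRow <= 24))
})
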