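# Scripted experiments with reproducible run manifests.

lifToList <- function(p) list(tau_m = p@tauM, Cm = p@cM, EL = p@eL,
                              Vth = p@vTh, Vreset = p@vReset, t_ref = p@tRef)
lifFromList <- function(x) LIFParams(tauM = x$tau_m, cM = x$Cm, eL = x$EL,
                                     vTh = x$Vth, vReset = x$Vreset,
                                     tRef = x$t_ref)
noiseToList <- function(p) list(mean_pA = p@mu, std_pA = p@sigma,
                                refresh_ms = p@refreshDt, seed = p@seed)
noiseFromList <- function(x) NoiseParams(mu = x$mean_pA, sigma = x$std_pA,
                                         refreshDt = x$refresh_ms,
                                         seed = x$seed)

makeManifest <- function(experiment, params) {
  list(experiment = experiment, package = "snnlab",
       version = as.character(utils::packageVersion("snnlab")),
       params = params)
}

#' Write a run manifest as JSON
#'
#' @param x an experiment result carrying a \code{manifest} attribute, or a
#'   manifest list itself
#' @param path output path
#' @return the path, invisibly
#' @export
writeManifest <- function(x, path) {
  m <- attr(x, "manifest")
  if (is.null(m)) m <- x
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Re-run an experiment from its manifest
#'
#' Replays the exact (config, seed) combination recorded in a manifest
#' (a list, or a path to a manifest JSON). Deterministic runs reproduce their
#' outputs bitwise; stochastic runs reproduce them given the recorded seeds.
#'
#' @param manifest a manifest list or JSON path
#' @return the experiment result
#' @export
rerunExperiment <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  p <- manifest$params
  switch(manifest$experiment,
    sweepRheobase = sweepRheobase(mu = unlist(p$mu), durationMs = p$durationMs,
                                  lif = lifFromList(p$lif), dt = p$dt),
    sweepNoiseMean = sweepNoiseMean(
      muGrid = unlist(p$muGrid), sigma = p$sigma, nTrain = p$nTrain,
      nTest = p$nTest, nIterations = p$nIterations, seeds = unlist(p$seeds),
      jitterPx = p$jitterPx, noiseLevel = p$noiseLevel,
      synCurrent = p$synCurrent, evalTest = p$evalTest),
    growthComparison = growthComparison(
      seeds = unlist(p$seeds), nPresentations = p$nPresentations,
      nImages = p$nImages, noise = noiseFromList(p$noise),
      nNoise = p$nNoise, jitterPx = p$jitterPx, noiseLevel = p$noiseLevel),
    stop("unknown experiment: ", manifest$experiment))
}

#' Single-neuron constant-current sweep (rheobase boundary)
#'
#' Simulates one LIF neuron per grid value of the constant current mean
#' (sigma = 0) for \code{durationMs} and reports whether it fired and when.
#' With the default parameters the firing boundary lies between 375 pA
#' (fixed point exactly at threshold, approached strictly from below: never
#' fires) and 376 pA (fires at ~59.3 ms).
#'
#' @param mu numeric vector of constant currents, pA
#' @param durationMs window per run, ms
#' @param lif a [LIFParams]
#' @param dt resolution, ms
#' @return data.frame with columns mu, fired, firstSpikeTime (NA if silent)
#' @export
sweepRheobase <- function(mu, durationMs = 200, lif = LIFParams(), dt = 0.1) {
  nSteps <- as.integer(round(durationMs / dt))
  nMu <- length(mu)
  u <- rep(lif@eL, nMu)
  refUntil <- rep(-Inf, nMu)
  first <- rep(NA_real_, nMu)
  decay <- exp(-dt / lif@tauM)
  uinf <- steadyStatePotential(lif, mu)
  for (k in seq_len(nSteps)) {
    now <- (k - 1) * dt
    refr <- now < refUntil - 1e-9
    un <- uinf + (u - uinf) * decay
    un[refr] <- lif@vReset
    fire <- !refr & (un > lif@vTh)
    if (any(fire)) {
      tEnd <- now + dt
      first[fire & is.na(first)] <- tEnd
      un[fire] <- lif@vReset
      refUntil[fire] <- tEnd + lif@tRef
    }
    u <- un
  }
  out <- data.frame(mu = mu, fired = !is.na(first), firstSpikeTime = first)
  attr(out, "manifest") <- makeManifest("sweepRheobase",
    list(mu = mu, durationMs = durationMs, lif = lifToList(lif), dt = dt))
  out
}

#' Noise-mean accuracy sweep on the synthetic-digit task
#'
#' Trains the two-layer network once per (mu, seed) pair — plus the mu = 0
#' baseline — on a balanced procedural digit set, and reports held-out test
#' accuracy and its difference to the baseline at matched seeds
#' (\code{delta = acc(mu) - acc(0)}). Per seed, the dataset and the initial
#' weights are identical across the whole mu grid, so delta isolates the
#' noise contribution.
#'
#' @param muGrid noise means to sweep, pA (baseline 0 is added internally)
#' @param sigma noise standard deviation, pA
#' @param nTrain,nTest dataset split sizes
#' @param nIterations training passes
#' @param seeds integer vector of run seeds
#' @param jitterPx,noiseLevel generator settings (see [generateDigits()])
#' @param synCurrent synaptic pulse amplitude, pA
#' @param evalTest "final" (default) or "each" iteration
#' @param verbose print one line per run
#' @return data.frame with columns mu, seed, trainAcc, testAcc, delta
#' @export
sweepNoiseMean <- function(muGrid = seq(2, 30, by = 2), sigma = 0,
                           nTrain = 200, nTest = 100, nIterations = 5,
                           seeds = 0:4, jitterPx = 1L, noiseLevel = 0.02,
                           synCurrent = 600, evalTest = "final",
                           verbose = FALSE) {
  rows <- list()
  for (s in seeds) {
    dataset <- generateDigits(nTrain + nTest, seed = s, jitterPx = jitterPx,
                              noiseLevel = noiseLevel)
    trainIdx <- seq_len(nTrain)
    testIdx <- nTrain + seq_len(nTest)
    trainImgs <- dataset@images[, , trainIdx, drop = FALSE]
    testImgs <- dataset@images[, , testIdx, drop = FALSE]
    trainLabs <- dataset@labels[trainIdx]
    testLabs <- dataset@labels[testIdx]
    for (mu in c(0, muGrid)) {
      net <- buildTwoLayer(
        noise = NoiseParams(mu = mu, sigma = sigma, seed = deriveSeed(s, 21)),
        synCurrent = synCurrent, seed = deriveSeed(s, 31))
      fit <- trainNetwork(net, trainImgs, trainLabs, nIterations,
                          testImages = testImgs, testLabels = testLabs,
                          evalTest = evalTest)
      last <- fit$log[nrow(fit$log), ]
      if (verbose)
        message(sprintf("mu=%g seed=%d: train %.3f test %.3f",
                        mu, s, last$trainAcc, last$testAcc))
      rows[[length(rows) + 1]] <- data.frame(
        mu = mu, seed = s, trainAcc = last$trainAcc, testAcc = last$testAcc)
    }
  }
  out <- do.call(rbind, rows)
  base <- out[out$mu == 0, c("seed", "testAcc")]
  out$delta <- out$testAcc - base$testAcc[match(out$seed, base$seed)]
  attr(out, "manifest") <- makeManifest("sweepNoiseMean",
    list(muGrid = muGrid, sigma = sigma, nTrain = nTrain, nTest = nTest,
         nIterations = nIterations, seeds = seeds, jitterPx = jitterPx,
         noiseLevel = noiseLevel, synCurrent = synCurrent,
         evalTest = evalTest))
  out
}

#' Three-condition growth comparison
#'
#' Runs the structural-growth experiment under conditions (a) stimulus only,
#' (b) noise only, (c) stimulus plus noise, at matched seeds, and tabulates
#' the synapse counts and the c-vs-a ratio.
#'
#' @param seeds integer vector of run seeds
#' @param nPresentations presentations per run
#' @param nImages images in the per-seed stimulus set
#' @param noise a [NoiseParams]; default mu = 400 pA, sigma = 0
#' @param nNoise number of attached generators
#' @param jitterPx,noiseLevel generator settings
#' @param ... further arguments passed to [runGrowthExperiment()]
#' @return list with \code{counts} (seed x condition table),
#'   \code{summary} (median count per condition and the median c/a ratio)
#'   and \code{reports} (list of [GrowthReport]s indexed "seed.condition")
#' @export
growthComparison <- function(seeds = 0:9, nPresentations = 20L, nImages = 20L,
                             noise = NoiseParams(mu = 400, sigma = 0),
                             nNoise = round(0.2 * 576), jitterPx = 1L,
                             noiseLevel = 0.02, ...) {
  rows <- list()
  reports <- list()
  for (s in seeds) {
    dataset <- generateDigits(nImages, seed = deriveSeed(s, 41),
                              jitterPx = jitterPx, noiseLevel = noiseLevel)
    for (cond in c("a", "b", "c")) {
      rep_ <- runGrowthExperiment(cond,
        dataset = if (cond == "b") NULL else dataset, noise = noise,
        nPresentations = nPresentations, seed = s, nNoise = nNoise, ...)
      reports[[paste(s, cond, sep = ".")]] <- rep_
      rows[[length(rows) + 1]] <- data.frame(seed = s, condition = cond,
                                             nSynapses = rep_@nSynapses)
    }
  }
  counts <- do.call(rbind, rows)
  med <- tapply(counts$nSynapses, counts$condition, stats::median)
  perSeed <- stats::reshape(counts, idvar = "seed", timevar = "condition",
                            direction = "wide")
  ratio <- stats::median(perSeed$nSynapses.c / pmax(perSeed$nSynapses.a, 1))
  out <- list(counts = counts,
              summary = list(median = med, medianRatioCvsA = ratio),
              reports = reports)
  attr(out, "manifest") <- makeManifest("growthComparison",
    list(seeds = seeds, nPresentations = nPresentations, nImages = nImages,
         noise = noiseToList(noise), nNoise = nNoise, jitterPx = jitterPx,
         noiseLevel = noiseLevel))
  out
}
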