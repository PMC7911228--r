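#' Build the two-layer classification network
#'
#' 28x28 = 784 relay input LIF neurons, each receiving (i) its pixel's
#' latency-encoded spike as a forced suprathreshold event and (ii) its own
#' seeded Gaussian noise generator (one-to-one wiring), fully connected by a
#' plastic 784 x 10 projection to 10 output LIF neurons (one per digit).
#' Initial weights are i.i.d. uniform on [0.3, 0.7] under the network seed.
#'
#' @param imageShape raw image shape, default c(28, 28)
#' @param nOut number of output neurons (10 digits)
#' @param noise a [NoiseParams] object attached to every input neuron
#' @param lif,stdp,encoding parameter objects
#' @param dt simulation resolution, ms
#' @param synCurrent synaptic delta-pulse amplitude at weight 1, pA
#' @param gapMs silent gap after the encoding window, ms
#' @param seed seed for the initial weights and noise streams
#' @return a [SpikingNetwork] object
#' @export
buildTwoLayer <- function(imageShape = c(28, 28), nOut = 10L,
                          noise = NoiseParams(), lif = LIFParams(),
                          stdp = STDPParams(), encoding = EncodingParams(),
                          dt = 0.1, synCurrent = 600, gapMs = 5, seed = 0L) {
  nIn <- as.integer(prod(imageShape))
  nOut <- as.integer(nOut)
  w <- withr::with_seed(deriveSeed(seed, 1),
                        matrix(stats::runif(nIn * nOut, 0.3, 0.7), nIn, nOut))
  new("SpikingNetwork", type = "two-layer", nIn = nIn, nOut = nOut,
      weights = w, lif = lif, stdp = stdp, encoding = encoding, noise = noise,
      noiseTargets = seq_len(nIn), dt = dt, synCurrent = synCurrent,
      gapMs = gapMs, seed = as.integer(seed), filters = list(),
      pooling = "max", imageShape = as.integer(imageShape))
}

#' Build the three-layer network with a conv/pool memory layer
#'
#' The raw 28x28 image is preprocessed by \code{nFilters} fixed 4x4
#' convolutions and 2x2 pooling into \code{nFilters} 12x12 channels, whose
#' pixels map one-to-one onto 4*12*12 = 576 memory-layer LIF neurons. A
#' seeded random subset of memory neurons (round(noiseFraction * 576) by
#' default, or exactly \code{nNoise}) each receives its own noise generator.
#' The memory layer projects fully onto 10 output neurons; lateral
#' memory-layer synapses start empty (or from a sparse random prior) and grow
#' via the structural rule (see [runGrowthExperiment()]).
#'
#' @inheritParams buildTwoLayer
#' @param nFilters number of convolution channels
#' @param filters list of 4x4 kernels, default [defaultKernels()]
#' @param pooling "max" or "mean"
#' @param noiseFraction fraction of memory neurons with a generator
#' @param nNoise exact number of generators (overrides noiseFraction;
#'   e.g. 120 to mirror a fixed generator budget)
#' @return a [SpikingNetwork] object
#' @export
buildThreeLayer <- function(imageShape = c(28, 28), nFilters = 4L, nOut = 10L,
                            noise = NoiseParams(), noiseFraction = 0.2,
                            nNoise = NULL, filters = defaultKernels(nFilters),
                            pooling = c("max", "mean"), lif = LIFParams(),
                            stdp = STDPParams(), encoding = EncodingParams(),
                            dt = 0.1, synCurrent = 600, gapMs = 5, seed = 0L) {
  stopifnot(noiseFraction >= 0, noiseFraction <= 1)
  pooling <- match.arg(pooling)
  nIn <- as.integer(nFilters * 12 * 12)
  nOut <- as.integer(nOut)
  if (is.null(nNoise)) nNoise <- round(noiseFraction * nIn)
  targets <- if (nNoise > 0) {
    withr::with_seed(deriveSeed(seed, 2), sort(sample.int(nIn, nNoise)))
  } else integer(0)
  w <- withr::with_seed(deriveSeed(seed, 1),
                        matrix(stats::runif(nIn * nOut, 0.3, 0.7), nIn, nOut))
  new("SpikingNetwork", type = "three-layer", nIn = nIn, nOut = nOut,
      weights = w, lif = lif, stdp = stdp, encoding = encoding, noise = noise,
      noiseTargets = as.integer(targets), dt = dt, synCurrent = synCurrent,
      gapMs = gapMs, seed = as.integer(seed), filters = filters,
      pooling = pooling, imageShape = as.integer(imageShape))
}

#' Encode a raw image into the network's input spike times
#'
#' Two-layer: elementwise latency encoding of the 28x28 image. Three-layer:
#' conv/pool preprocessing first, then latency encoding of each 12x12
#' channel; neuron order is channel-major, column-major within a channel.
#'
#' @param network a [SpikingNetwork]
#' @param image 28x28 numeric matrix, values in [0, 255]
#' @return numeric vector of spike times (ms), one per input/memory neuron
#' @export
encodeForNetwork <- function(network, image) {
  if (network@type == "two-layer") {
    as.vector(encodeImage(image, network@encoding))
  } else {
    pp <- preprocessImage(image, nFilters = length(network@filters),
                          filters = network@filters, pooling = network@pooling)
    as.vector(encodePixel(pp, network@encoding))
  }
}

decodePrediction <- function(trains, nOut) {
  counts <- lengths(trains)
  first <- vapply(trains, function(t) if (length(t)) t[1] else Inf, numeric(1))
  if (all(counts == 0)) {
    return(list(label = 0L, perOutputSpikeCounts = counts,
                firstSpikeTimes = first, noSpike = TRUE))
  }
  cand <- which(first == min(first))
  if (length(cand) > 1) cand <- cand[counts[cand] == max(counts[cand])]
  list(label = as.integer(min(cand) - 1L), perOutputSpikeCounts = counts,
       firstSpikeTimes = first, noSpike = FALSE)
}

# Core presentation: forced times must already be grid-quantized.
presentCore <- function(network, forced, duration) {
  inp <- simulateRelayLayer(network@nIn, network@lif, forced, duration,
                            network@dt, t0 = 0, noise = network@noise,
                            noiseTargets = network@noiseTargets)
  out <- runOutputLayer(network@weights, inp$spikes, network@lif, network@dt,
                        network@synCurrent, tEnd = duration)
  pred <- decodePrediction(out$trains, network@nOut)
  list(inputSpikes = inp$spikes, outputTrains = out$trains,
       events = out$events, prediction = pred)
}

#' Present one encoded image to the network
#'
#' Simulates the full presentation window: input/memory neurons emit their
#' encoded spikes (forced relay events, plus any noise-driven spikes when a
#' generator can reach threshold), each spike delivers one delta-current
#' pulse per outgoing synapse (amplitude proportional to the weight), and the
#' output neurons integrate them with the exact exponential update. Decoding:
#' earliest output spike; ties broken by larger spike count, then lowest
#' index; if no output spikes at all the label falls back to 0 with
#' \code{noSpike = TRUE}.
#'
#' @param network a [SpikingNetwork]
#' @param encoded spike-time vector/matrix from [encodeForNetwork()]
#' @param duration presentation length, ms (default: encoding window + gap)
#' @param details if TRUE, also return input spikes, output trains and the
#'   synaptic event schedule
#' @return a prediction list with elements \code{label},
#'   \code{perOutputSpikeCounts}, \code{firstSpikeTimes}, \code{noSpike}
#' @export
present <- function(network, encoded, duration = NULL, details = FALSE) {
  encoded <- as.vector(encoded)
  if (length(encoded) != network@nIn)
    stop(sprintf("encoded image has %d entries; network expects %d",
                 length(encoded), network@nIn))
  if (is.null(duration)) duration <- network@encoding@tStop + network@gapMs
  forced <- quantizeTime(encoded, network@dt)
  res <- presentCore(network, forced, duration)
  if (details) {
    c(res$prediction, list(inputSpikes = res$inputSpikes,
                           outputTrains = res$outputTrains,
                           events = res$events))
  } else {
    res$prediction
  }
}

# Supervised update from the flat spike representation used internally.
applyStdpUpdate <- function(network, inputSpikes, outputTrains, label) {
  p <- network@stdp
  w <- network@weights
  for (j in seq_len(network@nOut)) {
    lab <- j - 1L
    spiked <- length(outputTrains[[j]]) > 0
    if (lab == label || spiked) {
      d <- pairSumsPerInput(inputSpikes$neuron, inputSpikes$time,
                            outputTrains[[j]], network@nIn, p)
      w[, j] <- w[, j] + if (lab == label) p@rewardMatched * d
                         else p@rewardMismatched * abs(d)
    }
  }
  network@weights <- clip(w, p@wMin, p@wMax)
  network
}

#' Classification accuracy of a network on a labelled set
#'
#' @param network a [SpikingNetwork]
#' @param images 28 x 28 x n array, or a list of pre-encoded spike vectors
#' @param labels integer vector of true digits
#' @return fraction of correctly decoded labels
#' @export
evaluateAccuracy <- function(network, images, labels) {
  enc <- encodeSet(network, images)
  duration <- network@encoding@tStop + network@gapMs
  pred <- vapply(enc, function(e) {
    presentCore(network, quantizeTime(e, network@dt), duration)$prediction$label
  }, integer(1))
  mean(pred == labels)
}

encodeSet <- function(network, images) {
  if (is.list(images)) return(images)
  lapply(seq_len(dim(images)[3]), function(k)
    encodeForNetwork(network, images[, , k]))
}

#' Train a network with supervised STDP
#'
#' Loops presentations of the training set in order; after each presentation
#' the supervised STDP rule is applied (potentiate synapses onto the
#' true-label output by the all-pairs sum, depress synapses onto wrong
#' outputs that spiked by its magnitude). Training accuracy is recorded with
#' the weights the network had when each image was presented; test accuracy
#' is evaluated after each iteration (or only after the last, for speed).
#'
#' @param network a [SpikingNetwork]
#' @param images 28 x 28 x n training array (or list of encoded vectors)
#' @param labels integer digit labels for the training images
#' @param nIterations number of passes over the training set
#' @param testImages,testLabels optional held-out set
#' @param evalTest "each", "final" or "none"
#' @return list with the trained \code{network} and a \code{log} data.frame
#'   (iteration, trainAcc, testAcc)
#' @export
trainNetwork <- function(network, images, labels, nIterations,
                         testImages = NULL, testLabels = NULL,
                         evalTest = c("each", "final", "none")) {
  evalTest <- match.arg(evalTest)
  enc <- encodeSet(network, images)
  if (length(enc) == 0) stop("empty training set")
  stopifnot(length(enc) == length(labels))
  duration <- network@encoding@tStop + network@gapMs
  forcedList <- lapply(enc, quantizeTime, dt = network@dt)
  testEnc <- if (!is.null(testImages)) encodeSet(network, testImages)
  log <- data.frame(iteration = integer(0), trainAcc = numeric(0),
                    testAcc = numeric(0))
  if (nIterations < 1) return(list(network = network, log = log))
  for (it in seq_len(nIterations)) {
    correct <- 0L
    for (k in seq_along(forcedList)) {
      res <- presentCore(network, forcedList[[k]], duration)
      if (res$prediction$label == labels[k]) correct <- correct + 1L
      network <- applyStdpUpdate(network, res$inputSpikes, res$outputTrains,
                                 labels[k])
    }
    testAcc <- NA_real_
    if (!is.null(testEnc) &&
        (evalTest == "each" || (evalTest == "final" && it == nIterations))) {
      testAcc <- evaluateAccuracy(network, testEnc, testLabels)
    }
    log <- rbind(log, data.frame(iteration = it,
                                 trainAcc = correct / length(forcedList),
                                 testAcc = testAcc))
  }
  list(network = network, log = log)
}

#' Export a weight matrix as (pre, post, weight) triples
#'
#' @param network a [SpikingNetwork]
#' @param path optional CSV path; if given the table is also written there
#' @return data.frame with columns pre, post, weight
#' @export
weightsToTable <- function(network, path = NULL) {
  w <- network@weights
  df <- data.frame(pre = rep(seq_len(nrow(w)), times = ncol(w)),
                   post = rep(seq_len(ncol(w)), each = nrow(w)),
                   weight = as.vector(w))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
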