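#' @import methods
NULL

#' Leaky integrate-and-fire membrane parameters
#'
#' Physiological constants of the LIF neuron in the units used throughout the
#' package: ms, pF, mV, pA. The membrane resistance is derived,
#' R = tau_m / C_m (equivalently 1/g_l with g_l the leak conductance), and is
#' 40 MOhm for the defaults. Defaults are the NEST iaf defaults: tau_m = 10 ms,
#' C_m = 250 pF, E_L = V_reset = -70 mV, V_th = -55 mV, t_ref = 2 ms.
#'
#' @slot tauM membrane time constant, ms
#' @slot cM membrane capacitance, pF
#' @slot eL resting (leak reversal) potential, mV
#' @slot vTh spike threshold, mV
#' @slot vReset post-spike reset potential, mV
#' @slot tRef absolute refractory period, ms
#' @export
setClass("LIFParams",
  representation(tauM = "numeric", cM = "numeric", eL = "numeric",
                 vTh = "numeric", vReset = "numeric", tRef = "numeric"))

setValidity("LIFParams", function(object) {
  msg <- character(0)
  if (length(object@tauM) != 1 || !is.finite(object@tauM) || object@tauM <= 0)
    msg <- c(msg, "tauM must be a single positive number (ms)")
  if (length(object@cM) != 1 || !is.finite(object@cM) || object@cM <= 0)
    msg <- c(msg, "cM must be a single positive number (pF)")
  if (length(object@tRef) != 1 || !is.finite(object@tRef) || object@tRef < 0)
    msg <- c(msg, "tRef must be >= 0 (ms)")
  if (object@vReset > object@vTh)
    msg <- c(msg, "vReset must not exceed vTh")
  if (object@eL >= object@vTh)
    msg <- c(msg, "eL must lie strictly below vTh")
  if (length(msg)) msg else TRUE
})

#' @param tauM,cM,eL,vTh,vReset,tRef see slot documentation.
#' @return A \code{LIFParams} object.
#' @rdname LIFParams-class
#' @export
LIFParams <- function(tauM = 10, cM = 250, eL = -70, vTh = -55,
                      vReset = -70, tRef = 2) {
  new("LIFParams", tauM = tauM, cM = cM, eL = eL, vTh = vTh,
      vReset = vReset, tRef = tRef)
}

#' Gaussian white-noise current generator parameters
#'
#' Mean and standard deviation of the per-tick Gaussian current used as the
#' background-activity (default-mode) surrogate. A fresh value
#' I_k = mu + sigma * eta_k (eta_k iid standard normal) is drawn every
#' \code{refreshDt} and held constant within the tick, copying the NEST
#' noise-generator semantics: draws are NOT scaled by 1/sqrt(dt), so the
#' effective variance of the injected charge depends on the tick length.
#'
#' @slot mu mean current, pA
#' @slot sigma standard deviation, pA
#' @slot refreshDt interval between fresh draws, ms
#' @slot seed integer seed of the generator stream
#' @export
setClass("NoiseParams",
  representation(mu = "numeric", sigma = "numeric", refreshDt = "numeric",
                 seed = "integer"))

setValidity("NoiseParams", function(object) {
  msg <- character(0)
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@refreshDt <= 0) msg <- c(msg, "refreshDt must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param mu,sigma,refreshDt,seed see slot documentation.
#' @return A \code{NoiseParams} object.
#' @rdname NoiseParams-class
#' @export
NoiseParams <- function(mu = 0, sigma = 0, refreshDt = 0.1, seed = 0L) {
  new("NoiseParams", mu = mu, sigma = sigma, refreshDt = refreshDt,
      seed = as.integer(seed))
}

#' Latency-encoding window parameters
#'
#' Pixel values are mapped into spike times inside \code{[tStart, tStop]}:
#' brighter pixels spike earlier (rank-order coding).
#'
#' @slot tStart start of the encoding window, ms
#' @slot tStop end of the encoding window, ms
#' @export
setClass("EncodingParams",
  representation(tStart = "numeric", tStop = "numeric"))

setValidity("EncodingParams", function(object) {
  if (!(object@tStop > object@tStart && object@tStart >= 0))
    "need tStop > tStart >= 0" else TRUE
})

#' @param tStart,tStop see slot documentation.
#' @return An \code{EncodingParams} object.
#' @rdname EncodingParams-class
#' @export
EncodingParams <- function(tStart = 0, tStop = 10) {
  new("EncodingParams", tStart = tStart, tStop = tStop)
}

#' Pair-based STDP parameters
#'
#' Amplitudes and time constants of the piecewise-exponential STDP window,
#' weight bounds, and the supervisory reward factors applied to matched
#' (correct-label) and mismatched (wrong, but spiking) output neurons.
#' Defaults are the canonical pair-based values (A+ = 0.005,
#' A- = 1.05 * A+, tau+ = tau- = 20 ms).
#'
#' @slot aPlus LTP amplitude (dimensionless weight units)
#' @slot aMinus LTD amplitude
#' @slot tauPlus LTP time constant, ms
#' @slot tauMinus LTD time constant, ms
#' @slot wMin,wMax hard weight bounds
#' @slot rewardMatched multiplier for synapses onto the true-label output (+1)
#' @slot rewardMismatched multiplier for synapses onto wrong outputs that
#'   spiked; applied to the magnitude of the pair sum. Default -0.15: with
#'   nOut outputs, every presentation potentiates one output but can depress
#'   up to nOut - 1, so a mismatch magnitude near 1/(nOut - 1) balances the
#'   two drives; a symmetric -1 drives all weights to zero and silences the
#'   network (silence is absorbing because matched potentiation needs post
#'   spikes)
#' @export
setClass("STDPParams",
  representation(aPlus = "numeric", aMinus = "numeric", tauPlus = "numeric",
                 tauMinus = "numeric", wMin = "numeric", wMax = "numeric",
                 rewardMatched = "numeric", rewardMismatched = "numeric"))

setValidity("STDPParams", function(object) {
  msg <- character(0)
  if (any(c(object@aPlus, object@aMinus, object@tauPlus, object@tauMinus) <= 0))
    msg <- c(msg, "aPlus, aMinus, tauPlus, tauMinus must all be > 0")
  if (object@wMin >= object@wMax) msg <- c(msg, "need wMin < wMax")
  if (length(msg)) msg else TRUE
})

#' @param aPlus,aMinus,tauPlus,tauMinus,wMin,wMax,rewardMatched,rewardMismatched
#'   see slot documentation.
#' @return An \code{STDPParams} object.
#' @rdname STDPParams-class
#' @export
STDPParams <- function(aPlus = 0.005, aMinus = 1.05 * aPlus, tauPlus = 20,
                       tauMinus = 20, wMin = 0, wMax = 1,
                       rewardMatched = 1, rewardMismatched = -0.15) {
  new("STDPParams", aPlus = aPlus, aMinus = aMinus, tauPlus = tauPlus,
      tauMinus = tauMinus, wMin = wMin, wMax = wMax,
      rewardMatched = rewardMatched, rewardMismatched = rewardMismatched)
}

#' Coincidence-gated synapse growth rule
#'
#' Hebbian structural-plasticity rule for the memory layer: a new synapse
#' i -> j is created once the cumulative number of strictly causal spike pairs
#' (0 < t_j - t_i <= coincidenceWindow) between grid neighbours (Chebyshev
#' distance <= neighborhoodRadius) reaches \code{coincidenceThreshold}.
#' Synapses are never removed.
#'
#' @slot coincidenceWindow causal coincidence window, ms
#' @slot coincidenceThreshold cumulative pair count needed to grow a synapse
#' @slot neighborhoodRadius Chebyshev radius on the memory grid
#' @slot initialWeight weight assigned to a newly grown synapse
#' @export
setClass("GrowthRule",
  representation(coincidenceWindow = "numeric", coincidenceThreshold = "integer",
                 neighborhoodRadius = "integer", initialWeight = "numeric"))

setValidity("GrowthRule", function(object) {
  msg <- character(0)
  if (object@coincidenceWindow <= 0) msg <- c(msg, "coincidenceWindow must be > 0")
  if (object@coincidenceThreshold < 1L) msg <- c(msg, "coincidenceThreshold must be >= 1")
  if (object@neighborhoodRadius < 1L) msg <- c(msg, "neighborhoodRadius must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param coincidenceWindow,coincidenceThreshold,neighborhoodRadius,initialWeight
#'   see slot documentation.
#' @return A \code{GrowthRule} object.
#' @rdname GrowthRule-class
#' @export
GrowthRule <- function(coincidenceWindow = 10, coincidenceThreshold = 2L,
                       neighborhoodRadius = 3L, initialWeight = 0.5) {
  new("GrowthRule", coincidenceWindow = coincidenceWindow,
      coincidenceThreshold = as.integer(coincidenceThreshold),
      neighborhoodRadius = as.integer(neighborhoodRadius),
      initialWeight = initialWeight)
}

#' A labelled set of 28x28 grayscale digit images
#'
#' @slot images 28 x 28 x n integer array, values 0-255 (0 = background,
#'   255 = brightest stroke)
#' @slot labels integer vector of digits 0-9, one per image
#' @slot seed seed the set was generated with (NA for file-loaded sets)
#' @export
setClass("LabeledImageSet",
  representation(images = "array", labels = "integer", seed = "integer"))

setValidity("LabeledImageSet", function(object) {
  d <- dim(object@images)
  msg <- character(0)
  if (length(d) != 3 || d[1] != 28 || d[2] != 28)
    msg <- c(msg, "images must be a 28 x 28 x n array")
  else if (d[3] != length(object@labels))
    msg <- c(msg, "images and labels must have the same length")
  if (length(object@labels) && (min(object@labels) < 0L || max(object@labels) > 9L))
    msg <- c(msg, "labels must lie in 0..9")
  r <- range(object@images)
  if (r[1] < 0 || r[2] > 255) msg <- c(msg, "pixel values must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' Feed-forward spiking network specification
#'
#' Wiring, plastic weights, and all physiological parameters of the two-layer
#' (784 relay inputs -> 10 LIF outputs) or three-layer (conv/pool preprocessed
#' 576-neuron memory layer -> 10 outputs) network. Noise generators attach
#' one-to-one to the neurons listed in \code{noiseTargets}.
#'
#' @slot type "two-layer" or "three-layer"
#' @slot nIn,nOut layer sizes of the plastic projection
#' @slot weights nIn x nOut plastic weight matrix
#' @slot lif,stdp,encoding,noise parameter objects
#' @slot noiseTargets input/memory neuron indices with an attached generator
#' @slot dt simulation resolution, ms
#' @slot synCurrent delta-pulse amplitude at weight 1, pA (held for one dt)
#' @slot gapMs silent gap appended after the encoding window, ms
#' @slot seed seed for initial weights and generator streams
#' @slot filters list of 4x4 convolution kernels (three-layer only)
#' @slot pooling "max" or "mean" (three-layer only)
#' @slot imageShape expected raw image shape
#' @export
setClass("SpikingNetwork",
  representation(type = "character", nIn = "integer", nOut = "integer",
                 weights = "matrix", lif = "LIFParams", stdp = "STDPParams",
                 encoding = "EncodingParams", noise = "NoiseParams",
                 noiseTargets = "integer", dt = "numeric",
                 synCurrent = "numeric", gapMs = "numeric", seed = "integer",
                 filters = "list", pooling = "character",
                 imageShape = "integer"))

setValidity("SpikingNetwork", function(object) {
  msg <- character(0)
  if (!object@type %in% c("two-layer", "three-layer"))
    msg <- c(msg, "type must be 'two-layer' or 'three-layer'")
  if (!identical(dim(object@weights), c(object@nIn, object@nOut)))
    msg <- c(msg, "weights must be an nIn x nOut matrix")
  if (any(object@weights < object@stdp@wMin - 1e-12) ||
      any(object@weights > object@stdp@wMax + 1e-12))
    msg <- c(msg, "weights must lie within [wMin, wMax]")
  if (length(object@noiseTargets) &&
      (min(object@noiseTargets) < 1L || max(object@noiseTargets) > object@nIn))
    msg <- c(msg, "noiseTargets out of range")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (length(msg)) msg else TRUE
})

#' Report of one structural-growth run
#'
#' @slot condition "a" (stimulus only), "b" (noise only), or "c" (both)
#' @slot nSynapses number of synapses grown
#' @slot synapseMap data.frame of grown synapses with pre/post indices and
#'   24x24 grid coordinates
#' @slot noiseMap integer indices of memory neurons wired to a generator
#' @slot incidentCounts per-neuron count of incident grown synapses (length 576)
#' @slot seed,nPresentations run conditions
#' @export
setClass("GrowthReport",
  representation(condition = "character", nSynapses = "integer",
                 synapseMap = "data.frame", noiseMap = "integer",
                 incidentCounts = "integer", seed = "integer",
                 nPresentations = "integer"))

setValidity("GrowthReport", function(object) {
  msg <- character(0)
  if (object@nSynapses != nrow(object@synapseMap))
    msg <- c(msg, "nSynapses must equal nrow(synapseMap)")
  if (!object@condition %in% c("a", "b", "c"))
    msg <- c(msg, "condition must be one of 'a', 'b', 'c'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LIFParams", function(object) {
  cat(sprintf(
    "LIFParams: tau_m=%g ms, C_m=%g pF (R=%g MOhm), E_L=%g mV, V_th=%g mV, V_reset=%g mV, t_ref=%g ms\n",
    object@tauM, object@cM, membraneResistance(object), object@eL,
    object@vTh, object@vReset, object@tRef))
})

setMethod("show", "NoiseParams", function(object) {
  cat(sprintf("NoiseParams: mu=%g pA, sigma=%g pA, refresh=%g ms, seed=%d\n",
              object@mu, object@sigma, object@refreshDt, object@seed))
})

setMethod("show", "EncodingParams", function(object) {
  cat(sprintf("EncodingParams: window [%g, %g] ms (bright -> early)\n",
              object@tStart, object@tStop))
})

setMethod("show", "STDPParams", function(object) {
  cat(sprintf(
    "STDPParams: A+=%g, A-=%g, tau+=%g ms, tau-=%g ms, bounds [%g, %g], rewards (%+g matched, %+g mismatched)\n",
    object@aPlus, object@aMinus, object@tauPlus, object@tauMinus,
    object@wMin, object@wMax, object@rewardMatched, object@rewardMismatched))
})

setMethod("show", "GrowthRule", function(object) {
  cat(sprintf(
    "GrowthRule: window=%g ms, threshold=%d causal pairs, radius=%d (Chebyshev), w_init=%g\n",
    object@coincidenceWindow, object@coincidenceThreshold,
    object@neighborhoodRadius, object@initialWeight))
})

setMethod("show", "LabeledImageSet", function(object) {
  cat(sprintf("LabeledImageSet: %d images (28x28, 0-255), labels 0-9, seed=%s\n",
              length(object@labels),
              ifelse(is.na(object@seed), "NA", object@seed)))
})

setMethod("show", "SpikingNetwork", function(object) {
  cat(sprintf("SpikingNetwork (%s): %d -> %d, %d plastic synapses\n",
              object@type, object@nIn, object@nOut,
              object@nIn * object@nOut))
  cat(sprintf("  noise generators on %d neurons (mu=%g pA, sigma=%g pA)\n",
              length(object@noiseTargets), object@noise@mu, object@noise@sigma))
  cat(sprintf("  dt=%g ms, synaptic pulse %g pA at w=1, gap %g ms, seed=%d\n",
              object@dt, object@synCurrent, object@gapMs, object@seed))
})

setMethod("show", "GrowthReport", function(object) {
  cat(sprintf(
    "GrowthReport (condition %s): %d synapses grown over %d presentations (seed %d); %d noisy neurons\n",
    object@condition, object@nSynapses, object@nPresentations, object@seed,
    length(object@noiseMap)))
})
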