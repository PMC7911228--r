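#' Memory-layer grid geometry
#'
#' Maps the channel-major memory neuron index onto a single square grid: the
#' \code{nFilters} 12x12 channels are tiled two per row (channel 1 top-left,
#' 2 top-right, 3 bottom-left, 4 bottom-right), giving a 24x24 coordinate
#' map for 4 channels. The growth neighbourhood (Chebyshev distance) and the
#' dot-map export both live on these global coordinates.
#'
#' @param nFilters number of 12x12 channels
#' @return data.frame with columns neuron, channel, row, col, gRow, gCol
#' @export
memoryGeometry <- function(nFilters = 4) {
  neuron <- seq_len(nFilters * 144)
  channel <- (neuron - 1) %/% 144 + 1
  within <- (neuron - 1) %% 144
  col <- within %/% 12 + 1
  row <- within %% 12 + 1
  tileRow <- (channel - 1) %/% 2
  tileCol <- (channel - 1) %% 2
  data.frame(neuron = neuron, channel = channel, row = row, col = col,
             gRow = row + 12 * tileRow, gCol = col + 12 * tileCol)
}

#' Candidate synapse pairs within a grid neighbourhood
#'
#' All ordered pairs (i, j), i != j, whose global grid coordinates are within
#' the given Chebyshev radius.
#'
#' @param geometry a geometry table from [memoryGeometry()] (or any
#'   data.frame with neuron, gRow, gCol)
#' @param radius Chebyshev radius
#' @return data.frame with columns i, j
#' @export
neighborPairs <- function(geometry, radius) {
  maxR <- max(geometry$gRow); maxC <- max(geometry$gCol)
  lut <- matrix(NA_integer_, maxR, maxC)
  lut[cbind(geometry$gRow, geometry$gCol)] <- geometry$neuron
  iAll <- integer(0); jAll <- integer(0)
  for (dr in -radius:radius) for (dc in -radius:radius) {
    if (dr == 0 && dc == 0) next
    r <- geometry$gRow + dr; cc <- geometry$gCol + dc
    ok <- r >= 1 & r <= maxR & cc >= 1 & cc <= maxC
    j <- lut[cbind(r[ok], cc[ok])]
    keep <- !is.na(j)
    iAll <- c(iAll, geometry$neuron[ok][keep])
    jAll <- c(jAll, j[keep])
  }
  data.frame(i = iAll, j = jAll)
}

#' One structural-growth step
#'
#' For every ordered neighbour pair (i, j) without an existing synapse,
#' counts spike pairs with 0 < t_j - t_i <= coincidenceWindow in the given
#' trains (one presentation), adds them to the cumulative coincidence
#' accumulator, and creates the synapse i -> j at \code{initialWeight} once
#' the cumulative count reaches the threshold. Causal order is respected
#' (simultaneous spikes never count) and synapses are never removed.
#'
#' @param spikes data.frame with columns neuron, time (ms) for one
#'   presentation window
#' @param existing logical n x n adjacency matrix of existing synapses
#' @param rule a [GrowthRule]
#' @param geometry memory geometry (used to derive the neighbourhood when
#'   \code{pairs} is not supplied)
#' @param counts integer n x n cumulative coincidence accumulator (NULL for a
#'   fresh one)
#' @param pairs optional precomputed candidate pair table from
#'   [neighborPairs()]
#' @return list with updated \code{synapses}, \code{counts}, and a
#'   data.frame \code{new} of synapses created in this step
#' @export
growStep <- function(spikes, existing, rule, geometry = memoryGeometry(),
                     counts = NULL, pairs = NULL) {
  n <- nrow(existing)
  if (is.null(counts)) counts <- matrix(0L, n, n)
  if (is.null(pairs)) pairs <- neighborPairs(geometry, rule@neighborhoodRadius)
  newSyn <- data.frame(pre = integer(0), post = integer(0))
  if (nrow(spikes) > 0) {
    sp <- data.table::as.data.table(spikes)
    data.table::setnames(sp, c("neuron", "time"), c("n", "t"))
    P <- data.table::as.data.table(pairs)
    A <- merge(P, sp, by.x = "i", by.y = "n", allow.cartesian = TRUE)
    data.table::setnames(A, "t", "ti")
    A <- merge(A, sp, by.x = "j", by.y = "n", allow.cartesian = TRUE)
    data.table::setnames(A, "t", "tj")
    A <- A[A$tj - A$ti > 1e-9 & A$tj - A$ti <= rule@coincidenceWindow + 1e-9, ]
    if (nrow(A)) {
      tal <- A[, list(hits = .N), by = c("i", "j")]
      idx <- cbind(tal$i, tal$j)
      counts[idx] <- counts[idx] + tal$hits
      ready <- counts[idx] >= rule@coincidenceThreshold & !existing[idx]
      if (any(ready)) {
        newIdx <- idx[ready, , drop = FALSE]
        existing[newIdx] <- TRUE
        newSyn <- data.frame(pre = newIdx[, 1], post = newIdx[, 2])
      }
    }
  }
  list(synapses = existing, counts = counts, new = newSyn)
}

#' Run one condition of the synapse-growth experiment
#'
#' Wires the three-layer memory grid, simulates \code{nPresentations}
#' consecutive presentation windows in continuous time, applies the growth
#' rule after each presentation, and reports the grown synapses:
#' \itemize{
#' \item condition "a": image stimuli only (generators wired but silent);
#' \item condition "b": noise only, no image input;
#' \item condition "c": both image stimuli and noise.
#' }
#' Memory neurons bound to image pixels emit forced spikes at the encoded
#' latencies; neurons with an attached generator additionally integrate the
#' noise current (default mu = 400 pA, sigma = 0: a suprathreshold constant
#' drive, since the rheobase is 375 pA) and fire whenever they cross
#' threshold. Initial membrane potentials are drawn uniform on
#' [V_reset, V_th) under the run seed, desynchronizing the noise-driven
#' neurons.
#'
#' @param condition "a", "b" or "c"
#' @param dataset a [LabeledImageSet] (ignored for condition "b"); images are
#'   cycled over the presentations
#' @param noise a [NoiseParams]; default mu = 400 pA, sigma = 0
#' @param nPresentations number of presentation windows
#' @param seed run seed (noise target choice, initial potentials, streams)
#' @param rule a [GrowthRule]
#' @param lif,encoding parameter objects
#' @param dt resolution, ms
#' @param gapMs silent gap after the encoding window, ms
#' @param nFilters number of channels
#' @param filters convolution kernels
#' @param pooling "max" or "mean"
#' @param nNoise number of attached generators (default round(0.2 * 576))
#' @param priorDensity density of a random pre-existing lateral synapse mask
#'   (default 0: none)
#' @return a [GrowthReport]
#' @export
runGrowthExperiment <- function(condition = c("a", "b", "c"), dataset = NULL,
                                noise = NoiseParams(mu = 400, sigma = 0),
                                nPresentations = 20L, seed = 0L,
                                rule = GrowthRule(), lif = LIFParams(),
                                encoding = EncodingParams(), dt = 0.1,
                                gapMs = 5, nFilters = 4,
                                filters = defaultKernels(nFilters),
                                pooling = "max",
                                nNoise = round(0.2 * nFilters * 144),
                                priorDensity = 0) {
  condition <- match.arg(condition)
  n <- nFilters * 144L
  geometry <- memoryGeometry(nFilters)
  pairs <- neighborPairs(geometry, rule@neighborhoodRadius)
  useImages <- condition %in% c("a", "c")
  useNoise <- condition %in% c("b", "c")
  if (useImages && (is.null(dataset) || length(dataset@labels) == 0))
    stop("conditions 'a' and 'c' need a non-empty dataset")

  targets <- if (nNoise > 0) {
    withr::with_seed(deriveSeed(seed, 11), sort(sample.int(n, nNoise)))
  } else integer(0)
  u0 <- withr::with_seed(deriveSeed(seed, 12),
                         stats::runif(n, lif@vReset, lif@vTh))
  noiseRun <- NoiseParams(mu = noise@mu, sigma = noise@sigma,
                          refreshDt = noise@refreshDt,
                          seed = deriveSeed(seed, 13))

  synapses <- matrix(FALSE, n, n)
  if (priorDensity > 0) {
    pick <- withr::with_seed(deriveSeed(seed, 14),
                             stats::runif(nrow(pairs)) < priorDensity)
    synapses[cbind(pairs$i[pick], pairs$j[pick])] <- TRUE
  }
  preexisting <- which(synapses, arr.ind = TRUE)
  counts <- matrix(0L, n, n)
  grown <- data.frame(pre = integer(0), post = integer(0))

  period <- encoding@tStop + gapMs
  nSteps <- as.integer(round(period / dt))
  state <- list(u = u0, refUntil = rep(-Inf, n))
  nImg <- if (useImages) dim(dataset@images)[3] else 0L

  for (p in seq_len(nPresentations)) {
    t0 <- (p - 1) * period
    forced <- rep(NA_real_, n)
    if (useImages) {
      img <- dataset@images[, , ((p - 1) %% nImg) + 1]
      pp <- preprocessChannels(img, nFilters, filters, pooling)
      forced <- t0 + quantizeTime(as.vector(encodePixel(pp$values, encoding)), dt)
      # tailoring: pixels without a positive filter response carry no
      # information and do not drive their memory neuron, leaving those
      # neurons free to respond to the background-noise current
      forced[!as.vector(pp$active)] <- NA_real_
    }
    if (useNoise && length(targets)) {
      Imat <- matrix(0, n, nSteps)
      Imat[targets, ] <- noiseCurrentMatrix(noiseRun, targets, nSteps)
      forcedStepList <- NULL
      keep <- which(!is.na(forced))
      if (length(keep))
        forcedStepList <- split(keep, as.integer(round((forced[keep] - t0) / dt)))
      res <- runLayerGrid(n, lif, nSteps, dt, t0, Imat, forcedStepList, state)
    } else {
      res <- simulateRelayLayer(n, lif, forced, period, dt, t0 = t0,
                                state = state)
    }
    state <- if (is.null(res$state)) state else res$state
    g <- growStep(res$spikes, synapses, rule, geometry, counts, pairs)
    synapses <- g$synapses
    counts <- g$counts
    if (nrow(g$new)) grown <- rbind(grown, g$new)
  }

  synMap <- data.frame(
    pre = grown$pre, post = grown$post,
    preRow = geometry$gRow[grown$pre], preCol = geometry$gCol[grown$pre],
    postRow = geometry$gRow[grown$post], postCol = geometry$gCol[grown$post])
  incident <- integer(n)
  if (nrow(grown)) {
    tab <- table(factor(c(grown$pre, grown$post), levels = seq_len(n)))
    incident <- as.integer(tab)
  }
  new("GrowthReport", condition = condition, nSynapses = nrow(synMap),
      synapseMap = synMap, noiseMap = as.integer(targets),
      incidentCounts = incident, seed = as.integer(seed),
      nPresentations = as.integer(nPresentations))
}

#' Export a growth report as plottable tables
#'
#' Writes (or returns) the per-synapse map and the per-neuron dot map
#' (incident synapse counts plus noise-attachment flags) as CSV-ready
#' data.frames for replotting the growth dot maps.
#'
#' @param report a [GrowthReport]
#' @param synapsePath,neuronPath optional CSV paths
#' @return list with \code{synapses} and \code{neurons} data.frames
#' @export
growthReportTables <- function(report, synapsePath = NULL, neuronPath = NULL) {
  geo <- memoryGeometry()
  neurons <- data.frame(neuron = geo$neuron, gRow = geo$gRow, gCol = geo$gCol,
                        noisy = geo$neuron %in% report@noiseMap,
                        incidentSynapses = report@incidentCounts)
  if (!is.null(synapsePath))
    utils::write.csv(report@synapseMap, synapsePath, row.names = FALSE)
  if (!is.null(neuronPath))
    utils::write.csv(neurons, neuronPath, row.names = FALSE)
  list(synapses = report@synapseMap, neurons = neurons)
}
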