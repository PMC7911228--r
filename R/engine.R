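# Internal simulation engines.
#
# Two code paths are used for a layer of relay/LIF neurons that receive
# forced (encoded) spikes plus optional per-neuron noise currents:
#
# * an exact shortcut when no membrane trajectory can reach threshold
#   (no generator attached, or sigma = 0 with a subthreshold fixed point):
#   the emitted spikes are then exactly the forced spike times, which is the
#   closed-form solution, not an approximation;
# * a per-step grid simulation (exact exponential update, identical to
#   stepNeuron but vectorized across neurons) whenever noise can fire neurons.

# Grid simulation of n neurons over nSteps. `Imat` is n x nSteps (or NULL for
# zero current), `forcedStepList` maps step index (0 = at t0) to neuron
# indices forced to spike at that boundary. State carries (u, refUntil)
# across calls for continuous-time runs.
runLayerGrid <- function(n, lif, nSteps, dt, t0, Imat = NULL,
                         forcedStepList = NULL, state = NULL) {
  if (is.null(state)) state <- list(u = rep(lif@eL, n), refUntil = rep(-Inf, n))
  u <- state$u
  refUntil <- state$refUntil
  decay <- exp(-dt / lif@tauM)
  rm_ <- membraneResistance(lif) / 1000
  spkNeuron <- vector("list", nSteps + 1)
  spkTime <- vector("list", nSteps + 1)

  fireAt <- function(idx, tNow) {
    if (length(idx)) {
      u[idx] <<- lif@vReset
      refUntil[idx] <<- tNow + lif@tRef
    }
    idx
  }

  # forced spikes landing exactly on the start boundary t0
  f0 <- forcedStepList[["0"]]
  if (!is.null(f0)) {
    f0 <- f0[!(t0 < refUntil[f0] - 1e-9)]
    idx <- fireAt(f0, t0)
    if (length(idx)) { spkNeuron[[1]] <- idx; spkTime[[1]] <- rep(t0, length(idx)) }
  }

  for (k in seq_len(nSteps)) {
    now <- t0 + (k - 1) * dt
    tEnd <- now + dt
    refr <- now < refUntil - 1e-9
    I <- if (is.null(Imat)) 0 else Imat[, k]
    uinf <- lif@eL + rm_ * I
    un <- uinf + (u - uinf) * decay
    un[refr] <- lif@vReset
    fire <- !refr & (un > lif@vTh)
    fk <- forcedStepList[[as.character(k)]]
    if (!is.null(fk)) {
      fk <- fk[!refr[fk]]
      fire[fk] <- TRUE
    }
    u <- un
    if (any(fire)) {
      idx <- which(fire)
      u[idx] <- lif@vReset
      refUntil[idx] <- tEnd + lif@tRef
      spkNeuron[[k + 1]] <- idx
      spkTime[[k + 1]] <- rep(tEnd, length(idx))
    }
  }
  list(
    spikes = data.frame(neuron = unlist(spkNeuron), time = unlist(spkTime)),
    state = list(u = u, refUntil = refUntil))
}

# TRUE when membrane integration alone can never produce a spike for any
# attached generator, so the layer's output is exactly its forced spikes.
layerNoiseSilent <- function(lif, noise, noiseTargets) {
  if (length(noiseTargets) == 0) return(TRUE)
  noise@sigma == 0 && steadyStatePotential(lif, noise@mu) <= lif@vTh
}

# Simulate a relay layer for one presentation window [t0, t0 + duration).
# `forcedTimes`: numeric vector, one (already grid-quantized, absolute) spike
# time per neuron, or NA for silent neurons.
simulateRelayLayer <- function(n, lif, forcedTimes, duration, dt, t0 = 0,
                               noise = NULL, noiseTargets = integer(0),
                               state = NULL) {
  if (is.null(noise) || layerNoiseSilent(lif, noise, noiseTargets)) {
    keep <- which(!is.na(forcedTimes))
    sp <- data.frame(neuron = keep, time = forcedTimes[keep])
    sp <- sp[order(sp$time, sp$neuron), , drop = FALSE]
    rownames(sp) <- NULL
    return(list(spikes = sp, state = state))
  }
  nSteps <- as.integer(round(duration / dt))
  Imat <- NULL
  if (length(noiseTargets)) {
    Imat <- matrix(0, nrow = n, ncol = nSteps)
    Imat[noiseTargets, ] <- noiseCurrentMatrix(noise, noiseTargets, nSteps)
  }
  forcedStepList <- NULL
  keep <- which(!is.na(forcedTimes))
  if (length(keep)) {
    stepIdx <- as.integer(round((forcedTimes[keep] - t0) / dt))
    forcedStepList <- split(keep, stepIdx)
  }
  runLayerGrid(n, lif, nSteps, dt, t0, Imat, forcedStepList, state)
}

# Event-driven exact simulation of the output layer for one presentation.
# Each presynaptic spike at (grid) time t delivers a delta-current pulse of
# amplitude w * synCurrent held for one dt, i.e. a membrane jump of
# w * R * synCurrent * (1 - exp(-dt/tau)) visible at t + dt; between jumps
# the membrane decays exactly toward E_L. Equivalent to the grid integrator,
# but stepping only at input events.
runOutputLayer <- function(weights, inputSpikes, lif, dt, synCurrent, tEnd,
                           t0 = 0) {
  nOut <- ncol(weights)
  trains <- rep(list(numeric(0)), nOut)
  events <- list(times = numeric(0), nInputs = integer(0))
  if (nrow(inputSpikes) == 0)
    return(list(trains = trains, events = events))

  kick <- membraneResistance(lif) * synCurrent / 1000 * (1 - exp(-dt / lif@tauM))
  grp <- match(inputSpikes$time, sort(unique(inputSpikes$time)))
  drive <- rowsum(weights[inputSpikes$neuron, , drop = FALSE], group = grp)
  gTimes <- sort(unique(inputSpikes$time))
  nPerGroup <- tabulate(grp, nbins = length(gTimes))

  u <- rep(lif@eL, nOut)
  refUntil <- rep(-Inf, nOut)
  tLast <- t0
  for (g in seq_along(gTimes)) {
    te <- gTimes[g] + dt           # jump lands at the end of the pulse step
    if (te > tEnd + 1e-9) break
    refr <- (te - dt) < refUntil - 1e-9
    start <- pmax(tLast, pmin(refUntil, te))
    u0 <- ifelse(refUntil > tLast, lif@vReset, u)
    un <- lif@eL + (u0 - lif@eL) * exp(-(te - start) / lif@tauM)
    un <- un + ifelse(refr, 0, kick * drive[g, ])
    un[refr] <- lif@vReset
    fire <- !refr & (un > lif@vTh)
    if (any(fire)) {
      for (j in which(fire)) trains[[j]] <- c(trains[[j]], te)
      un[fire] <- lif@vReset
      refUntil[fire] <- te + lif@tRef
    }
    u <- un
    tLast <- te
  }
  list(trains = trains,
       events = list(times = gTimes, nInputs = nPerGroup))
}
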