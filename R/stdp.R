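#' Pair-based STDP window
#'
#' The piecewise exponential f(dt) = A+ exp(-dt/tau+) for dt > 0 (LTP,
#' causal pre-before-post) and -A- exp(dt/tau-) for dt < 0 (LTD, anticausal).
#' f(0) is defined as 0: the two branch limits disagree and simultaneous
#' spikes carry no causal order.
#'
#' @param deltaT post-minus-pre spike time difference(s), ms
#' @param params an [STDPParams] object
#' @return weight change(s), dimensionless
#' @export
stdpWindow <- function(deltaT, params = STDPParams()) {
  out <- numeric(length(deltaT))
  pos <- deltaT > 0
  neg <- deltaT < 0
  out[pos] <- params@aPlus * exp(-deltaT[pos] / params@tauPlus)
  out[neg] <- -params@aMinus * exp(deltaT[neg] / params@tauMinus)
  dim(out) <- dim(deltaT)
  out
}

#' All-pairs STDP weight change for one synapse
#'
#' Double sum of the STDP window over every (pre, post) spike pair of one
#' presentation: Delta w = sum_a sum_b f(t_post_b - t_pre_a).
#'
#' @param pre,post numeric vectors of spike times, ms
#' @param params an [STDPParams] object
#' @return scalar weight change
#' @export
pairWeightChange <- function(pre, post, params = STDPParams()) {
  if (length(pre) == 0 || length(post) == 0) return(0)
  sum(stdpWindow(outer(post, pre, "-"), params))
}

# Fast path used by the training loop: pair sums for every input synapse onto
# one output neuron, from flattened pre spikes (preIdx / preT) and that
# output's post spike times. Returns a length-nIn vector.
pairSumsPerInput <- function(preIdx, preT, postT, nIn, params) {
  d <- numeric(nIn)
  if (length(preT) == 0 || length(postT) == 0) return(d)
  m <- stdpWindow(outer(preT, postT, function(a, b) b - a), params)
  s <- if (is.matrix(m)) rowSums(m) else m
  agg <- rowsum(s, group = preIdx)
  d[as.integer(rownames(agg))] <- agg[, 1]
  d
}

#' Supervised (reward-modulated) STDP update of a projection
#'
#' Implements the match/mismatch rule: synapses onto the true-label output
#' neuron receive \code{rewardMatched * pairWeightChange}; synapses onto any
#' other output that spiked during the presentation receive
#' \code{rewardMismatched * |pairWeightChange|} (the pair-sum magnitude keeps
#' the update timing-sensitive). All weights are then clipped to
#' [wMin, wMax]. Outputs that stayed silent, other than the true label, are
#' untouched.
#'
#' @param weights nIn x nOut weight matrix
#' @param preTrains list of nIn numeric vectors (input spike times, ms)
#' @param postTrains list of nOut numeric vectors (output spike times, ms)
#' @param trueLabel integer in [0, nOut)
#' @param params an [STDPParams] object
#' @return the updated weight matrix
#' @export
supervisedUpdate <- function(weights, preTrains, postTrains, trueLabel,
                             params = STDPParams()) {
  nIn <- nrow(weights); nOut <- ncol(weights)
  stopifnot(length(preTrains) == nIn, length(postTrains) == nOut)
  if (!(is.numeric(trueLabel) && length(trueLabel) == 1 &&
        trueLabel >= 0 && trueLabel < nOut))
    stop("trueLabel must lie in [0, nOut)")
  nPre <- lengths(preTrains)
  preIdx <- rep(seq_len(nIn), nPre)
  preT <- unlist(preTrains, use.names = FALSE)
  for (j in seq_len(nOut)) {
    lab <- j - 1L
    spiked <- length(postTrains[[j]]) > 0
    if (lab == trueLabel) {
      d <- pairSumsPerInput(preIdx, preT, postTrains[[j]], nIn, params)
      weights[, j] <- weights[, j] + params@rewardMatched * d
    } else if (spiked) {
      d <- pairSumsPerInput(preIdx, preT, postTrains[[j]], nIn, params)
      weights[, j] <- weights[, j] + params@rewardMismatched * abs(d)
    }
  }
  clip(weights, params@wMin, params@wMax)
}
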