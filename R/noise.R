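#' Draw a piecewise-constant Gaussian noise current trace
#'
#' One value per refresh interval: I_k = mu + sigma * eta_k with eta_k
#' independent standard-normal draws from the generator's own seeded stream.
#' The value is held constant within each interval and added to the
#' deterministic drive, realizing the Langevin forcing term. As in the NEST
#' noise generator, draws are per-interval and NOT scaled by 1/sqrt(dt), so
#' the effective noise variance of the integrated membrane depends on the
#' refresh interval; this deviates from a true Wiener (white-noise)
#' discretization on purpose.
#'
#' @param params a [NoiseParams] object
#' @param duration trace length, ms (must be > 0)
#' @param dt refresh interval override, ms (default: \code{params@refreshDt})
#' @return numeric vector of currents in pA, one per interval
#' @export
drawCurrentTrace <- function(params, duration, dt = params@refreshDt) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0")
  n <- as.integer(ceiling(duration / dt - 1e-9))
  if (params@sigma == 0) return(rep(params@mu, n))
  withr::with_seed(params@seed, params@mu + params@sigma * stats::rnorm(n))
}

# Per-neuron noise current matrix (neurons x steps). Each attached neuron
# gets its own seed stream derived from the generator seed and its index,
# mirroring the one-to-one generator -> neuron wiring.
noiseCurrentMatrix <- function(params, neurons, nSteps) {
  m <- matrix(params@mu, nrow = length(neurons), ncol = nSteps)
  if (params@sigma > 0) {
    for (i in seq_along(neurons)) {
      s <- deriveSeed(params@seed, neurons[i])
      m[i, ] <- withr::with_seed(s, params@mu + params@sigma * stats::rnorm(nSteps))
    }
  }
  m
}
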