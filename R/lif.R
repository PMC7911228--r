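#' Membrane resistance derived from the time constant and capacitance
#'
#' R = tau_m / C_m (equivalently 1/g_l with g_l the leak conductance), in
#' MOhm. With the default parameters R = 40 MOhm, so a current of I pA drives
#' the membrane fixed point to E_L + 0.04 * I mV.
#'
#' @param params a [LIFParams] object
#' @return resistance in MOhm
#' @export
membraneResistance <- function(params) 1000 * params@tauM / params@cM

# Fixed point of the membrane for a constant current I (pA), in mV.
steadyStatePotential <- function(params, I) {
  params@eL + membraneResistance(params) * I / 1000
}

#' Minimal constant current whose membrane fixed point reaches threshold
#'
#' rheobase = C_m (V_th - E_L) / tau_m. At exactly this current the fixed
#' point equals V_th and the exact update approaches it strictly from below,
#' so the neuron never fires; any constant current above it fires in finite
#' time. 375 pA for the default parameters.
#'
#' @param params a [LIFParams] object
#' @return current in pA
#' @export
rheobase <- function(params) {
  params@cM * (params@vTh - params@eL) / params@tauM
}

#' Analytic subthreshold membrane trajectory
#'
#' Closed-form solution of the membrane equation for a constant current,
#' u(t) = E_L + R I + (u0 - E_L - R I) exp(-t / tau_m), valid while no spike
#' occurs. Serves as the exact oracle for the stepped integrator.
#'
#' @param params a [LIFParams] object
#' @param u0 initial potential, mV
#' @param I constant current, pA
#' @param t elapsed time, ms (vectorized)
#' @return membrane potential(s) in mV
#' @export
closedFormPotential <- function(params, u0, I, t) {
  stopifnot(all(t >= 0))
  uinf <- steadyStatePotential(params, I)
  uinf + (u0 - uinf) * exp(-t / params@tauM)
}

#' Analytic time to threshold under a constant current
#'
#' tau_m * log((u_inf - u0) / (u_inf - V_th)) when the fixed point u_inf
#' exceeds threshold, Inf otherwise.
#'
#' @inheritParams closedFormPotential
#' @return time in ms (Inf if the neuron never reaches threshold)
#' @export
timeToThreshold <- function(params, u0, I) {
  uinf <- steadyStatePotential(params, I)
  if (uinf <= params@vTh || u0 > params@vTh) {
    if (u0 > params@vTh) return(0)
    return(Inf)
  }
  params@tauM * log((uinf - u0) / (uinf - params@vTh))
}

#' Fresh neuron state at rest
#'
#' @param params a [LIFParams] object
#' @param u0 initial membrane potential, mV (default: resting potential)
#' @return a list with elements \code{u} (mV), \code{refractoryUntil} (ms) and
#'   \code{spikes} (numeric vector of spike times, ms)
#' @export
newNeuronState <- function(params, u0 = params@eL) {
  list(u = u0, refractoryUntil = -Inf, spikes = numeric(0))
}

#' Advance one neuron by a single time step (exact exponential update)
#'
#' The input current is held constant over \code{[now, now + dt)} and the
#' membrane is advanced with the exact solution
#' u' = u_inf + (u - u_inf) exp(-dt / tau_m), u_inf = E_L + R I. If u'
#' strictly exceeds V_th and the neuron is not refractory, a spike is recorded
#' at \code{now + dt}, the membrane is reset to V_reset, and the neuron stays
#' clamped at V_reset for t_ref. Threshold crossing is strict (u' > V_th):
#' at exactly rheobase the trajectory approaches V_th from below and must
#' never fire, which a non-strict test would violate once the approach falls
#' below double-precision resolution.
#'
#' @param state a neuron state as returned by [newNeuronState()]
#' @param params a [LIFParams] object
#' @param I total input current over the step, pA
#' @param dt step length, ms (must be > 0)
#' @param now time at the start of the step, ms
#' @return the advanced state
#' @export
stepNeuron <- function(state, params, I, dt, now) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number")
  tEnd <- now + dt
  if (now < state$refractoryUntil - 1e-9) {
    state$u <- params@vReset
    return(state)
  }
  uinf <- steadyStatePotential(params, I)
  u <- uinf + (state$u - uinf) * exp(-dt / params@tauM)
  if (u > params@vTh) {
    state$spikes <- c(state$spikes, tEnd)
    u <- params@vReset
    state$refractoryUntil <- tEnd + params@tRef
  }
  state$u <- u
  state
}

#' Simulate one neuron over a time span
#'
#' Steps the exact exponential update over \code{duration} ms. The current may
#' be a scalar (constant) or a vector with one value per step (piecewise
#' constant input, e.g. a noise trace from [drawCurrentTrace()]).
#'
#' @param params a [LIFParams] object
#' @param I input current, pA: scalar or vector of length \code{duration/dt}
#' @param duration simulated time, ms
#' @param dt step length, ms
#' @param u0 initial membrane potential, mV
#' @return a list with \code{times} (step boundaries incl. 0), \code{u}
#'   (membrane trace at those times), and \code{spikes} (spike times, ms)
#' @export
simulateNeuron <- function(params, I, duration, dt = 0.1, u0 = params@eL) {
  nSteps <- as.integer(round(duration / dt))
  if (length(I) == 1) I <- rep(I, nSteps)
  stopifnot(length(I) == nSteps)
  state <- newNeuronState(params, u0)
  trace <- numeric(nSteps + 1)
  trace[1] <- u0
  for (k in seq_len(nSteps)) {
    state <- stepNeuron(state, params, I[k], dt, (k - 1) * dt)
    trace[k + 1] <- state$u
  }
  list(times = seq(0, by = dt, length.out = nSteps + 1), u = trace,
       spikes = state$spikes)
}

#' Read LIF parameters from a YAML config file
#'
#' Accepts the NEST-style names \code{EL}, \code{Vth}, \code{Vreset},
#' \code{Cm}, \code{tau_m}, \code{t_ref} (mV / pF / ms); missing keys keep
#' the package defaults.
#'
#' @param path path to a YAML file
#' @return a [LIFParams] object
#' @export
lifParamsFromConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  d <- LIFParams()
  pick <- function(key, default) if (!is.null(cfg[[key]])) as.numeric(cfg[[key]]) else default
  LIFParams(tauM = pick("tau_m", d@tauM), cM = pick("Cm", d@cM),
            eL = pick("EL", d@eL), vTh = pick("Vth", d@vTh),
            vReset = pick("Vreset", d@vReset), tRef = pick("t_ref", d@tRef))
}
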