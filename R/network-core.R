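#' Membrane input
#'
#' Computes the input \eqn{s_i = \sum_{j \ne i} w_{ij} x_j - h_i} each
#' recurrent neuron receives from the current binary state \code{x}
#' (recurrent and external neurons).  Because the recurrent diagonal of the
#' weight matrix is identically zero, the \eqn{j \ne i} restriction is
#' automatic.
#'
#' @param x binary 0/1 vector over all neurons (recurrent + external).
#' @param params a \code{\link{SynapticParameters}} object.
#' @return numeric vector of membrane inputs, one per recurrent neuron.
#' @export
membraneInput <- function(x, params) {
  w <- params@weights
  if (length(x) != ncol(w))
    stop(sprintf("state length %d does not match %d presynaptic columns",
                 length(x), ncol(w)))
  if (!all(x %in% c(0, 1))) stop("state entries must be 0 or 1")
  as.vector(w %*% x) - params@thresholds
}

#' Transmission probability
#'
#' Maps membrane inputs to next-step firing probabilities
#' \eqn{p = p_{max}\,\sigma(s)} with \eqn{\sigma} the logistic function.
#' At \eqn{s = s_0 = \log(p_0/(p_{max}-p_0))} the probability is exactly
#' \eqn{p_0}.
#'
#' @param s numeric vector of membrane inputs.
#' @param pMax maximal transmission probability in (0, 1].
#' @return probabilities in [0, pMax].
#' @export
transmissionProbability <- function(s, pMax) {
  if (!(pMax > 0 && pMax <= 1)) stop("pMax must lie in (0, 1]")
  if (any(!is.finite(s))) stop("membrane inputs must be finite")
  pMax * logistic(s)
}

#' Initialize a network
#'
#' Draws weights i.i.d. uniform on [-0.1, 0.1] (weak random connections,
#' modeling synapses just after formation), zeroes the recurrent diagonal,
#' and sets every threshold to \eqn{\log((p_{max}-p_0)/p_0)} so that the
#' unconnected neurons fire almost independently with probability \eqn{p_0}.
#'
#' @param config a \code{\link{NetworkConfig}}.
#' @param seed optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return a \code{\link{SynapticParameters}} object.
#' @export
initializeNetwork <- function(config, seed = NULL) {
  n <- config@nNeurons
  ntot <- n + config@nExternal
  if (config@p0 >= config@pMax) stop("p0 must be smaller than pMax")
  w <- withLocalSeed(seed, matrix(stats::runif(n * ntot, -0.1, 0.1), n, ntot))
  w[cbind(seq_len(n), seq_len(n))] <- 0
  h <- rep(log((config@pMax - config@p0) / config@p0), n)
  synapticParameters(w, h)
}

#' Advance the network by one step
#'
#' Samples the next recurrent state conditionally independently with
#' probabilities \eqn{p_{max}\sigma(s_i)} computed from the current state;
#' external entries are copied from \code{stimulus}, never sampled.  The
#' returned state retains the membrane inputs used for the sampling, so the
#' conditional probability of the transition can be evaluated without
#' recomputation.
#'
#' @param state a \code{\link{NetworkState}}.
#' @param params a \code{\link{SynapticParameters}}.
#' @param config a \code{\link{NetworkConfig}} (supplies \code{pMax}).
#' @param stimulus binary vector of external firing, length \code{nExternal}.
#' @return the next \code{NetworkState}.
#' @export
stepNetwork <- function(state, params, config, stimulus = integer(0)) {
  n <- nRecurrent(params)
  next_ <- nExternal(params)
  if (length(stimulus) != next_)
    stop(sprintf("stimulus length %d does not match %d external neurons",
                 length(stimulus), next_))
  if (length(stimulus) && !all(stimulus %in% c(0, 1)))
    stop("stimulus entries must be 0 or 1")
  s <- membraneInput(state@x, params)
  p <- transmissionProbability(s, config@pMax)
  xn <- c(as.integer(stats::runif(n) < p), as.integer(stimulus))
  networkState(xn, s, state@t + 1L)
}

#' Simulate a fixed network
#'
#' Runs the stochastic dynamics for \code{nSteps} steps with frozen
#' parameters.  Row \code{t} of the raster holds the state at step \code{t};
#' with \code{recordInputs = TRUE}, row \code{t} of the input history holds
#' the membrane inputs computed from that state (the inputs that generate
#' the recurrent part of row \code{t + 1}).
#'
#' @param params a \code{\link{SynapticParameters}}.
#' @param config a \code{\link{NetworkConfig}}.
#' @param nSteps number of steps (>= 1).
#' @param stimulus \code{NULL} for no external neurons, or an
#'   \code{nSteps} x \code{nExternal} binary matrix whose row \code{t} is the
#'   external state at step \code{t}.
#' @param seed optional integer seed (caller's RNG state preserved).
#' @param recordInputs record the membrane-input history.
#' @param x0 optional initial state over all neurons; defaults to all-quiescent.
#' @return a \code{\link{SpikeRaster}}.
#' @export
simulateNetwork <- function(params, config, nSteps, stimulus = NULL,
                            seed = NULL, recordInputs = FALSE, x0 = NULL) {
  stopifnot(nSteps >= 1)
  ntot <- ncol(params@weights)
  next_ <- nExternal(params)
  if (is.null(x0)) x0 <- integer(ntot)
  if (next_ > 0) {
    if (is.null(stimulus)) stop("network has external neurons but no stimulus was supplied")
    stimulus <- as.matrix(stimulus)
    if (nrow(stimulus) < nSteps)
      stop("stimulus source exhausted before nSteps: ",
           nrow(stimulus), " rows for ", nSteps, " steps")
    storage.mode(stimulus) <- "integer"
  } else stimulus <- NULL
  res <- withLocalSeed(seed,
    cpp_simulate(params@weights, params@thresholds, as.integer(nSteps),
                 config@pMax, stimulus, as.integer(x0), recordInputs))
  spikeRaster(res$spikes, res$inputs)
}

#' Leaky integrate-and-fire f-I curve
#'
#' Integrates a noisy leaky integrate-and-fire neuron,
#' \eqn{\tau_m dV = (-V + V_{rest} + I)dt + D\,d\xi}, by the Euler-Maruyama
#' method; on crossing \eqn{\theta} the potential resets to \eqn{V_{rest}}
#' and is held for the refractory period.  With noise, the firing frequency
#' as a function of the constant current falls on a saturating
#' sigmoid-shaped curve, which motivates the logistic transfer of the binary
#' model; the saturation level is set by the refractory period
#' (\eqn{f \le 1/t_{ref}}).
#'
#' @param currents input currents in mV (unit input resistance).
#' @param tauM membrane time constant, ms.
#' @param theta threshold potential, mV.
#' @param vRest resting potential, mV.
#' @param noiseCoef Wiener-noise coefficient D.
#' @param tRef refractory period, ms.
#' @param dt integration step, ms (must be < tauM).
#' @param duration simulated time per current, ms.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{current} and \code{frequency}
#'   (cycles/ms).
#' @export
lifFICurve <- function(currents, tauM = 15, theta = -50, vRest = -70,
                       noiseCoef = 3, tRef = 1, dt = 0.01, duration = 10000,
                       seed = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (dt >= tauM) stop("dt >= tauM: integration would be unstable")
  if (duration <= 10 * tRef) stop("duration must be much longer than tRef")
  f <- withLocalSeed(seed,
    cpp_lif_fi(as.numeric(currents), tauM, theta, vRest, noiseCoef, tRef,
               dt, duration))
  data.frame(current = as.numeric(currents), frequency = f)
}

#' Simulate and record only population spike counts
#'
#' Runs the same dynamics as \code{\link{simulateNetwork}} for a
#' recurrent-only network but records just the number of spikes per step,
#' so avalanche statistics can be collected over horizons where a full
#' raster would not fit in memory.
#'
#' @param params a \code{\link{SynapticParameters}} (no external neurons).
#' @param config a \code{\link{NetworkConfig}}.
#' @param nSteps number of steps.
#' @param seed optional integer seed.
#' @param x0 optional initial state (default all-quiescent).
#' @return integer vector of population spike counts per step.
#' @export
simulatePopulationCounts <- function(params, config, nSteps, seed = NULL,
                                     x0 = NULL) {
  if (nExternal(params) > 0)
    stop("count-only simulation supports recurrent-only networks")
  if (is.null(x0)) x0 <- integer(ncol(params@weights))
  withLocalSeed(seed,
    cpp_simulate_counts(params@weights, params@thresholds, as.integer(nSteps),
                        config@pMax, as.integer(x0)))
}
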