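# Exact enumeration machinery for tiny networks (N <= 12): transition
# kernel, stationary distribution, exact mutual information and the exact
# objective.  These serve as oracles for the stochastic learning rule and
# for the Gaussian mutual-information estimate.

enumerateStates <- function(n) {
  if (n > 12) stop("exact enumeration is capped at 12 neurons")
  k <- 2^n
  states <- matrix(0L, k, n)
  for (j in seq_len(n)) states[, j] <- rep(rep(0:1, each = 2^(j - 1)), length.out = k)
  states
}

# transition matrix P[x -> x'] of the conditionally independent Bernoulli
# dynamics (recurrent neurons only; no external inputs)
transitionKernel <- function(params, config) {
  n <- nRecurrent(params)
  if (nExternal(params) > 0)
    stop("exact enumeration supports networks without external neurons")
  states <- enumerateStates(n)
  p <- t(apply(states, 1, function(x)
    transmissionProbability(membraneInput(x, params), config@pMax)))
  if (n == 1) p <- matrix(p, ncol = 1)
  k <- nrow(states)
  P <- matrix(0, k, k)
  for (to in seq_len(k)) {
    xto <- states[to, ]
    lik <- rep(1, k)
    for (j in seq_len(n))
      lik <- lik * (if (xto[j] == 1) p[, j] else 1 - p[, j])
    P[, to] <- lik
  }
  list(states = states, P = P, fireProb = p)
}

stationaryDistribution <- function(P, tol = 1e-13, maxIter = 100000L) {
  k <- nrow(P)
  pi <- rep(1 / k, k)
  for (it in seq_len(maxIter)) {
    pin <- as.vector(pi %*% P)
    pin <- pin / sum(pin)
    if (max(abs(pin - pi)) < tol) return(pin)
    pi <- pin
  }
  stop("stationary distribution did not converge")
}

#' Exact mutual information of a tiny network
#'
#' Builds the full transition kernel over all \eqn{2^N} states, solves for
#' the stationary distribution, and evaluates the discrete mutual
#' information \eqn{I[x^t; x^{t-1}]} in bits.  Serves as the ground truth
#' against which the Gaussian covariance estimate \code{\link{iGauss}} is
#' validated.  Capped at N = 12 recurrent neurons.
#'
#' @param params a \code{\link{SynapticParameters}} without external inputs.
#' @param config a \code{\link{NetworkConfig}}.
#' @return mutual information in bits (nonnegative, at most N).
#' @export
exactMutualInformation <- function(params, config) {
  kern <- transitionKernel(params, config)
  pi <- stationaryDistribution(kern$P)
  P <- kern$P
  mi <- 0
  for (from in seq_len(nrow(P))) {
    if (pi[from] == 0) next
    nz <- P[from, ] > 0
    mi <- mi + pi[from] * sum(P[from, nz] * log2(P[from, nz] / pi[nz]))
  }
  max(mi, 0)
}

# per-neuron information I[x_i^t ; x^{t-1}] in nats, under the stationary
# distribution
perNeuronInformation <- function(kern, pi) {
  p <- kern$fireProb
  n <- ncol(p)
  vapply(seq_len(n), function(i) {
    pbar <- sum(pi * p[, i])
    terms <- pi * (p[, i] * log(pmax(p[, i], 1e-300) / pbar) +
                   (1 - p[, i]) * log(pmax(1 - p[, i], 1e-300) / (1 - pbar)))
    sum(terms)
  }, numeric(1))
}

#' Exact objective of a tiny network
#'
#' Evaluates the approximate Infomax objective
#' \eqn{A = A_1 - A_2 - A_3 - A_4} exactly, with all expectations taken
#' under the enumerated stationary distribution: \eqn{A_1} the sum of the
#' logs of the per-neuron informations (natural log; the \code{a_prime}
#' variant uses \eqn{N\log\sum_i I_i} instead), \eqn{A_2} the weighted sum
#' of pairwise covariances, \eqn{A_3} the rate penalty, and \eqn{A_4} the
#' input-fluctuation penalty.
#'
#' @param params,config as in \code{\link{exactMutualInformation}}.
#' @param coeffs a \code{\link{PenaltyCoefficients}}.
#' @param variant \code{"standard"} or \code{"a_prime"}.
#' @return list with components \code{A}, \code{A1}, \code{A2}, \code{A3},
#'   \code{A4} and the per-neuron informations \code{info} (nats).
#' @export
exactObjective <- function(params, config, coeffs, variant = "standard") {
  kern <- transitionKernel(params, config)
  pi <- stationaryDistribution(kern$P)
  states <- kern$states
  n <- ncol(states)
  info <- perNeuronInformation(kern, pi)
  A1 <- if (variant == "a_prime") n * log(sum(info)) else sum(log(info))
  rates <- as.vector(pi %*% states)
  Exx <- t(states) %*% (pi * states)
  covM <- Exx - outer(rates, rates)
  A2 <- coeffs@kappa * sum(covM[upper.tri(covM)])
  A3 <- 0.5 * coeffs@eta * sum((rates - config@p0)^2)
  s0 <- referenceInput(config@p0, config@pMax)
  smat <- t(apply(states, 1, function(x) membraneInput(x, params)))
  if (n == 1) smat <- matrix(smat, ncol = 1)
  A4 <- 0.5 * coeffs@zeta * sum(pi * rowSums((smat - s0)^2))
  list(A = A1 - A2 - A3 - A4, A1 = A1, A2 = A2, A3 = A3, A4 = A4, info = info)
}

#' Exact objective gradient by central differences
#'
#' Numerical gradient of \code{\link{exactObjective}} with respect to the
#' off-diagonal recurrent weights and the thresholds.  The objective is
#' evaluated exactly at each displaced parameter set, so the only error is
#' the O(step^2) finite-difference truncation.
#'
#' @param params,config,coeffs,variant as in \code{\link{exactObjective}}.
#' @param step central-difference step.
#' @return list with \code{wGrad} (matrix, zero diagonal) and \code{hGrad}.
#' @export
exactObjectiveGradient <- function(params, config, coeffs, variant = "standard",
                                   step = 1e-5) {
  w <- params@weights; h <- params@thresholds
  n <- nrow(w)
  evalAt <- function(w2, h2) exactObjective(synapticParameters(w2, h2),
                                            config, coeffs, variant)$A
  wGrad <- matrix(0, n, ncol(w))
  for (i in seq_len(n)) for (j in seq_len(ncol(w))) {
    if (i == j) next
    wp <- w; wp[i, j] <- w[i, j] + step
    wm <- w; wm[i, j] <- w[i, j] - step
    wGrad[i, j] <- (evalAt(wp, h) - evalAt(wm, h)) / (2 * step)
  }
  hGrad <- numeric(n)
  for (i in seq_len(n)) {
    hp <- h; hp[i] <- h[i] + step
    hm <- h; hm[i] <- h[i] - step
    hGrad[i] <- (evalAt(w, hp) - evalAt(w, hm)) / (2 * step)
  }
  list(wGrad = wGrad, hGrad = hGrad)
}

#' Empirical objective diagnostics from a recorded raster
#'
#' Estimates the four objective terms from a simulated raster whose
#' membrane-input history was recorded.  The per-neuron information terms
#' use the plug-in estimator \eqn{\hat H[x_i] - \hat H[x_i | x^{t-1}]}: the
#' conditional term is the mean negative log transition likelihood under the
#' recorded inputs, the marginal term the binary entropy of the empirical
#' rate (natural logs).  For networks of at most 12 neurons,
#' \code{exact = TRUE} computes \eqn{A_1} by full state enumeration instead.
#'
#' @param raster a \code{\link{SpikeRaster}} with recorded inputs.
#' @param coeffs a \code{\link{PenaltyCoefficients}}.
#' @param config a \code{\link{NetworkConfig}}.
#' @param exact use enumeration for the information terms (requires
#'   \code{params}).
#' @param params parameters, only for \code{exact = TRUE}.
#' @return list with \code{A1..A4}, \code{A} and per-neuron \code{info} (nats).
#' @export
objectiveDiagnostics <- function(raster, coeffs, config, exact = FALSE,
                                 params = NULL) {
  if (is.null(raster@inputs)) stop("raster has no recorded membrane inputs")
  x <- raster@spikes
  n <- config@nNeurons
  xr <- x[, seq_len(n), drop = FALSE]
  s <- raster@inputs
  T <- nrow(xr)
  if (exact) {
    if (is.null(params)) stop("exact mode needs the network parameters")
    kern <- transitionKernel(params, config)
    pi <- stationaryDistribution(kern$P)
    info <- perNeuronInformation(kern, pi)
  } else {
    # spikes row t+1 was generated from inputs row t
    pPred <- config@pMax * logistic(s[seq_len(T - 1), , drop = FALSE])
    xNext <- xr[-1, , drop = FALSE]
    condH <- -colMeans(xNext * log(pmax(pPred, 1e-300)) +
                       (1 - xNext) * log(pmax(1 - pPred, 1e-300)))
    rate <- colMeans(xNext)
    margH <- ifelse(rate %in% c(0, 1), 0,
                    -(rate * log(rate) + (1 - rate) * log(1 - rate)))
    info <- margH - condH
  }
  A1 <- sum(log(pmax(info, 1e-300)))
  rates <- colMeans(xr)
  covM <- crossprod(xr) / T - outer(rates, rates)
  A2 <- coeffs@kappa * sum(covM[upper.tri(covM)])
  A3 <- 0.5 * coeffs@eta * sum((rates - config@p0)^2)
  s0 <- referenceInput(config@p0, config@pMax)
  A4 <- 0.5 * coeffs@zeta * mean(rowSums((s - s0)^2))
  list(A = A1 - A2 - A3 - A4, A1 = A1, A2 = A2, A3 = A3, A4 = A4, info = info)
}
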