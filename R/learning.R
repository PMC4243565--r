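#' Scale the penalty coefficients
#'
#' The penalty coefficients of the objective are reported as scaled
#' parameters \code{cKappa}, \code{cEta}, \code{cZeta} whose magnitudes are
#' independent of the system size and the target rate.  The unscaled
#' coefficients are
#' \deqn{\kappa = \frac{2}{(N-1)\,c_\kappa\,p_0^2},\qquad
#'       \eta = \frac{1}{c_\eta^2\,p_0^4},\qquad
#'       \zeta = \frac{1}{c_\zeta^2}.}
#'
#' @param cKappa,cEta,cZeta positive scaled coefficients.
#' @param nNeurons number of recurrent neurons (>= 2).
#' @param p0 target mean firing rate.
#' @return a \code{\link{PenaltyCoefficients}} object.
#' @export
scaleCoefficients <- function(cKappa, cEta, cZeta, nNeurons, p0) {
  if (nNeurons < 2) stop("kappa is undefined for fewer than 2 neurons")
  stopifnot(cKappa > 0, cEta > 0, cZeta > 0, p0 > 0)
  new("PenaltyCoefficients",
      kappa = 2 / ((nNeurons - 1) * cKappa * p0^2),
      eta = 1 / (cEta^2 * p0^4),
      zeta = 1 / cZeta^2)
}

#' Leaky running average
#'
#' One step of the recursion
#' \eqn{\langle q\rangle \leftarrow q/\lambda + (1 - 1/\lambda)\langle q\rangle},
#' a leaky integration of the past values with leak constant \eqn{\lambda}.
#' All running averages of the learning rule (both the synaptic traces with
#' constant \code{tau} and the long averages with constant \code{Tavg}) use
#' this form, started from zero.
#'
#' @param avg current average (vector or matrix).
#' @param newValue new observation, conformable with \code{avg}.
#' @param leak leak constant, >= 1.
#' @return the updated average.
#' @export
leakyUpdate <- function(avg, newValue, leak) {
  if (any(leak < 1)) stop("leak constant must be >= 1")
  newValue / leak + (1 - 1 / leak) * avg
}

#' Eligibility score term
#'
#' The derivative of the log transition likelihood with respect to the
#' membrane input,
#' \deqn{\psi = 1-\sigma(s) \textrm{ if the neuron fired next},\qquad
#'       \psi = -\frac{p_{max}\sigma(s)(1-\sigma(s))}{1-p_{max}\sigma(s)}
#'       \textrm{ otherwise.}}
#' It is positive exactly when an observed spike was under-predicted, and
#' its conditional expectation given \code{s} is identically zero (a score
#' function).
#'
#' @param sPost membrane input(s) of the postsynaptic neuron.
#' @param firedNext 0/1, whether the neuron fired at the next step.
#' @param pMax maximal transmission probability.
#' @return psi, vectorized over the inputs.
#' @export
eligibilityPsi <- function(sPost, firedNext, pMax) {
  n <- max(length(sPost), length(firedNext), length(pMax))
  sg <- rep_len(logistic(sPost), n)
  fired <- rep_len(firedNext, n)
  pm <- rep_len(pMax, n)
  den <- 1 - pm * sg
  if (any(fired == 0 & den <= 0))
    stop("psi undefined: pMax*sigma(s) = 1 with a silent outcome")
  ifelse(fired == 1, 1 - sg, -pm * sg * (1 - sg) / den)
}

#' Per-neuron surprise terms
#'
#' For the state \code{xNow} generated from the inputs \code{sPrev}, returns
#' the log ratio \eqn{\log\{p(x_i|x^{t-1})/Z_i\}} between the realized
#' transition probability and the running estimate \eqn{Z_i} of the marginal
#' firing probability, together with the \eqn{Z_i} used.  \eqn{Z_i} is the
#' long average of the predicted firing probability when the neuron fired
#' and its complement otherwise; it is floored at \code{delta} to remove the
#' cold-start singularity of the zero-initialized averages.
#'
#' @param xNow binary state vector (recurrent part used).
#' @param sPrev membrane inputs that generated \code{xNow}.
#' @param traces a \code{\link{TraceState}}.
#' @param pMax maximal transmission probability.
#' @param delta positive floor.
#' @return list with \code{logRatio} and \code{Z}, one entry per recurrent
#'   neuron.
#' @export
surpriseTerms <- function(xNow, sPrev, traces, pMax, delta = 1e-3) {
  n <- length(sPrev)
  xr <- xNow[seq_len(n)]
  sg <- pMax * logistic(sPrev)
  pe <- ifelse(xr == 1, sg, 1 - sg)
  pe <- pmax(pe, 1e-300)
  Z <- ifelse(xr == 1, traces@avgFireProb, 1 - traces@avgFireProb)
  Z <- ifelse(Z <= delta, delta, Z)
  list(logRatio = log(pe) - log(Z), Z = Z)
}

# gamma signals from precomputed log ratios (shared by globalSignals and the
# reference learning step)
gammaFromLogRatio <- function(lr, xNow, sNow, traces, coeffs, lconfig) {
  scope <- lconfig@gammaScope
  xs <- xNow[scope]
  m <- sum(xs)
  delta <- lconfig@delta
  if (lconfig@variant == "standard") {
    den <- traces@avgLogSurprise[scope]
    den <- ifelse(den <= delta, delta, den)
    g1 <- sum(lr[scope] / den)
  } else {
    den <- sum(traces@avgLogSurprise[scope])
    if (den <= delta) den <- delta
    g1 <- sum(lr[scope]) / den
  }
  g2 <- coeffs@kappa * (0.5 * m * (m - 1) - (traces@avgM - lconfig@p0) * m)
  g3 <- coeffs@eta * sum((traces@avgFireProb[scope] - lconfig@p0) * xs)
  s0 <- referenceInput(lconfig@p0, lconfig@pMax)
  g4 <- 0.5 * coeffs@zeta * sum((sNow[scope] - s0)^2)
  new("GlobalSignals", gamma1 = g1, gamma2 = g2, gamma3 = g3, gamma4 = g4)
}

#' Global modulatory signals
#'
#' Computes the four population scalars gating the plasticity at one step:
#' \code{gamma1} (predictability, from the per-neuron surprise ratios
#' normalized by their long averages), \code{gamma2} (decorrelation /
#' population sparseness, a nonlinear function of the population count),
#' \code{gamma3} (rate control) and \code{gamma4} (input-fluctuation
#' control).  All sums run over \code{gammaScope} only, which is how the
#' image-encoding experiment restricts the objective to the recurrent
#' population.
#'
#' @param xNow binary state at the current step.
#' @param sNow membrane inputs computed from \code{xNow}.
#' @param sPrev membrane inputs that generated \code{xNow}.
#' @param traces a \code{\link{TraceState}} (long averages strictly causal,
#'   i.e. current through the previous step).
#' @param coeffs a \code{\link{PenaltyCoefficients}}.
#' @param lconfig a \code{\link{LearningConfig}}.
#' @return a \code{\link{GlobalSignals}} object.
#' @export
globalSignals <- function(xNow, sNow, sPrev, traces, coeffs, lconfig) {
  st <- surpriseTerms(xNow, sPrev, traces, lconfig@pMax, lconfig@delta)
  gammaFromLogRatio(st$logRatio, xNow, sNow, traces, coeffs, lconfig)
}

#' Apply one parameter update
#'
#' The two-term update of the weights and thresholds:
#' \deqn{\Delta w_{ij} = \epsilon\frac{\tau}{T}\,\Gamma\,\langle\psi_i x_j\rangle_\tau
#'       - \epsilon\frac{\zeta}{T}(s_i - s_0)x_j,\qquad
#'       \Delta h_i = -\epsilon\frac{\tau}{T}\,\Gamma\,\langle\psi_i\rangle_\tau
#'       + \epsilon\frac{\zeta}{T}(s_i - s_0),}
#' with \eqn{\Gamma = \gamma_1-\gamma_2-\gamma_3-\gamma_4}.  Only entries in
#' the plastic row/column masks change, and the recurrent diagonal always
#' stays zero.
#'
#' @param params a \code{\link{SynapticParameters}}.
#' @param traces a \code{\link{TraceState}} (traces through the previous step).
#' @param signals a \code{\link{GlobalSignals}}.
#' @param sNow current membrane inputs.
#' @param xNow current binary state.
#' @param coeffs a \code{\link{PenaltyCoefficients}}.
#' @param lconfig a \code{\link{LearningConfig}}.
#' @return the updated \code{SynapticParameters}.
#' @export
applyUpdate <- function(params, traces, signals, sNow, xNow, coeffs, lconfig) {
  w <- params@weights
  n <- nrow(w); ntot <- ncol(w)
  G <- combinedSignal(signals)
  a <- lconfig@epsilon * (lconfig@tau / lconfig@Tavg) * G
  b <- lconfig@epsilon * (coeffs@zeta / lconfig@Tavg)
  s0 <- referenceInput(lconfig@p0, lconfig@pMax)
  dw <- a * traces@eligPair
  fired <- which(xNow == 1)
  if (length(fired))
    dw[, fired] <- dw[, fired] - b * (sNow - s0)
  rowMask <- seq_len(n) %in% lconfig@plasticRows
  colMask <- seq_len(ntot) %in% lconfig@plasticCols
  dw[!rowMask, ] <- 0
  dw[, !colMask] <- 0
  dw[cbind(seq_len(n), seq_len(n))] <- 0
  dh <- -a * traces@eligPost + b * (sNow - s0)
  dh[!rowMask] <- 0
  if (!all(is.finite(dw)) || !all(is.finite(dh)))
    stop("non-finite parameter update: the run has diverged")
  synapticParameters(w + dw, params@thresholds + dh)
}

# One full canonical learning step in plain R, used as the reference
# implementation against which the compiled training loop is checked.
# `state` is a list(x, sPrev) with x = x^t and sPrev = s^{t-1}; stimulusNext
# is the external part of x^{t+1}.  Consumes runif(nRecurrent) once, in the
# same order as the compiled loop.
learningStep <- function(params, traces, state, lconfig, coeffs,
                         stimulusNext = integer(0), freeze = FALSE) {
  n <- nrow(params@weights)
  x <- state$x
  sNow <- membraneInput(x, params)
  st <- surpriseTerms(x, state$sPrev, traces, lconfig@pMax, lconfig@delta)
  lr <- st$logRatio
  lr[-lconfig@gammaScope] <- 0
  sig <- gammaFromLogRatio(lr, x, sNow, traces, coeffs, lconfig)
  params2 <- if (freeze) params else
    applyUpdate(params, traces, sig, sNow, x, coeffs, lconfig)
  p <- lconfig@pMax * logistic(sNow)
  xn <- c(as.integer(stats::runif(n) < p), as.integer(stimulusNext))
  psi <- eligibilityPsi(sNow, xn[seq_len(n)], lconfig@pMax)
  eligPair <- (1 - 1 / lconfig@tau) * traces@eligPair
  firedPre <- which(x == 1)
  if (length(firedPre))
    eligPair[, firedPre] <- eligPair[, firedPre] + psi / lconfig@tau
  traces2 <- new("TraceState",
    eligPair = eligPair,
    eligPost = leakyUpdate(traces@eligPost, psi, lconfig@tau),
    avgM = leakyUpdate(traces@avgM, sum(x[lconfig@gammaScope]), lconfig@Tavg),
    avgFireProb = leakyUpdate(traces@avgFireProb, lconfig@pMax * logistic(sNow),
                              lconfig@Tavg),
    avgLogSurprise = leakyUpdate(traces@avgLogSurprise, lr, lconfig@Tavg))
  list(params = params2, traces = traces2,
       state = list(x = xn, sPrev = sNow), signals = sig)
}

#' Train a network by the Infomax plasticity rule
#'
#' Runs the full learning schedule: at each step the membrane inputs and
#' global signals are computed, the masked parameters receive the two-term
#' update, the next state is sampled, and the eligibility traces and long
#' averages are advanced (strictly causally: every running average used at a
#' step contains only earlier steps).  The loop runs in compiled code in
#' chunks of \code{recordEvery} steps; after each chunk a metrics row is
#' logged (mean rate, Gaussian mutual-information estimate over the chunk,
#' mean global signals, weight norms) and the optional callback is invoked.
#'
#' Randomness is split into independent streams derived from the root seed
#' (initialization / dynamics / stimulus), so recording choices never
#' perturb trajectories and a run can be resumed bit-identically.
#'
#' @param config a \code{\link{NetworkConfig}}.
#' @param lconfig a \code{\link{LearningConfig}}.
#' @param nSteps number of learning steps.
#' @param stimulus \code{NULL}, an \code{nSteps} x \code{nExternal} binary
#'   matrix, or an \code{\link{EpisodicSequenceConfig}} (generated
#'   internally from the stimulus stream seed).
#' @param seed root integer seed.
#' @param init optional initial \code{\link{SynapticParameters}}; default
#'   \code{\link{initializeNetwork}} under the initialization stream.
#' @param recordEvery metrics cadence in steps (also the window over which
#'   the Gaussian mutual-information estimate is computed).
#' @param snapshotEvery if > 0, parameter snapshots are stored at this cadence.
#' @param callback optional \code{function(info)} called after each chunk
#'   with \code{info = list(step, params, metrics)}.
#' @param freeze if TRUE, parameters are never changed and the would-be
#'   updates are accumulated instead; the averaged update is returned in
#'   \code{$update} (used to compare the stochastic rule against exact
#'   gradients).
#' @param resume a previous training result to continue from (its RNG state,
#'   traces and parameters are restored; \code{nSteps} additional steps are
#'   run).
#' @return a list of class \code{infomaxTraining}: \code{params},
#'   \code{metrics} (data.frame), \code{snapshots}, \code{traces},
#'   \code{state}, \code{update} (freeze mode), \code{diverged}, and the
#'   configurations and seed used.
#' @export
trainNetwork <- function(config, lconfig, nSteps, stimulus = NULL, seed = 1L,
                         init = NULL, recordEvery = 10000L, snapshotEvery = 0L,
                         callback = NULL, freeze = FALSE, resume = NULL) {
  stopifnot(nSteps >= 1)
  n <- config@nNeurons
  next_ <- config@nExternal
  ntot <- n + next_
  coeffs <- scaleCoefficients(lconfig@cKappa, lconfig@cEta, lconfig@cZeta,
                              n, lconfig@p0)

  # stimulus matrix for the steps to run, under its own stream
  stimM <- NULL
  if (is(stimulus, "EpisodicSequenceConfig") && !is.null(resume))
    stop("resume requires an explicit stimulus matrix for the remaining steps")
  if (is(stimulus, "EpisodicSequenceConfig")) {
    if (next_ != stimulus@nExt)
      stop("episodic config has ", stimulus@nExt, " external neurons; network has ", next_)
    stimM <- episodicStimulus(nSteps, stimulus,
                              seed = deriveStreamSeed(seed, 2L))$stimulus
  } else if (is.matrix(stimulus)) {
    if (nrow(stimulus) < nSteps) stop("stimulus source exhausted before nSteps")
    stimM <- stimulus
    storage.mode(stimM) <- "integer"
  } else if (!is.null(stimulus)) stop("unsupported stimulus type")
  if (next_ > 0 && is.null(stimM))
    stop("network has external neurons but no stimulus was supplied")

  if (!is.null(resume)) {
    params <- resume$params
    traces <- resume$traces
    st <- resume$state
    assign(".Random.seed", resume$rngState, envir = .GlobalEnv)
    stepOffset <- resume$stepsDone
  } else {
    params <- if (is.null(init)) initializeNetwork(config, deriveStreamSeed(seed, 0L)) else init
    traces <- traceState(n, ntot)
    x0 <- integer(ntot)
    st <- list(x = x0, sPrev = membraneInput(x0, params),
               xPrevRec = integer(n))
    set.seed(deriveStreamSeed(seed, 1L))
    stepOffset <- 0L
  }

  scopeMask <- seq_len(n) %in% lconfig@gammaScope
  rowMask <- seq_len(n) %in% lconfig@plasticRows
  colMask <- seq_len(ntot) %in% lconfig@plasticCols

  nChunks <- ceiling(nSteps / recordEvery)
  metrics <- vector("list", nChunks)
  snapshots <- list()
  updW <- if (freeze) matrix(0, n, ntot) else NULL
  updH <- if (freeze) numeric(n) else NULL
  done <- 0L
  diverged <- FALSE
  lastGood <- params

  for (k in seq_len(nChunks)) {
    len <- min(recordEvery, nSteps - done)
    chunkStim <- if (!is.null(stimM)) stimM[done + seq_len(len), , drop = FALSE] else NULL
    res <- cpp_train_chunk(params@weights, params@thresholds,
                           as.integer(st$x), st$sPrev, as.integer(st$xPrevRec),
                           traces@eligPair, traces@eligPost, traces@avgM,
                           traces@avgFireProb, traces@avgLogSurprise,
                           lconfig@pMax, lconfig@p0, lconfig@epsilon,
                           coeffs@kappa, coeffs@eta, coeffs@zeta,
                           lconfig@tau, lconfig@Tavg, lconfig@delta,
                           if (lconfig@variant == "standard") 0L else 1L,
                           scopeMask, rowMask, colMask,
                           as.integer(len), chunkStim, freeze, TRUE)
    if (res$diverged) {
      diverged <- TRUE
      warning("training diverged at step ", stepOffset + done + res$stepsDone,
              "; returning the last finite snapshot")
      break
    }
    lastGood <- params <- synapticParameters(res$weights, res$thresholds)
    traces <- new("TraceState", eligPair = res$eligPair, eligPost = res$eligPost,
                  avgM = res$avgM, avgFireProb = res$avgFire,
                  avgLogSurprise = res$avgLS)
    st <- list(x = res$x, sPrev = res$sPrev, xPrevRec = res$xPrevRec)
    if (freeze) { updW <- updW + res$updW; updH <- updH + res$updH }
    done <- done + len
    ig <- tryCatch(
      suppressMessages(iGaussFromStats(res$covS1, res$covS2, res$covN)),
      error = function(e) NA_real_)
    mrow <- data.frame(step = stepOffset + done,
                       meanRate = res$meanM / sum(scopeMask),
                       iGauss = ig,
                       gamma1 = res$meanGamma[1], gamma2 = res$meanGamma[2],
                       gamma3 = res$meanGamma[3], gamma4 = res$meanGamma[4],
                       meanAbsW = mean(abs(params@weights)),
                       maxAbsW = max(abs(params@weights)))
    metrics[[k]] <- mrow
    if (snapshotEvery > 0 && (stepOffset + done) %% snapshotEvery == 0)
      snapshots[[as.character(stepOffset + done)]] <- params
    if (!is.null(callback))
      callback(list(step = stepOffset + done, params = params, metrics = mrow))
  }

  out <- list(params = if (diverged) lastGood else params,
              metrics = do.call(rbind, metrics[!vapply(metrics, is.null, logical(1))]),
              snapshots = snapshots, traces = traces, state = st,
              rngState = get(".Random.seed", envir = .GlobalEnv),
              stepsDone = stepOffset + done, diverged = diverged,
              update = if (freeze) list(w = updW / done, h = updH / done) else NULL,
              config = config, lconfig = lconfig, seed = seed)
  class(out) <- "infomaxTraining"
  out
}

#' @export
print.infomaxTraining <- function(x, ...) {
  cat(sprintf("Infomax training: %d steps done%s\n", x$stepsDone,
              if (x$diverged) " (DIVERGED)" else ""))
  if (!is.null(x$metrics) && nrow(x$metrics)) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  final mean rate %.4g (target p0 = %g), iGauss %.4g bits\n",
                last$meanRate, x$lconfig@p0, last$iGauss))
  }
  invisible(x)
}
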