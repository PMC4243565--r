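#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Network configuration
#'
#' Static description of one stochastic binary network: the number of
#' recurrent neurons, the maximal transmission probability \code{pMax}, the
#' target mean firing rate \code{p0}, and the number of non-plastic external
#' input neurons appended after the recurrent ones.
#'
#' @slot nNeurons integer, number of recurrent neurons (N >= 1).
#' @slot pMax maximal firing-transmission probability, in (0, 1].
#' @slot p0 target mean firing rate, in (0, pMax).
#' @slot nExternal number of external input neurons (>= 0).
#' @export
setClass("NetworkConfig",
  representation(nNeurons = "integer", pMax = "numeric", p0 = "numeric",
                 nExternal = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@nNeurons) != 1 || object@nNeurons < 1)
      msg <- c(msg, "nNeurons must be a single integer >= 1")
    if (!(object@pMax > 0 && object@pMax <= 1))
      msg <- c(msg, "pMax must lie in (0, 1]")
    if (!(object@p0 > 0 && object@p0 < object@pMax))
      msg <- c(msg, "p0 must lie in (0, pMax)")
    if (object@nExternal < 0) msg <- c(msg, "nExternal must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @param nNeurons,pMax,p0,nExternal see slot documentation.
#' @return a \code{NetworkConfig}.
#' @rdname NetworkConfig-class
#' @export
networkConfig <- function(nNeurons, pMax = 0.95, p0 = 0.05, nExternal = 0L) {
  new("NetworkConfig", nNeurons = as.integer(nNeurons), pMax = pMax, p0 = p0,
      nExternal = as.integer(nExternal))
}

#' Synaptic parameters
#'
#' The learnable state of one network: a weight matrix whose rows are
#' postsynaptic recurrent neurons and whose columns are presynaptic neurons
#' (recurrent first, then external), and a threshold vector over recurrent
#' neurons.  The recurrent diagonal is identically zero: neurons have no
#' self-connections.
#'
#' @slot weights numeric matrix, nRecurrent x (nRecurrent + nExternal).
#' @slot thresholds numeric vector over recurrent neurons.
#' @export
setClass("SynapticParameters",
  representation(weights = "matrix", thresholds = "numeric"),
  validity = function(object) {
    w <- object@weights; h <- object@thresholds
    msg <- character(0)
    n <- nrow(w)
    if (ncol(w) < n) msg <- c(msg, "weights must have at least as many columns as rows")
    if (length(h) != n) msg <- c(msg, "thresholds length must equal number of weight rows")
    if (!all(is.finite(w)) || !all(is.finite(h)))
      msg <- c(msg, "weights and thresholds must be finite")
    else if (any(diag(w[, seq_len(n), drop = FALSE]) != 0))
      msg <- c(msg, "recurrent diagonal must be exactly zero (no self-connections)")
    if (length(msg)) msg else TRUE
  })

#' @param weights,thresholds see slot documentation.
#' @rdname SynapticParameters-class
#' @export
synapticParameters <- function(weights, thresholds) {
  new("SynapticParameters", weights = weights, thresholds = as.numeric(thresholds))
}

#' Instantaneous network state
#'
#' The binary firing vector over all neurons, the membrane inputs that
#' generated its recurrent part, and the time index.
#'
#' @slot x integer 0/1 vector over recurrent + external neurons.
#' @slot s numeric membrane-input vector over recurrent neurons.
#' @slot t nonnegative integer time index.
#' @export
setClass("NetworkState",
  representation(x = "integer", s = "numeric", t = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!all(object@x %in% c(0L, 1L))) msg <- c(msg, "x entries must be 0 or 1")
    if (object@t < 0) msg <- c(msg, "t must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' @param x,s,t see slot documentation.
#' @rdname NetworkState-class
#' @export
networkState <- function(x, s, t = 0L) {
  new("NetworkState", x = as.integer(x), s = as.numeric(s), t = as.integer(t))
}

#' Spike raster
#'
#' A time-by-neuron binary firing history.  Row \code{t} holds the network
#' state at step \code{t}; when membrane inputs are recorded, row \code{t} of
#' \code{inputs} holds the inputs computed from that state, i.e. the inputs
#' that generate the recurrent part of row \code{t + 1}.
#'
#' @slot spikes T x N binary matrix.
#' @slot inputs optional T x nRecurrent numeric matrix of membrane inputs.
#' @slot t0 integer start index of the recording.
#' @export
setClass("SpikeRaster",
  representation(spikes = "matrix", inputs = "matrixOrNULL", t0 = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!binaryCheck(object@spikes)) msg <- c(msg, "spikes entries must be 0 or 1")
    if (!is.null(object@inputs) && nrow(object@inputs) != nrow(object@spikes))
      msg <- c(msg, "inputs must be aligned row-for-row with spikes")
    if (length(msg)) msg else TRUE
  })

#' @param spikes,inputs,t0 see slot documentation.
#' @rdname SpikeRaster-class
#' @export
spikeRaster <- function(spikes, inputs = NULL, t0 = 0L) {
  storage.mode(spikes) <- "integer"
  new("SpikeRaster", spikes = spikes, inputs = inputs, t0 = as.integer(t0))
}

#' Learning configuration
#'
#' All tunables of the plasticity rule: learning rate, scaled penalty
#' coefficients, the eligibility leak constant \code{tau}, the long-average
#' leak constant \code{Tavg}, the denominator floor \code{delta}, the plastic
#' row/column index sets, the set of neurons entering the global-signal sums,
#' and the objective variant.
#'
#' @slot epsilon learning rate (held constant during a run).
#' @slot cKappa,cEta,cZeta scaled penalty coefficients.
#' @slot tau eligibility leak constant in steps (>= 1).
#' @slot Tavg long-average leak constant in steps (should be >> tau).
#' @slot delta positive floor applied to estimated denominators.
#' @slot p0,pMax as in \code{NetworkConfig}.
#' @slot plasticRows postsynaptic (row) indices updated.
#' @slot plasticCols presynaptic (column) indices updated.
#' @slot gammaScope recurrent neuron indices entering the global-signal sums.
#' @slot variant \code{"standard"} or \code{"a_prime"}.
#' @export
setClass("LearningConfig",
  representation(epsilon = "numeric", cKappa = "numeric", cEta = "numeric",
                 cZeta = "numeric", tau = "numeric", Tavg = "numeric",
                 delta = "numeric", p0 = "numeric", pMax = "numeric",
                 plasticRows = "integer", plasticCols = "integer",
                 gammaScope = "integer", variant = "character"),
  validity = function(object) {
    msg <- character(0)
    if (object@tau < 1) msg <- c(msg, "tau must be >= 1")
    if (object@delta <= 0) msg <- c(msg, "delta must be > 0")
    if (!(object@variant %in% c("standard", "a_prime")))
      msg <- c(msg, "variant must be 'standard' or 'a_prime'")
    if (!(object@p0 > 0 && object@p0 < object@pMax && object@pMax <= 1))
      msg <- c(msg, "need 0 < p0 < pMax <= 1")
    if (length(msg)) msg else TRUE
  })

#' @param config a \code{NetworkConfig} supplying \code{p0}, \code{pMax} and
#'   the default index sets (all recurrent rows plastic, all columns plastic,
#'   global signals over all recurrent neurons).
#' @param epsilon,cKappa,cEta,cZeta,tau,Tavg,delta,plasticRows,plasticCols,gammaScope,variant
#'   see slot documentation.
#' @rdname LearningConfig-class
#' @export
learningConfig <- function(config, epsilon, cKappa, cEta, cZeta, tau, Tavg,
                           delta = 1e-3, plasticRows = NULL, plasticCols = NULL,
                           gammaScope = NULL, variant = "standard") {
  n <- config@nNeurons
  ntot <- n + config@nExternal
  if (is.null(plasticRows)) plasticRows <- seq_len(n)
  if (is.null(plasticCols)) plasticCols <- seq_len(ntot)
  if (is.null(gammaScope)) gammaScope <- seq_len(n)
  obj <- new("LearningConfig", epsilon = epsilon, cKappa = cKappa, cEta = cEta,
             cZeta = cZeta, tau = tau, Tavg = Tavg, delta = delta,
             p0 = config@p0, pMax = config@pMax,
             plasticRows = as.integer(plasticRows),
             plasticCols = as.integer(plasticCols),
             gammaScope = as.integer(gammaScope), variant = variant)
  if (Tavg < 10 * tau)
    warning("Tavg < 10 * tau: the long averages will track the eligibility time scale")
  obj
}

#' Trace state of the learning rule
#'
#' All leaky running averages the rule maintains: the per-synapse eligibility
#' traces, the per-neuron eligibility, and the three long T-averages
#' (population activity, predicted firing probability, log-surprise).  All
#' are zero-initialized.
#'
#' @slot eligPair matrix of pair eligibility traces over (post, pre).
#' @slot eligPost per-neuron eligibility trace.
#' @slot avgM long average of the population spike count.
#' @slot avgFireProb long average of the predicted firing probabilities.
#' @slot avgLogSurprise long average of the per-neuron log surprise ratio.
#' @export
setClass("TraceState",
  representation(eligPair = "matrix", eligPost = "numeric", avgM = "numeric",
                 avgFireProb = "numeric", avgLogSurprise = "numeric"),
  validity = function(object) {
    ok <- all(is.finite(object@eligPair)) && all(is.finite(object@eligPost)) &&
      is.finite(object@avgM) && all(is.finite(object@avgFireProb)) &&
      all(is.finite(object@avgLogSurprise))
    if (ok) TRUE else "trace state must be finite"
  })

#' @param nRecurrent,nTotal dimensions of the network.
#' @rdname TraceState-class
#' @export
traceState <- function(nRecurrent, nTotal = nRecurrent) {
  new("TraceState", eligPair = matrix(0, nRecurrent, nTotal),
      eligPost = numeric(nRecurrent), avgM = 0,
      avgFireProb = numeric(nRecurrent), avgLogSurprise = numeric(nRecurrent))
}

#' Global modulatory signals
#'
#' The four population-level scalars gating the eligibility traces:
#' predictability (gamma1), decorrelation/sparseness (gamma2), rate control
#' (gamma3) and input-fluctuation control (gamma4).  The combined modulation
#' is \code{gamma1 - gamma2 - gamma3 - gamma4}.
#'
#' @slot gamma1,gamma2,gamma3,gamma4 real scalars.
#' @export
setClass("GlobalSignals",
  representation(gamma1 = "numeric", gamma2 = "numeric", gamma3 = "numeric",
                 gamma4 = "numeric"),
  validity = function(object) {
    if (object@gamma4 < 0) return("gamma4 must be nonnegative")
    TRUE
  })

#' Penalty coefficients
#'
#' The unscaled coefficients kappa, eta, zeta of the correlation, rate and
#' input-fluctuation penalties, produced by \code{\link{scaleCoefficients}}.
#'
#' @slot kappa,eta,zeta positive reals.
#' @export
setClass("PenaltyCoefficients",
  representation(kappa = "numeric", eta = "numeric", zeta = "numeric"),
  validity = function(object) {
    if (object@kappa > 0 && object@eta > 0 && object@zeta > 0) TRUE
    else "all coefficients must be positive"
  })

#' Burst catalog
#'
#' Sizes and durations of the population bursts (avalanches) found in a
#' raster: maximal runs of consecutive steps with at least one spike,
#' partitioned by silent steps.
#'
#' @slot sizes integer spike counts per burst.
#' @slot durations integer step counts per burst.
#' @export
setClass("BurstCatalog",
  representation(sizes = "integer", durations = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@sizes) != length(object@durations))
      msg <- c(msg, "sizes and durations must have equal length")
    if (any(object@sizes < object@durations))
      msg <- c(msg, "every burst step carries at least one spike, so size >= duration")
    if (length(msg)) msg else TRUE
  })

#' Firing pattern and sequence census
#'
#' Counts of distinct whole-network firing patterns and of distinct
#' length-L pattern sequences in a counting window, together with how many
#' sequences recur at least \code{repeatedMin} times.
#'
#' @slot census data.frame with one row per sequence length.
#' @slot nPatterns number of distinct single-step firing patterns.
#' @slot occurrences per-length occurrence tables (named integer vectors).
#' @slot repeatedMin minimal occurrence count for "repeated".
#' @slot window number of steps counted.
#' @export
setClass("SequenceCensus",
  representation(census = "data.frame", nPatterns = "integer",
                 occurrences = "list", repeatedMin = "integer", window = "integer"))

#' Receptive-field map
#'
#' Raw and rescaled spike-triggered averages per recurrent neuron.  Rescaled
#' patches are affinely mapped so the pixel mean is exactly 128 and the
#' maximal absolute deviation from the mean is exactly 127 (gray range
#' 1..255); they are kept numeric, and quantized to integers only on export.
#'
#' @slot raw neurons x pixels matrix of raw spike-triggered averages.
#' @slot rescaled neurons x pixels matrix of rescaled patches.
#' @slot degenerate logical; TRUE for neurons with no spikes or flat averages.
#' @slot side patch side length in pixels.
#' @export
setClass("ReceptiveFieldMap",
  representation(raw = "matrix", rescaled = "matrix", degenerate = "logical",
                 side = "integer"))

#' Strong-transmission chain graph
#'
#' Breadth-first expansion from root neurons along edges whose synaptic
#' weight exceeds a threshold, up to a maximal poly-synaptic depth.
#'
#' @slot nodes data.frame (neuron, depth) with first-reach depths.
#' @slot edges data.frame (pre, post, weight) of strong edges among nodes.
#' @slot threshold weight threshold.
#' @slot maxDepth maximal depth expanded.
#' @export
setClass("ChainGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 threshold = "numeric", maxDepth = "integer"))

#' Grayscale image set
#'
#' A list of square real-valued grayscale images plus a provenance tag
#' distinguishing user-supplied files from the synthetic 1/f fixture.
#'
#' @slot images list of square numeric matrices.
#' @slot provenance "external-file" or "synthetic-fixture".
#' @export
setClass("ImageSet",
  representation(images = "list", provenance = "character"),
  validity = function(object) {
    ok <- all(vapply(object@images, function(im)
      is.matrix(im) && nrow(im) == ncol(im), logical(1)))
    if (!ok) return("all images must be square matrices")
    TRUE
  })

#' @param images,provenance see slot documentation.
#' @rdname ImageSet-class
#' @export
imageSet <- function(images, provenance = "external-file") {
  new("ImageSet", images = images, provenance = provenance)
}

#' Episodic external-sequence configuration
#'
#' The episodic input protocol: a small pool of external neurons fires in a
#' fixed within-episode timetable (by default neuron 1 at offset 0, neuron 3
#' at offset 2, neuron 2 at offset 4), each scheduled slot firing
#' independently with \code{fireProb}; episode onsets are separated by
#' integer gaps uniform on [gapMin, gapMax].
#'
#' @slot nExt number of external neurons.
#' @slot offsets within-episode time offsets (0-based).
#' @slot neurons external-neuron index (1-based) firing at each offset.
#' @slot fireProb per-slot firing probability.
#' @slot gapMin,gapMax bounds of the uniform onset-to-onset gap.
#' @export
setClass("EpisodicSequenceConfig",
  representation(nExt = "integer", offsets = "integer", neurons = "integer",
                 fireProb = "numeric", gapMin = "integer", gapMax = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@offsets < 0)) msg <- c(msg, "offsets must be nonnegative")
    if (anyDuplicated(object@offsets)) msg <- c(msg, "one slot per offset")
    if (!(object@fireProb > 0 && object@fireProb <= 1))
      msg <- c(msg, "fireProb must lie in (0, 1]")
    if (object@gapMin > object@gapMax) msg <- c(msg, "gapMin must be <= gapMax")
    if (any(object@neurons < 1 | object@neurons > object@nExt))
      msg <- c(msg, "scheduled neurons must be valid external indices")
    if (length(msg)) msg else TRUE
  })

#' @param nExt,offsets,neurons,fireProb,gapMin,gapMax see slot documentation.
#' @rdname EpisodicSequenceConfig-class
#' @export
episodicSequenceConfig <- function(nExt = 3L, offsets = c(0L, 2L, 4L),
                                   neurons = c(1L, 3L, 2L), fireProb = 0.5,
                                   gapMin = 50L, gapMax = 100L) {
  new("EpisodicSequenceConfig", nExt = as.integer(nExt),
      offsets = as.integer(offsets), neurons = as.integer(neurons),
      fireProb = fireProb, gapMin = as.integer(gapMin), gapMax = as.integer(gapMax))
}

#' ON/OFF encoder configuration
#'
#' @slot xi gain mapping pixel intensity to firing probability.
#' @slot patchSide patch side length in pixels.
#' @export
setClass("OnOffEncoderConfig",
  representation(xi = "numeric", patchSide = "integer"),
  validity = function(object) if (object@xi > 0) TRUE else "xi must be > 0")

#' @param xi,patchSide see slot documentation.
#' @rdname OnOffEncoderConfig-class
#' @export
onOffEncoderConfig <- function(xi = 1.65, patchSide = 12L) {
  new("OnOffEncoderConfig", xi = xi, patchSide = as.integer(patchSide))
}
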