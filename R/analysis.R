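# Spike-train and connectivity readouts.

asSpikeMatrix <- function(raster) {
  if (is(raster, "SpikeRaster")) raster@spikes else as.matrix(raster)
}

# I_gauss from covariance sufficient statistics: S1 = column sums and
# S2 = cross-product sums of z = (x^t, x^{t-1}) over n pairs.
iGaussFromStats <- function(S1, S2, n) {
  if (n < 4) stop("too few samples for a covariance estimate")
  zdim <- length(S1)
  N <- zdim / 2
  mu <- S1 / n
  D <- S2 / n - outer(mu, mu)
  keep <- which(diag(D)[seq_len(N)] > 0 & diag(D)[N + seq_len(N)] > 0)
  if (length(keep) < 1) stop("all neurons have zero variance in the window")
  if (length(keep) < N)
    message(sprintf("iGauss: dropping %d zero-variance neuron(s)", N - length(keep)))
  idx <- c(keep, N + keep)
  D <- D[idx, idx, drop = FALSE]
  C <- D[seq_along(keep), seq_along(keep), drop = FALSE]
  ldC <- determinant(C, logarithm = TRUE)
  ldD <- determinant(D, logarithm = TRUE)
  if (!is.finite(ldC$modulus) || !is.finite(ldD$modulus) ||
      ldC$sign <= 0 || ldD$sign <= 0)
    stop("singular covariance after degenerate-neuron removal")
  (as.numeric(ldC$modulus) - 0.5 * as.numeric(ldD$modulus)) / log(2)
}

#' Gaussian estimate of the retained mutual information
#'
#' Approximates \eqn{I[x^t; x^{t-1}]} by treating the firing distribution as
#' Gaussian: \eqn{\hat I_{gauss} = \log_2|\hat C| - \frac12\log_2|\hat D|},
#' with \eqn{\hat C} the empirical covariance of \eqn{x^t} and \eqn{\hat D}
#' that of the concatenation \eqn{(x^t, x^{t-1})}.  Zero for temporally
#' independent data (up to small-sample bias).  Neurons with zero variance
#' in the window are dropped (their determinant contribution is singular and
#' they carry no information).
#'
#' @param raster a \code{\link{SpikeRaster}} or binary matrix (time x neurons).
#' @return the estimate in bits.
#' @export
iGauss <- function(raster) {
  x <- asSpikeMatrix(raster)
  T <- nrow(x); N <- ncol(x)
  if (T < 10 * N) warning("fewer than 10 samples per neuron: the estimate will be biased")
  z <- cbind(x[2:T, , drop = FALSE], x[1:(T - 1), , drop = FALSE])
  iGaussFromStats(colSums(z), crossprod(z), nrow(z))
}

#' Detect population bursts (neuronal avalanches)
#'
#' A burst is a maximal cluster of consecutive steps each containing at
#' least one spike, partitioned by empty steps; its size is the total number
#' of spikes in the cluster and its duration the number of steps.  Clusters
#' touching the first or last step of the raster are censored (their extent
#' is unknown) and discarded.
#'
#' @param raster a \code{\link{SpikeRaster}} or binary matrix.
#' @return a \code{\link{BurstCatalog}}.
#' @export
detectBursts <- function(raster) {
  x <- asSpikeMatrix(raster)
  burstsFromCounts(rowSums(x))
}

#' Burst detection from per-step population spike counts
#'
#' Same partition as \code{\link{detectBursts}}, applied directly to a
#' vector of population spike counts per step (e.g. from
#' \code{\link{simulatePopulationCounts}}, which avoids materializing long
#' rasters).
#'
#' @param counts integer vector of spikes per step.
#' @return a \code{\link{BurstCatalog}}.
#' @export
burstsFromCounts <- function(counts) {
  occ <- counts > 0
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  isBurst <- r$values
  # censored clusters at the raster boundary
  if (length(isBurst) && isBurst[1]) isBurst[1] <- FALSE
  if (length(isBurst) && r$values[length(isBurst)]) isBurst[length(isBurst)] <- FALSE
  keep <- which(isBurst)
  sizes <- vapply(keep, function(k) sum(counts[starts[k]:ends[k]]), numeric(1))
  durations <- r$lengths[keep]
  new("BurstCatalog", sizes = as.integer(sizes), durations = as.integer(durations))
}

#' Fit a power-law slope to the burst-size distribution
#'
#' Ordinary least squares on \eqn{(\log s, \log \hat p(s))} over occupied
#' integer sizes in \code{[sMin, sMax]}, with \eqn{\hat p} the empirical
#' occurrence probability.  Near criticality (branching ratio 1) the
#' expected exponent is \eqn{-3/2}.
#'
#' @param catalog a \code{\link{BurstCatalog}}.
#' @param sMin,sMax size range of the fit.
#' @param minSizes minimal number of occupied sizes required.
#' @return list with \code{slope}, \code{stderr}, \code{nSizes} and the
#'   fitted \code{lm} object.
#' @export
fitPowerLawSlope <- function(catalog, sMin = 1, sMax = 50, minSizes = 10) {
  sizes <- catalog@sizes
  if (!length(sizes)) stop("empty burst catalog")
  tab <- table(sizes)
  s <- as.integer(names(tab))
  ok <- s >= sMin & s <= sMax
  if (sum(ok) < minSizes)
    stop(sprintf("only %d occupied sizes in [%g, %g]; need >= %d",
                 sum(ok), sMin, sMax, minSizes))
  p <- as.numeric(tab[ok]) / length(sizes)
  fit <- stats::lm(log(p) ~ log(s[ok]))
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2, 1]), stderr = unname(sm[2, 2]),
       nSizes = sum(ok), fit = fit)
}

#' Census of firing patterns and repeated sequences
#'
#' A firing pattern is the exact binary configuration of the network at one
#' step; a sequence of length L is the exact concatenation of L consecutive
#' patterns (sliding window, stride 1).  Counts distinct patterns, distinct
#' sequences per length, and sequences occurring at least \code{repeatedMin}
#' times.
#'
#' @param raster a \code{\link{SpikeRaster}} or binary matrix.
#' @param lengths sequence lengths L to census.
#' @param window number of steps counted (from \code{start}).
#' @param start first step of the counting window.
#' @param repeatedMin minimal occurrence count to call a sequence repeated
#'   (3 = "repeated more than twice").
#' @return a \code{\link{SequenceCensus}}.
#' @export
countPatternsAndSequences <- function(raster, lengths = c(2, 3, 5, 10),
                                      window = NULL, start = 1,
                                      repeatedMin = 3) {
  x <- asSpikeMatrix(raster)
  if (is.null(window)) window <- nrow(x) - start + 1
  if (start + window - 1 > nrow(x)) stop("window exceeds raster length")
  if (any(lengths > window)) stop("sequence length exceeds the window")
  x <- x[start:(start + window - 1), , drop = FALSE]
  keys <- do.call(paste0, lapply(seq_len(ncol(x)), function(j) x[, j]))
  nPatterns <- length(unique(keys))
  occurrences <- list()
  rows <- lapply(sort(lengths), function(L) {
    nSeq <- window - L + 1
    sk <- do.call(paste, c(lapply(seq_len(L) - 1L,
                                  function(d) keys[(1 + d):(nSeq + d)]),
                           sep = "|"))
    tab <- table(sk)
    occurrences[[as.character(L)]] <<- as.integer(tab)
    data.frame(L = L, distinctSequences = length(tab),
               repeatedSequences = sum(tab >= repeatedMin))
  })
  new("SequenceCensus", census = do.call(rbind, rows),
      nPatterns = as.integer(nPatterns), occurrences = occurrences,
      repeatedMin = as.integer(repeatedMin), window = as.integer(window))
}

#' Autocorrelogram of a single spike train
#'
#' \eqn{C(\rho) = \frac{1}{T_0-\rho}\sum_t x^t x^{t-\rho}}; \eqn{C(0)} is
#' the firing rate, and for an independent train \eqn{C(\rho)} at positive
#' lag approaches the squared rate.
#'
#' @param spikeTrain binary 0/1 vector.
#' @param maxLag largest lag (must be < train length).
#' @return numeric vector of \eqn{C(\rho)} for \eqn{\rho = 0..maxLag}.
#' @export
autocorrelogram <- function(spikeTrain, maxLag) {
  T0 <- length(spikeTrain)
  if (maxLag >= T0) stop("maxLag must be smaller than the train length")
  vapply(0:maxLag, function(rho) {
    sum(spikeTrain[(1 + rho):T0] * spikeTrain[1:(T0 - rho)]) / (T0 - rho)
  }, numeric(1))
}

#' Coefficient of variation of inter-spike intervals
#'
#' SD/mean over the inter-spike intervals of the train, with the population
#' (1/U) normalization in the standard deviation.  Zero for perfectly
#' periodic firing; approaches 1 for a memoryless (Poisson-like) train, and
#' equals \eqn{\sqrt{1-p}} in closed form for a Bernoulli(p) train (whose
#' ISIs are geometric).
#'
#' @param spikeTrain binary 0/1 vector.
#' @return the CV (nonnegative scalar).
#' @export
cvIsi <- function(spikeTrain) {
  idx <- which(spikeTrain == 1)
  if (length(idx) < 3) stop("CV undefined: fewer than 3 spikes in the window")
  isi <- diff(idx)
  m <- mean(isi)
  sdev <- sqrt(mean((isi - m)^2))
  sdev / m
}

#' Shuffle the recurrent weights
#'
#' Permutes the off-diagonal recurrent weights uniformly at random over
#' their positions; the weight multiset, the zero diagonal, any external
#' columns and the thresholds are preserved exactly.  Used to compare a
#' learned network with random networks having identical weight statistics.
#'
#' @param params a \code{\link{SynapticParameters}}.
#' @param seed optional integer seed.
#' @return a new \code{SynapticParameters}.
#' @export
shuffleWeights <- function(params, seed = NULL) {
  w <- params@weights
  n <- nrow(w)
  off <- which(row(w[, seq_len(n), drop = FALSE]) !=
               col(w[, seq_len(n), drop = FALSE]))
  vals <- w[, seq_len(n)][off]
  perm <- withLocalSeed(seed, sample.int(length(off)))
  wrec <- w[, seq_len(n), drop = FALSE]
  wrec[off] <- vals[perm]
  w[, seq_len(n)] <- wrec
  synapticParameters(w, params@thresholds)
}

#' Spike-triggered averages and receptive-field maps
#'
#' For each recurrent neuron, averages the input patch presented at the step
#' before each firing: \eqn{y^{(i)}_{STA} = \langle y^{t-1} x_i^t\rangle}.
#' Each nondegenerate average is then affinely rescaled so that its pixel
#' mean is exactly 128 and its maximal absolute deviation from the mean is
#' exactly 127 (gray range 1..255).  Neurons that never fire (or whose
#' average is flat) are flagged degenerate and receive no rescaled patch.
#'
#' @param raster a \code{\link{SpikeRaster}} (or binary matrix); only the
#'   first \code{nNeurons} columns are used if wider.
#' @param patches patches x pixels matrix, row \code{t} presented at step
#'   \code{t} (so row \code{t-1} precedes the spikes in raster row \code{t}).
#' @param nNeurons number of recurrent neurons to map (default all columns).
#' @return a \code{\link{ReceptiveFieldMap}}.
#' @export
spikeTriggeredAverage <- function(raster, patches, nNeurons = NULL) {
  x <- asSpikeMatrix(raster)
  if (nrow(patches) != nrow(x))
    stop("patch stream and raster are misaligned: ",
         nrow(patches), " patches for ", nrow(x), " steps")
  if (is.null(nNeurons)) nNeurons <- ncol(x)
  x <- x[, seq_len(nNeurons), drop = FALSE]
  T <- nrow(x)
  raw <- crossprod(x[2:T, , drop = FALSE], patches[1:(T - 1), , drop = FALSE]) / (T - 1)
  nSpikes <- colSums(x[2:T, , drop = FALSE])
  rescaled <- matrix(NA_real_, nrow(raw), ncol(raw))
  degenerate <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    y <- raw[i, ]
    dev <- max(abs(y - mean(y)))
    if (nSpikes[i] == 0 || dev == 0) { degenerate[i] <- TRUE; next }
    rescaled[i, ] <- 128 + (y - mean(y)) * 127 / dev
  }
  side <- as.integer(round(sqrt(ncol(patches))))
  new("ReceptiveFieldMap", raw = raw, rescaled = rescaled,
      degenerate = degenerate, side = side)
}

#' Extract strong poly-synaptic transmission chains
#'
#' Breadth-first expansion from root neurons along edges whose weight
#' exceeds \code{threshold} (presynaptic column j to postsynaptic row i),
#' up to \code{maxDepth} transmissions.  Nodes are labeled with the depth at
#' which they are first reached; the returned edge list contains every
#' above-threshold edge among the included nodes.
#'
#' @param params a \code{\link{SynapticParameters}}.
#' @param roots neuron (column) indices to start from, e.g. external inputs.
#' @param threshold weight threshold (> 0).
#' @param maxDepth maximal number of transmissions.
#' @return a \code{\link{ChainGraph}}.
#' @export
extractStrongChains <- function(params, roots, threshold = 8, maxDepth = 6) {
  stopifnot(threshold > 0)
  w <- params@weights
  n <- nrow(w); ntot <- ncol(w)
  if (any(roots < 1 | roots > ntot)) stop("invalid root indices")
  depth <- rep(NA_integer_, ntot)
  depth[roots] <- 0L
  frontier <- as.integer(roots)
  d <- 0L
  while (length(frontier) && d < maxDepth) {
    d <- d + 1L
    nxt <- integer(0)
    for (j in frontier) {
      posts <- which(w[, j] > threshold)
      newNodes <- posts[is.na(depth[posts])]
      depth[newNodes] <- d
      nxt <- c(nxt, newNodes)
    }
    frontier <- unique(nxt)
  }
  nodes <- which(!is.na(depth))
  edges <- which(w > threshold, arr.ind = TRUE)
  keepE <- edges[, "row"] %in% nodes & edges[, "col"] %in% nodes
  edges <- edges[keepE, , drop = FALSE]
  new("ChainGraph",
      nodes = data.frame(neuron = nodes, depth = depth[nodes]),
      edges = data.frame(pre = unname(edges[, "col"]),
                         post = unname(edges[, "row"]),
                         weight = w[edges]),
      threshold = threshold, maxDepth = as.integer(maxDepth))
}

#' Simulate an avalanche catalog directly
#'
#' Runs the network dynamics for a (possibly very long) horizon and returns
#' only the burst catalog.  Silent stretches are skipped exactly: given a
#' silent step and uniform thresholds the dynamics are memoryless, so the
#' waiting time to the next initiation is geometric and the initiating
#' spike set is a conditioned Bernoulli draw.  This makes horizons of 1e9
#' steps affordable at low spontaneous rates.
#'
#' @param params a \code{\link{SynapticParameters}} (recurrent only, uniform
#'   thresholds).
#' @param config a \code{\link{NetworkConfig}}.
#' @param nSteps horizon in steps.
#' @param seed optional integer seed.
#' @return a \code{\link{BurstCatalog}}.
#' @export
avalancheCatalog <- function(params, config, nSteps, seed = NULL) {
  res <- withLocalSeed(seed,
    cpp_avalanche_catalog(params@weights, params@thresholds,
                          as.numeric(nSteps), config@pMax))
  new("BurstCatalog", sizes = as.integer(res$sizes),
      durations = as.integer(res$durations))
}

#' Critical branching network
#'
#' Builds the avalanche test bed: each of \code{n} neurons sends a strong
#' excitatory weight (transmitting at essentially \code{pMax}) to 2 or 3
#' random targets (mean 2.5), so that with \code{pMax = 0.4} one spike
#' evokes on average \eqn{2.5 \times 0.4 = 1} spike at the next step --
#' branching ratio one, the critical point of the avalanche dynamics.
#' Uniform thresholds set the spontaneous per-neuron rate that seeds
#' avalanches; it is kept very low so that avalanches rarely merge.
#'
#' @param n number of neurons.
#' @param pMax maximal transmission probability.
#' @param strongWeight weight of the strong connections.
#' @param spontaneousRate per-neuron spontaneous firing probability per step.
#' @param seed optional integer seed (graph realization).
#' @return a \code{\link{SynapticParameters}}.
#' @export
criticalBranchingNetwork <- function(n = 50, pMax = 0.4, strongWeight = 15,
                                     spontaneousRate = 4e-6, seed = NULL) {
  sigma <- spontaneousRate / pMax
  stopifnot(sigma > 0, sigma < 1)
  h <- rep(log(1 / sigma - 1), n)
  withLocalSeed(seed, {
    w <- matrix(0, n, n)
    outdeg <- rep(c(2L, 3L), length.out = n)
    for (j in seq_len(n))
      w[sample(setdiff(seq_len(n), j), outdeg[j]), j] <- strongWeight
    synapticParameters(w, h)
  })
}
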