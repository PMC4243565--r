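#' Episodic external-sequence stimulus
#'
#' Generates the firing of a small pool of external neurons that fire in a
#' fixed within-episode timetable.  Episode onsets are separated by integer
#' gaps drawn uniformly on [gapMin, gapMax]; within an episode each
#' scheduled slot fires independently with probability \code{fireProb}.
#' With the default three-neuron schedule and \code{fireProb = 1/2}, the
#' network receives \eqn{2^3 - 1 = 7} kinds of slightly different non-silent
#' input sequences.  Outside episode slots the output is identically zero.
#'
#' @param nSteps number of time steps to generate.
#' @param config an \code{\link{EpisodicSequenceConfig}}.
#' @param seed optional integer seed.
#' @return list with \code{stimulus} (an \code{nSteps} x \code{nExt} binary
#'   integer matrix), \code{onsets} (episode onset steps, 1-based), and
#'   \code{episodeFiring} (episodes x slots 0/1 matrix of which scheduled
#'   slots actually fired, columns ordered as \code{config@neurons}).
#' @export
episodicStimulus <- function(nSteps, config = episodicSequenceConfig(),
                             seed = NULL) {
  withLocalSeed(seed, {
    maxOff <- max(config@offsets)
    onsets <- integer(0)
    pos <- 0L
    repeat {
      gap <- sample(config@gapMin:config@gapMax, 1L)
      pos <- pos + gap
      if (pos + maxOff > nSteps) break
      onsets <- c(onsets, pos)
    }
    stim <- matrix(0L, nSteps, config@nExt)
    nslots <- length(config@offsets)
    firing <- matrix(0L, length(onsets), nslots)
    for (e in seq_along(onsets)) {
      fire <- as.integer(stats::runif(nslots) < config@fireProb)
      firing[e, ] <- fire
      steps <- onsets[e] + config@offsets
      stim[cbind(steps, config@neurons)] <- fire
    }
    colnames(firing) <- paste0("ext", config@neurons)
    list(stimulus = stim, onsets = onsets, episodeFiring = firing)
  })
}

#' Census of episode firing combinations
#'
#' Tabulates the distinct non-silent firing combinations realized across
#' episodes (each episode realizes one of the \eqn{2^{n_{slots}}} subsets of
#' its scheduled slots).
#'
#' @param episodeFiring the \code{episodeFiring} matrix from
#'   \code{\link{episodicStimulus}}.
#' @return named integer vector of occurrence counts per non-silent
#'   combination.
#' @export
episodeCombinationCensus <- function(episodeFiring) {
  keys <- apply(episodeFiring, 1, paste, collapse = "")
  tab <- table(keys)
  tab <- tab[names(tab) != paste(rep("0", ncol(episodeFiring)), collapse = "")]
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
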