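# internal helpers

# logistic evaluated branch-wise so exp() never overflows
logistic <- function(s) {
  out <- numeric(length(s))
  pos <- !is.na(s) & s >= 0
  out[pos] <- 1 / (1 + exp(-s[pos]))
  e <- exp(s[!pos])
  out[!pos] <- e / (1 + e)
  out[is.na(s)] <- NA_real_
  out
}

#' Reference membrane input
#'
#' The input strength \eqn{s_0 = \log(p_0/(p_{max}-p_0))} at which a neuron
#' fires with probability exactly \eqn{p_0}.
#'
#' @param p0 target mean firing rate.
#' @param pMax maximal transmission probability.
#' @return a scalar.
#' @export
referenceInput <- function(p0, pMax) {
  stopifnot(p0 > 0, p0 < pMax, pMax <= 1)
  log(p0 / (pMax - p0))
}

# Deterministically derive independent sub-seeds from one root seed so that
# initialization, dynamics and stimulus generation use separate streams.
deriveStreamSeed <- function(root, k) {
  v <- (as.double(root) * 1103515245 + 12345 + as.double(k) * 2654435761) %% 2147483647
  as.integer(v)
}

# Evaluate expr under a local seed, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# djb2-style string hash (hex), used for config hashes in run manifests
hashString <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

binaryCheck <- function(m) {
  v <- as.vector(m)
  all(v == 0 | v == 1)
}
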