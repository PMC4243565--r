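# Shared builders for small test networks.

zeroCouplingParams <- function(n, pMax = 0.95, p0 = 0.05, nExt = 0) {
  synapticParameters(matrix(0, n, n + nExt), rep(log((pMax - p0) / p0), n))
}

randomWeakParams <- function(n, scale = 1, pMax = 0.95, p0 = 0.05, seed = 1) {
  set.seed(seed)
  w <- matrix(runif(n * n, -scale, scale), n, n)
  diag(w) <- 0
  synapticParameters(w, rep(log((pMax - p0) / p0), n))
}

fig2LearningSetup <- function(n = 3, pMax = 0.95, p0 = 0.05, tau = 15,
                              Tavg = 1e4, epsilon = 0) {
  cfg <- networkConfig(n, pMax, p0)
  lc <- suppressWarnings(learningConfig(cfg, epsilon = epsilon, cKappa = 1.0,
                                        cEta = 1.5, cZeta = 3.0, tau = tau,
                                        Tavg = Tavg))
  co <- scaleCoefficients(1.0, 1.5, 3.0, n, p0)
  list(cfg = cfg, lc = lc, co = co)
}
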