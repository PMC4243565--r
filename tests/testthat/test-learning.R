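test_that("coefficient scaling follows the size-free parameterization", {
  co <- scaleCoefficients(1.0, 1.5, 3.0, 50, 0.05)
  expect_equal(co@kappa, 2 / (49 * 1.0 * 0.05^2), tolerance = 1e-12)
  expect_equal(co@kappa, 16.3265, tolerance = 1e-4)
  expect_equal(co@eta, 1 / (1.5^2 * 0.05^4), tolerance = 1e-12)
  expect_equal(scaleCoefficients(1, 1, 3, 50, 0.05)@zeta, 1 / 9, tolerance = 1e-12)
  # scaling laws of the adopted reading
  expect_equal(scaleCoefficients(2, 1.5, 3, 50, 0.05)@kappa, co@kappa / 2)
  expect_equal(scaleCoefficients(1, 1.5, 12, 50, 0.05)@zeta, co@zeta / 16)
  expect_error(scaleCoefficients(1, 1, 1, 1, 0.05), "fewer than 2")
})

test_that("leaky update recursion has the right fixed point and transient", {
  expect_equal(leakyUpdate(3.2, 3.2, 17), 3.2)
  expect_equal(leakyUpdate(0, 5, 10), 0.5)
  avg <- 0
  for (k in 1:100) avg <- leakyUpdate(avg, 1, 10)
  expect_equal(avg, 1 - 0.9^100, tolerance = 1e-12)
  # convergence to the mean of a stationary stream
  set.seed(2)
  stream <- rnorm(20 * 50, mean = 2)
  avg <- 0
  for (q in stream) avg <- leakyUpdate(avg, q, 50)
  expect_lt(abs(avg - 2) / 2, 0.05)
  expect_error(leakyUpdate(0, 1, 0.5), "leak")
})

test_that("psi is the score of the transition likelihood", {
  expect_equal(eligibilityPsi(0, 1, 0.95), 0.5)
  expect_equal(eligibilityPsi(0, 0, 0.95), -0.2375 / 0.525, tolerance = 1e-10)
  expect_lt(eligibilityPsi(30, 1, 0.95), 1e-10)  # saturated prediction
  # score-function identity E[psi | s] = 0, exact on a (s, pMax) grid
  grid <- expand.grid(s = seq(-6, 6, length.out = 40),
                      p = seq(0.05, 0.99, length.out = 25))
  sg <- 1 / (1 + exp(-grid$s))
  pFire <- grid$p * sg
  ev <- pFire * eligibilityPsi(grid$s, 1, grid$p) +
    (1 - pFire) * eligibilityPsi(grid$s, 0, grid$p)
  expect_lt(max(abs(ev)), 1e-14)
  # psi equals d/ds log p(x'|s), central finite differences
  eps <- 1e-6
  for (fired in c(1, 0)) {
    logp <- function(s, p) if (fired == 1) log(p / (1 + exp(-s)))
                           else log(1 - p / (1 + exp(-s)))
    fd <- (logp(grid$s + eps, grid$p) - logp(grid$s - eps, grid$p)) / (2 * eps)
    expect_lt(max(abs(eligibilityPsi(grid$s, fired, grid$p) - fd)), 1e-6)
  }
  expect_error(eligibilityPsi(40, 0, 1), "undefined")
})

test_that("surprise terms use the realized transition probability over floored Z", {
  tr <- traceState(3)
  # perfectly predicted firing: p equals the running Z -> log ratio 0
  tr@avgFireProb <- rep(0.3, 3)
  sMatch <- -log(0.95 / 0.3 - 1)  # pMax*sigma(s) = 0.3
  st <- surpriseTerms(c(1L, 1L, 1L), rep(sMatch, 3), tr, 0.95)
  expect_equal(st$logRatio, rep(0, 3), tolerance = 1e-10)
  # firing at pMax against a marginal estimate of p0: log(pMax/p0) = log 19
  tr@avgFireProb <- rep(0.05, 3)
  st <- surpriseTerms(c(1L, 1L, 1L), rep(50, 3), tr, 0.95)
  expect_equal(st$logRatio, rep(log(0.95 / 0.05), 3), tolerance = 1e-8)
  # denominator average at 1e-6 is floored to delta = 1e-3
  tr@avgFireProb <- rep(1e-6, 3)
  st <- surpriseTerms(c(1L, 1L, 1L), rep(0, 3), tr, 0.95, delta = 1e-3)
  expect_equal(st$Z, rep(1e-3, 3))
})

test_that("global signals vanish where every term carries a silent factor", {
  setup <- fig2LearningSetup(n = 4, Tavg = 100)
  tr <- traceState(4)
  tr@avgM <- 2.5
  s0 <- referenceInput(0.05, 0.95)
  sig <- globalSignals(integer(4), rep(s0, 4), rep(0, 4), tr, setup$co, setup$lc)
  expect_equal(sig@gamma2, 0)   # m = 0
  expect_equal(sig@gamma3, 0)
  expect_equal(sig@gamma4, 0)   # s = s0 everywhere
  # gamma2 worked example: m=2, <m>=2.5, p0=0.05, kappa for N=50
  co50 <- scaleCoefficients(1.0, 1.5, 3.0, 50, 0.05)
  g2 <- co50@kappa * (0.5 * 2 * 1 - (2.5 - 0.05) * 2)
  expect_equal(g2, co50@kappa * (1 - 4.9), tolerance = 1e-12)
  expect_equal(g2, -63.67, tolerance = 1e-3)
})

test_that("the two-term update changes only plastic entries and keeps the diagonal zero", {
  setup <- fig2LearningSetup(n = 4, Tavg = 100, epsilon = 0.01)
  par <- randomWeakParams(4, scale = 0.1, seed = 12)
  tr <- traceState(4)
  s0v <- rep(referenceInput(0.05, 0.95), 4)
  sigZero <- new("GlobalSignals", gamma1 = 0, gamma2 = 0, gamma3 = 0, gamma4 = 0)
  # zero traces and s = s0: parameters unchanged
  out <- applyUpdate(par, tr, sigZero, s0v, c(1L, 0L, 1L, 0L), setup$co, setup$lc)
  expect_identical(synapticWeights(out), synapticWeights(par))
  expect_identical(thresholds(out), thresholds(par))
  # combined signal zero: only the input-regularization term remains
  sNow <- s0v + c(0.5, -0.2, 0, 0.1)
  x <- c(1L, 0L, 0L, 1L)
  out <- applyUpdate(par, tr, sigZero, sNow, x, setup$co, setup$lc)
  b <- 0.01 * setup$co@zeta / 100
  dW <- synapticWeights(out) - synapticWeights(par)
  expect_equal(dW[, 2], rep(0, 4))              # silent presynaptic column
  expect_equal(dW[2, 1], -b * (sNow[2] - s0v[2]), tolerance = 1e-9)
  expect_equal(diag(dW), rep(0, 4))
  expect_equal(thresholds(out) - thresholds(par), b * (sNow - s0v),
               tolerance = 1e-9)
  # single-synapse worked example: trace 0.2, signal 3, eps 0.01, tau 15, T 5e4
  cfg <- networkConfig(2, 0.95, 0.05)
  lc <- learningConfig(cfg, epsilon = 0.01, cKappa = 1, cEta = 1.5, cZeta = 3,
                       tau = 15, Tavg = 5e4)
  par2 <- zeroCouplingParams(2)
  tr2 <- traceState(2)
  tr2@eligPair[1, 2] <- 0.2
  sig3 <- new("GlobalSignals", gamma1 = 3, gamma2 = 0, gamma3 = 0, gamma4 = 0)
  co2 <- scaleCoefficients(1, 1.5, 3, 2, 0.05)
  s0v2 <- rep(referenceInput(0.05, 0.95), 2)
  out2 <- applyUpdate(par2, tr2, sig3, s0v2, integer(2), co2, lc)
  expect_equal(synapticWeights(out2)[1, 2], 0.01 * (15 / 5e4) * 3 * 0.2,
               tolerance = 1e-9)
})

test_that("compiled training loop agrees with the plain-R reference step", {
  ns <- asNamespace("RecurrentInfomax")
  learningStep <- get("learningStep", ns)
  deriveStreamSeed <- get("deriveStreamSeed", ns)
  cfg <- networkConfig(4, 0.95, 0.05)
  # nontrivial global-signal scope and plastic masks
  lc <- suppressWarnings(learningConfig(cfg, epsilon = 0.01, cKappa = 1,
                                        cEta = 1.5, cZeta = 3, tau = 5, Tavg = 100,
                                        gammaScope = 1:3, plasticRows = 1:3,
                                        plasticCols = c(1L, 2L, 4L)))
  co <- scaleCoefficients(1, 1.5, 3, 4, 0.05)
  par <- initializeNetwork(cfg, seed = 5)
  fit <- trainNetwork(cfg, lc, 300, seed = 1, init = par, recordEvery = 97)
  set.seed(deriveStreamSeed(1, 1))
  pr <- par; tr <- traceState(4, 4)
  st <- list(x = integer(4), sPrev = membraneInput(integer(4), par))
  for (t in 1:300) {
    out <- learningStep(pr, tr, st, lc, co)
    pr <- out$params; tr <- out$traces; st <- out$state
  }
  expect_equal(synapticWeights(pr), synapticWeights(fit$params), tolerance = 1e-10)
  expect_equal(thresholds(pr), thresholds(fit$params), tolerance = 1e-10)
  expect_equal(tr@eligPair, fit$traces@eligPair, tolerance = 1e-12)
  expect_equal(tr@avgLogSurprise, fit$traces@avgLogSurprise, tolerance = 1e-12)
  expect_identical(as.integer(st$x), as.integer(fit$state$x))
})

test_that("a null learning rate and masked entries leave parameters untouched", {
  cfg <- networkConfig(5, 0.95, 0.05)
  lc <- learningConfig(cfg, epsilon = 0, cKappa = 1, cEta = 1.5, cZeta = 3,
                       tau = 15, Tavg = 5e4)
  par <- initializeNetwork(cfg, seed = 2)
  fit <- trainNetwork(cfg, lc, 2000, seed = 3, init = par, recordEvery = 1000)
  expect_identical(synapticWeights(fit$params), synapticWeights(par))
  expect_identical(thresholds(fit$params), thresholds(par))
  # plastic masks: only listed rows/cols may change, bit-identical elsewhere
  lc2 <- learningConfig(cfg, epsilon = 0.05, cKappa = 1, cEta = 1.5, cZeta = 3,
                        tau = 15, Tavg = 1000, plasticRows = c(1L, 2L),
                        plasticCols = c(1L, 2L, 3L))
  fit2 <- trainNetwork(cfg, lc2, 2000, seed = 3, init = par, recordEvery = 1000)
  w0 <- synapticWeights(par); w1 <- synapticWeights(fit2$params)
  expect_identical(w1[3:5, ], w0[3:5, ])
  expect_identical(w1[, 4:5], w0[, 4:5])
  expect_identical(thresholds(fit2$params)[3:5], thresholds(par)[3:5])
  expect_false(identical(w1[1:2, 1:3], w0[1:2, 1:3]))
})

test_that("training is deterministic given the root seed and resumes bit-identically", {
  cfg <- networkConfig(5, 0.95, 0.05)
  lc <- learningConfig(cfg, epsilon = 0.01, cKappa = 1, cEta = 1.5, cZeta = 3,
                       tau = 15, Tavg = 1000)
  a <- trainNetwork(cfg, lc, 400, seed = 9, recordEvery = 100)
  b <- trainNetwork(cfg, lc, 400, seed = 9, recordEvery = 100)
  expect_identical(synapticWeights(a$params), synapticWeights(b$params))
  # resume: 200 + 200 equals 400 uninterrupted
  half <- trainNetwork(cfg, lc, 200, seed = 9, recordEvery = 100)
  resumed <- trainNetwork(cfg, lc, 200, seed = 9, recordEvery = 100, resume = half)
  expect_identical(synapticWeights(resumed$params), synapticWeights(a$params))
  expect_identical(thresholds(resumed$params), thresholds(a$params))
  # metrics were recorded at the requested cadence
  expect_equal(a$metrics$step, seq(100, 400, by = 100))
})

test_that("divergence aborts with the last finite snapshot", {
  cfg <- networkConfig(3, 0.95, 0.05)
  lc <- suppressWarnings(learningConfig(cfg, epsilon = 1e6, cKappa = 1,
                                        cEta = 1.5, cZeta = 3, tau = 2, Tavg = 10))
  expect_warning(fit <- trainNetwork(cfg, lc, 5000, seed = 1, recordEvery = 500),
                 "diverged")
  expect_true(fit$diverged)
  expect_true(all(is.finite(synapticWeights(fit$params))))
})


test_that("the a_prime variant normalizes by the population-summed surprise average", {
  ns <- asNamespace("RecurrentInfomax")
  learningStep <- get("learningStep", ns)
  deriveStreamSeed <- get("deriveStreamSeed", ns)
  cfg <- networkConfig(3, 0.95, 0.05)
  co <- scaleCoefficients(1, 1.5, 3, 3, 0.05)
  lcA <- suppressWarnings(learningConfig(cfg, epsilon = 0.01, cKappa = 1,
                                         cEta = 1.5, cZeta = 3, tau = 5,
                                         Tavg = 100, variant = "a_prime"))
  lcS <- suppressWarnings(learningConfig(cfg, epsilon = 0.01, cKappa = 1,
                                         cEta = 1.5, cZeta = 3, tau = 5,
                                         Tavg = 100))
  par <- initializeNetwork(cfg, seed = 6)
  fitA <- trainNetwork(cfg, lcA, 200, seed = 2, init = par, recordEvery = 100)
  fitS <- trainNetwork(cfg, lcS, 200, seed = 2, init = par, recordEvery = 100)
  expect_false(identical(synapticWeights(fitA$params), synapticWeights(fitS$params)))
  # compiled a_prime loop agrees with the reference step
  set.seed(deriveStreamSeed(2, 1))
  pr <- par; tr <- traceState(3)
  st <- list(x = integer(3), sPrev = membraneInput(integer(3), par))
  for (t in 1:200) {
    out <- learningStep(pr, tr, st, lcA, co)
    pr <- out$params; tr <- out$traces; st <- out$state
  }
  expect_equal(synapticWeights(pr), synapticWeights(fitA$params), tolerance = 1e-10)
  expect_equal(thresholds(pr), thresholds(fitA$params), tolerance = 1e-10)
})
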