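test_that("iGauss is near zero for temporally independent firing", {
  set.seed(1)
  x <- matrix(rbinom(1e5 * 10, 1, 0.05), ncol = 10)
  ig <- iGauss(x)
  expect_lt(abs(ig), 0.01)
})

test_that("iGauss tracks the exact mutual information of a copy-dynamics pair", {
  cfg <- networkConfig(2, 0.95, 0.2)
  par <- synapticParameters(matrix(c(0, 2, 2, 0), 2, 2),
                            rep(log((0.95 - 0.2) / 0.2), 2))
  exact <- exactMutualInformation(par, cfg)
  x <- spikes(simulateNetwork(par, cfg, 4e5, seed = 2))
  ig <- iGauss(x)
  expect_lt(abs(ig - exact) / exact, 0.2)
  # duplicating the data leaves the estimate essentially unchanged
  expect_equal(iGauss(rbind(x, x)), ig, tolerance = 0.02)
})

test_that("iGauss drops zero-variance neurons and flags singular covariance", {
  set.seed(3)
  x <- cbind(matrix(rbinom(4e4, 1, 0.2), ncol = 4), 0L)
  expect_message(ig <- iGauss(x), "zero-variance")
  expect_lt(abs(ig), 0.02)
  # a duplicated column makes the covariance exactly singular
  y <- cbind(x[, 1:4], x[, 4])
  expect_error(iGauss(y), "singular")
})

test_that("burst partition matches the worked example and recount oracle", {
  # population counts [0,3,2,2,0]: one burst of size 7 lasting 3 steps
  counts <- c(0, 3, 2, 2, 0)
  b <- burstsFromCounts(counts)
  expect_identical(burstSizes(b), 7L)
  expect_identical(burstDurations(b), 3L)
  # all-silent raster: empty catalog
  expect_identical(length(burstSizes(detectBursts(matrix(0L, 10, 4)))), 0L)
  # clusters touching the boundary are censored
  b2 <- burstsFromCounts(c(2, 1, 0, 3, 0, 1))
  expect_identical(burstSizes(b2), 3L)
  # random raster: sizes sum to the interior spike count (independent scan)
  set.seed(4)
  x <- matrix(rbinom(5000, 1, 0.2), ncol = 5)
  b3 <- detectBursts(x)
  cnt <- rowSums(x)
  occ <- which(cnt > 0)
  runs <- split(occ, cumsum(c(1, diff(occ) != 1)))
  runs <- Filter(function(r) r[1] > 1 && r[length(r)] < nrow(x), runs)
  expect_identical(sum(burstSizes(b3)),
                   as.integer(sum(vapply(runs, function(r) sum(cnt[r]), numeric(1)))))
  expect_identical(length(burstSizes(b3)), length(runs))
  expect_true(all(burstSizes(b3) >= burstDurations(b3)))
})

test_that("power-law fit recovers a planted exponent and flatness", {
  set.seed(5)
  s <- 1:200
  p <- s^(-1.5) / sum(s^(-1.5))
  sizes <- sample(s, 1e5, replace = TRUE, prob = p)
  cat <- new("BurstCatalog", sizes = as.integer(sizes),
             durations = as.integer(pmax(1, round(sizes / 2))))
  fit <- fitPowerLawSlope(cat, 1, 50)
  expect_equal(fit$slope, -1.5, tolerance = 0.1)
  # uniform size distribution: slope near zero
  sizesU <- sample(1:50, 2e4, replace = TRUE)
  catU <- new("BurstCatalog", sizes = as.integer(sizesU),
              durations = as.integer(sizesU))
  expect_lt(abs(fitPowerLawSlope(catU, 1, 50)$slope), 0.05)
  expect_error(fitPowerLawSlope(cat, 1, 5), "occupied sizes")
})

test_that("pattern/sequence census counts configurations exactly", {
  # strict period-3 cycle of 3 distinct nonzero patterns
  pats <- rbind(c(1, 0, 0, 1), c(0, 1, 0, 0), c(0, 0, 1, 1))
  x <- pats[rep(1:3, length.out = 3000), ]
  cen <- countPatternsAndSequences(x, lengths = 3, window = 3000)
  expect_identical(cen@nPatterns, 3L)
  expect_identical(cen@census$distinctSequences, 3L)
  expect_identical(cen@census$repeatedSequences, 3L)
  expect_true(all(cen@occurrences[["3"]] >= 997))
  # all-silent raster: one pattern, one sequence per length
  silent <- countPatternsAndSequences(matrix(0L, 100, 5), lengths = c(2, 5))
  expect_identical(silent@nPatterns, 1L)
  expect_true(all(silent@census$distinctSequences == 1L))
  # i.i.d. raster at N = 50: length-10 collisions essentially impossible
  set.seed(6)
  big <- matrix(rbinom(5e4 * 50, 1, 0.05), ncol = 50)
  cen2 <- countPatternsAndSequences(big, lengths = 10, window = 5e4)
  expect_identical(cen2@census$repeatedSequences, 0L)
  # relabeling neurons consistently changes keys, not counts
  perm <- sample(4)
  cenP <- countPatternsAndSequences(x[, perm], lengths = 3, window = 3000)
  expect_identical(cenP@census, cen@census)
  expect_error(countPatternsAndSequences(x, lengths = 3, window = 5000),
               "window exceeds")
})

test_that("autocorrelogram matches closed forms on periodic and random trains", {
  expect_equal(autocorrelogram(rep(1L, 100), 5), rep(1, 6))
  train <- rep(c(1L, 0L), 50)
  ac <- autocorrelogram(train, 4)
  expect_equal(ac[c(2, 4)], c(0, 0))               # odd lags
  expect_equal(ac[3], sum(train[3:100] * train[1:98]) / 98)
  set.seed(7)
  bern <- rbinom(2e5, 1, 0.1)
  acb <- autocorrelogram(bern, 3)
  expect_equal(acb[1], mean(bern))
  expect_equal(acb[-1], rep(0.01, 3), tolerance = 0.15)
  expect_error(autocorrelogram(train, 100), "maxLag")
})

test_that("CV of ISIs: periodic zero, geometric closed form, few-spike guard", {
  periodic <- integer(1000); periodic[seq(10, 1000, by = 10)] <- 1L
  expect_equal(cvIsi(periodic), 0)
  # Bernoulli(p) train has geometric ISIs with CV sqrt(1-p)
  set.seed(8)
  train <- rbinom(5e5, 1, 0.2)
  expect_equal(cvIsi(train), sqrt(0.8), tolerance = 0.01)
  expect_error(cvIsi(c(0L, 1L, 0L, 1L)), "fewer than 3")
})

test_that("weight shuffling preserves the multiset and is position-uniform", {
  par <- randomWeakParams(3, scale = 1, seed = 9)
  par@weights[1, 2] <- 7  # make all six off-diagonal entries distinct
  sh <- shuffleWeights(par, seed = 10)
  off <- row(matrix(0, 3, 3)) != col(matrix(0, 3, 3))
  expect_identical(sort(synapticWeights(sh)[off]),
                   sort(synapticWeights(par)[off]))
  expect_identical(diag(synapticWeights(sh)), rep(0, 3))
  expect_identical(thresholds(sh), thresholds(par))
  # shuffling twice is itself a single permutation of the original multiset
  sh2 <- shuffleWeights(sh, seed = 11)
  expect_identical(sort(synapticWeights(sh2)[off]),
                   sort(synapticWeights(par)[off]))
  # uniformity: which value lands in the first off-diagonal slot
  vals <- synapticWeights(par)[off]
  set.seed(12)
  first <- replicate(6000, synapticWeights(shuffleWeights(par))[2, 1])
  tab <- table(factor(first, levels = sort(vals)))
  expect_gt(chisq.test(tab)$p.value, 0.001)
  # external columns are untouched
  cfgE <- networkConfig(3, 0.95, 0.05, nExternal = 2)
  parE <- initializeNetwork(cfgE, seed = 13)
  shE <- shuffleWeights(parE, seed = 14)
  expect_identical(synapticWeights(shE)[, 4:5], synapticWeights(parE)[, 4:5])
})

test_that("spike-triggered averages localize the driving pixel and obey the rescale contract", {
  set.seed(15)
  T <- 4000; npix <- 16
  patches <- matrix(rnorm(T * npix), T, npix)
  # neuron 1 fires iff pixel 7 of the previous patch is positive; neuron 2 random;
  # neuron 3 never fires
  x <- cbind(c(0L, as.integer(patches[1:(T - 1), 7] > 0)),
             rbinom(T, 1, 0.3), integer(T))
  map <- spikeTriggeredAverage(x, patches)
  expect_identical(which.max(abs(map@raw[1, ])), 7L)
  expect_identical(map@degenerate, c(FALSE, FALSE, TRUE))
  for (i in 1:2) {
    expect_equal(mean(map@rescaled[i, ]), 128, tolerance = 1e-9)
    expect_equal(max(abs(map@rescaled[i, ] - 128)), 127, tolerance = 1e-9)
    expect_true(all(map@rescaled[i, ] >= 1 & map@rescaled[i, ] <= 255))
  }
  expect_true(all(is.na(map@rescaled[3, ])))
  expect_error(spikeTriggeredAverage(x, patches[1:100, ]), "misaligned")
})

test_that("strong-chain extraction reproduces hand-enumerated reachability", {
  w <- matrix(0, 6, 8)   # 6 recurrent + 2 external columns
  w[1, 7] <- 100         # external 7 -> neuron 1
  w[4, 1] <- 9; w[3, 4] <- 8.5; w[2, 3] <- 12
  w[5, 2] <- 7           # below threshold
  par <- synapticParameters(w, numeric(6))
  g <- extractStrongChains(par, roots = 7, threshold = 8, maxDepth = 6)
  expect_identical(g@nodes$neuron, c(1L, 2L, 3L, 4L, 7L))
  expect_identical(g@nodes$depth[match(c(7, 1, 4, 3, 2), g@nodes$neuron)], 0:4)
  expect_identical(nrow(g@edges), 4L)
  # no edge above threshold: roots only
  g0 <- extractStrongChains(par, roots = 8, threshold = 8)
  expect_identical(g0@nodes$neuron, 8L)
  expect_identical(nrow(g0@edges), 0L)
  # raising the threshold never adds nodes
  g2 <- extractStrongChains(par, roots = 7, threshold = 9.5, maxDepth = 6)
  expect_true(all(g2@nodes$neuron %in% g@nodes$neuron))
  # depth cap prunes the far end of the chain
  g3 <- extractStrongChains(par, roots = 7, threshold = 8, maxDepth = 2)
  expect_false(3 %in% g3@nodes$neuron || 2 %in% g3@nodes$neuron)
})

test_that("avalanche catalog path agrees with the raster path in distribution", {
  par <- criticalBranchingNetwork(20, 0.4, spontaneousRate = 1e-4, seed = 16)
  cfg <- networkConfig(20, 0.4, 0.001)
  b1 <- avalancheCatalog(par, cfg, 5e5, seed = 17)
  counts <- simulatePopulationCounts(par, cfg, 5e5, seed = 18)
  b2 <- burstsFromCounts(counts)
  expect_gt(length(burstSizes(b1)), 100)
  expect_equal(length(burstSizes(b1)) / length(burstSizes(b2)), 1, tolerance = 0.1)
  expect_equal(mean(burstSizes(b1)), mean(burstSizes(b2)), tolerance = 0.15)
  expect_equal(mean(burstDurations(b1)), mean(burstDurations(b2)), tolerance = 0.15)
})
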