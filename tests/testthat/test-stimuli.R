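test_that("episodic source is silent outside episodes and deterministic at fireProb 1", {
  cfgE <- episodicSequenceConfig(fireProb = 1)
  out <- episodicStimulus(5000, cfgE, seed = 3)
  stim <- out$stimulus
  # every episode realizes the full fixed timetable
  for (o in out$onsets) {
    expect_identical(stim[o + 0L, ], c(1L, 0L, 0L))
    expect_identical(stim[o + 2L, ], c(0L, 0L, 1L))
    expect_identical(stim[o + 4L, ], c(0L, 1L, 0L))
  }
  # silence invariant: zero outside the scheduled slots
  slotSteps <- as.vector(outer(out$onsets, c(0L, 2L, 4L), `+`))
  expect_equal(sum(stim), length(slotSteps))
  expect_true(all(rowSums(stim)[-slotSteps] == 0))
})

test_that("onset-to-onset gaps are uniform on [gapMin, gapMax]", {
  out <- episodicStimulus(8e5, episodicSequenceConfig(), seed = 5)
  gaps <- diff(out$onsets)
  expect_true(all(gaps >= 50 & gaps <= 100))
  tab <- table(factor(gaps, levels = 50:100))
  chi <- chisq.test(tab)
  expect_gt(chi$p.value, 0.001)
})

test_that("the three-neuron episodic protocol yields exactly 7 non-silent combinations", {
  out <- episodicStimulus(3e4, episodicSequenceConfig(), seed = 7)
  census <- episodeCombinationCensus(out$episodeFiring)
  expect_identical(length(census), 7L)
  expect_setequal(names(census),
                  setdiff(apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = ""),
                          "000"))
})

test_that("whitening zeroes DC, is linear, and scales sinusoids by L(f)", {
  # constant image maps to exactly zero
  const <- imageSet(list(matrix(5, 32, 32)))
  expect_equal(max(abs(whitenImages(const)@images[[1]])), 0, tolerance = 1e-12)
  # filter response value at the cutoff
  expect_equal(whiteningResponse(200, 200), 200 * exp(-1), tolerance = 1e-12)
  # linearity to machine precision
  set.seed(8)
  a <- matrix(rnorm(32^2), 32); b <- matrix(rnorm(32^2), 32)
  wa <- whitenImages(imageSet(list(a)))@images[[1]]
  wb <- whitenImages(imageSet(list(b)))@images[[1]]
  wab <- whitenImages(imageSet(list(2 * a + 3 * b)))@images[[1]]
  expect_equal(wab, 2 * wa + 3 * wb, tolerance = 1e-10)
  # a pure sinusoid at radial frequency f0 is scaled by exactly L(f0)
  n <- 64; f0 <- 5
  img <- matrix(cos(2 * pi * f0 * (0:(n - 1)) / n), n, n, byrow = TRUE)
  out <- whitenImages(imageSet(list(img)), fc = 200)@images[[1]]
  expect_equal(out, whiteningResponse(f0, 200) * img, tolerance = 1e-8)
  expect_error(whitenImages(imageSet(list(matrix(0, 4, 4)[, 1:3, drop = FALSE]))),
               "square")
})

test_that("synthetic fixture has the requested radial spectral slope", {
  fitSlope <- function(im) {
    n <- nrow(im)
    amp <- Mod(stats::fft(im))
    k <- c(0:(n / 2), -(n / 2 - 1):-1)
    f <- sqrt(outer(k^2, k^2, "+"))
    sel <- f > 2 & f < n / 4
    fb <- round(f[sel])
    m <- tapply(amp[sel], fb, mean)
    coef(lm(log(m) ~ log(as.numeric(names(m)))))[2]
  }
  white <- syntheticImageFixture(3, 128, spectralExponent = 0, seed = 2)
  wslopes <- vapply(white@images, fitSlope, numeric(1))
  expect_lt(abs(mean(wslopes)), 0.1)
  pink <- syntheticImageFixture(3, 128, spectralExponent = 1, seed = 3)
  slopes <- vapply(pink@images, fitSlope, numeric(1))
  expect_equal(unname(mean(slopes)), -1, tolerance = 0.1)
  expect_equal(vapply(pink@images, sd, numeric(1)), rep(1, 3), tolerance = 1e-10)
  expect_identical(pink@provenance, "synthetic-fixture")
  expect_equal(syntheticImageFixture(2, 32, seed = 9)@images,
               syntheticImageFixture(2, 32, seed = 9)@images)
})

test_that("patch sampling is uniform, deterministic, and bounded by the image", {
  imgs <- syntheticImageFixture(2, 24, seed = 4)
  full <- samplePatches(imgs, 24, 5, seed = 1)
  flat <- vapply(imgs@images, function(im) as.vector(im), numeric(24^2))
  for (k in 1:5) expect_true(any(apply(flat, 2, identical, y = full[k, ])))
  expect_identical(samplePatches(imgs, 12, 20, seed = 6),
                   samplePatches(imgs, 12, 20, seed = 6))
  expect_error(samplePatches(imgs, 25, 1), "exceeds")
})

test_that("ON/OFF encoding separates signs and respects the probability map", {
  cfgE <- onOffEncoderConfig(xi = 1.65)
  zero <- onOffEncode(rep(0, 16), cfgE, seed = 1)
  expect_identical(zero$on, rep(0L, 16))
  expect_identical(zero$off, rep(0L, 16))
  # clipped probability at y = 2/xi; certainty of ON, OFF silent
  patch <- rep(2 / 1.65, 20)
  enc <- onOffEncode(patch, cfgE, seed = 2)
  expect_identical(enc$on, rep(1L, 20))
  expect_identical(enc$off, rep(0L, 20))
  # p(OFF) = 0.825 for y = -0.5 at xi = 1.65
  set.seed(5)
  offs <- onOffEncodeStream(matrix(-0.5, 4000, 1), cfgE, seed = 3)[, 2]
  expect_equal(mean(offs), 0.825, tolerance = 0.02)
  # mean ON+OFF rate is monotone in xi on fixture patches
  imgs <- whitenImages(syntheticImageFixture(2, 64, seed = 6))
  y <- samplePatches(imgs, 12, 500, seed = 7)
  rates <- vapply(c(0.5, 1.65, 5), function(xi)
    mean(onOffEncodeStream(y, onOffEncoderConfig(xi = xi), seed = 8)), numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("the encoder gain calibrates to a requested input rate by bisection", {
  imgs <- whitenImages(syntheticImageFixture(3, 64, seed = 10))
  xi <- calibrateXi(imgs, targetRate = 0.15, seed = 11)
  y <- samplePatches(imgs, 12, 4000, seed = 12)
  enc <- onOffEncodeStream(y, onOffEncoderConfig(xi = xi), seed = 13)
  expect_equal(mean(enc), 0.15, tolerance = 0.01)
})
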