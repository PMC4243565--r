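# Image preparation for the receptive-field experiment: whitening filter,
# synthetic natural-like fixture, patch sampling and ON/OFF encoding.

# radial frequency grid in cycles per picture, unshifted FFT indexing
radialFrequency <- function(side) {
  k <- c(0:floor(side / 2), -(ceiling(side / 2) - 1):-1)
  k <- k[seq_len(side)]
  sqrt(outer(k^2, k^2, "+"))
}

#' Whitening / low-pass filter response
#'
#' \eqn{L(f) = f \exp(-(f/f_c)^4)}: the linear ramp whitens the roughly
#' 1/f amplitude spectrum of natural scenes (and zeroes the DC component),
#' while the quartic exponential removes high-frequency sampling artifacts.
#'
#' @param f radial frequency in cycles per picture.
#' @param fc cut-off frequency, default 200 cycles per picture.
#' @return filter amplitude response.
#' @export
whiteningResponse <- function(f, fc = 200) f * exp(-(f / fc)^4)

#' Whiten and low-pass filter an image set
#'
#' Applies \code{\link{whiteningResponse}} multiplicatively in the 2-D
#' Fourier domain, with the radial frequency measured in cycles per picture
#' on the standard FFT grid.  Because \eqn{L(0) = 0}, the output is exactly
#' zero-centered.  The transform is linear in the input images.
#'
#' @param images an \code{\link{ImageSet}}.
#' @param fc cut-off frequency in cycles per picture.
#' @return a whitened \code{ImageSet} (provenance preserved).
#' @export
whitenImages <- function(images, fc = 200) {
  stopifnot(fc > 0)
  out <- lapply(images@images, function(im) {
    if (nrow(im) != ncol(im)) stop("images must be square")
    L <- whiteningResponse(radialFrequency(nrow(im)), fc)
    Re(stats::fft(stats::fft(im) * L, inverse = TRUE)) / length(im)
  })
  imageSet(out, images@provenance)
}

#' Synthetic natural-like image fixture
#'
#' Gaussian random-phase images with radial amplitude spectrum
#' \eqn{|f|^{-\alpha}} (default \eqn{\alpha = 1}, the approximate spectral
#' statistics of natural scenes), normalized to zero mean and unit variance.
#' A download-free stand-in ensemble suitable as input to
#' \code{\link{whitenImages}}; it reproduces the second-order (spectral)
#' statistics of natural images but none of their higher-order structure
#' (edges, occlusions, sparse structure).
#'
#' @param nImages number of images.
#' @param side image side in pixels (>= 16).
#' @param spectralExponent alpha of the 1/f^alpha amplitude spectrum.
#' @param seed optional integer seed.
#' @return an \code{ImageSet} with provenance \code{"synthetic-fixture"}.
#' @export
syntheticImageFixture <- function(nImages = 10, side = 128,
                                  spectralExponent = 1.0, seed = NULL) {
  stopifnot(side >= 16)
  withLocalSeed(seed, {
    f <- radialFrequency(side)
    amp <- ifelse(f > 0, f^(-spectralExponent), 0)
    imgs <- lapply(seq_len(nImages), function(k) {
      noise <- matrix(stats::rnorm(side^2), side, side)
      im <- Re(stats::fft(stats::fft(noise) * amp, inverse = TRUE)) / side^2
      im <- im - mean(im)
      im / stats::sd(im)
    })
    imageSet(imgs, "synthetic-fixture")
  })
}

#' Sample square patches i.i.d. from an image set
#'
#' Each patch is cut at an image index and top-left corner drawn uniformly
#' and independently.
#'
#' @param images an \code{\link{ImageSet}}.
#' @param side patch side in pixels (at most the image side).
#' @param n number of patches.
#' @param seed optional integer seed.
#' @return an \code{n} x \code{side^2} matrix; each row is one patch,
#'   flattened column-major.
#' @export
samplePatches <- function(images, side, n, seed = NULL) {
  sides <- vapply(images@images, nrow, integer(1))
  if (any(side > sides)) stop("patch side exceeds image side")
  withLocalSeed(seed, {
    idx <- sample.int(length(images@images), n, replace = TRUE)
    out <- matrix(0, n, side^2)
    for (k in seq_len(n)) {
      im <- images@images[[idx[k]]]
      lim <- nrow(im) - side + 1L
      r <- sample.int(lim, 1L)
      cc <- sample.int(lim, 1L)
      out[k, ] <- as.vector(im[r:(r + side - 1L), cc:(cc + side - 1L)])
    }
    out
  })
}

#' ON/OFF encoding of one patch
#'
#' A pair of ON and OFF cells per pixel fires with probability proportional
#' to the positive and negative pixel intensity respectively:
#' \eqn{p(ON) = \min(\xi y, 1)} for \eqn{y \ge 0} (OFF silent), and
#' \eqn{p(OFF) = \min(-\xi y, 1)} for \eqn{y \le 0} (ON silent).  The two
#' populations are therefore never both eligible on the same pixel, and the
#' sampling is independent across pixels.
#'
#' @param patch numeric pixel vector.
#' @param config an \code{\link{OnOffEncoderConfig}} (gain \code{xi}).
#' @param seed optional integer seed.
#' @return list with binary vectors \code{on} and \code{off}.
#' @export
onOffEncode <- function(patch, config = onOffEncoderConfig(), seed = NULL) {
  pOn <- pmin(config@xi * pmax(patch, 0), 1)
  pOff <- pmin(-config@xi * pmin(patch, 0), 1)
  withLocalSeed(seed, {
    u <- stats::runif(2 * length(patch))
    list(on = as.integer(u[seq_along(patch)] < pOn),
         off = as.integer(u[length(patch) + seq_along(patch)] < pOff))
  })
}

#' ON/OFF encoding of a patch stream
#'
#' Vectorized \code{\link{onOffEncode}} over rows of a patch matrix;
#' returns the stimulus matrix for a network whose external population is
#' the ON block followed by the OFF block.
#'
#' @param patches patches x pixels matrix (rows presented sequentially).
#' @param config an \code{\link{OnOffEncoderConfig}}.
#' @param seed optional integer seed.
#' @return binary integer matrix, rows aligned with patches, columns
#'   \code{[ON pixels, OFF pixels]}.
#' @export
onOffEncodeStream <- function(patches, config = onOffEncoderConfig(),
                              seed = NULL) {
  pOn <- pmin(config@xi * pmax(patches, 0), 1)
  pOff <- pmin(-config@xi * pmin(patches, 0), 1)
  withLocalSeed(seed, {
    on <- matrix(as.integer(stats::runif(length(pOn)) < pOn), nrow(patches))
    off <- matrix(as.integer(stats::runif(length(pOff)) < pOff), nrow(patches))
    cbind(on, off)
  })
}

#' Calibrate the ON/OFF gain to a target input rate
#'
#' The gain printed for the original natural-image ensemble yields a mean
#' input rate of about 0.15 only on that ensemble; for other image sets the
#' gain is found by bisection so that the population-average ON+OFF firing
#' rate (which is monotone increasing in the gain) hits \code{targetRate}.
#'
#' @param images an \code{\link{ImageSet}} (already whitened).
#' @param targetRate desired mean firing rate over ON and OFF cells.
#' @param side patch side in pixels.
#' @param nPatches number of calibration patches.
#' @param seed optional integer seed.
#' @return the calibrated gain xi.
#' @export
calibrateXi <- function(images, targetRate = 0.15, side = 12, nPatches = 2000,
                        seed = NULL) {
  stopifnot(targetRate > 0, targetRate < 0.5)
  y <- abs(samplePatches(images, side, nPatches, seed = seed))
  rateAt <- function(xi) mean(pmin(xi * y, 1)) / 2
  lo <- 1e-8; hi <- 1
  while (rateAt(hi) < targetRate) {
    hi <- hi * 2
    if (hi > 1e8) stop("cannot reach the target rate")
  }
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (rateAt(mid) < targetRate) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Read / write grayscale images as plain-text PGM
#'
#' Minimal plain (P2) PGM support for persisting image sets as text.
#'
#' @param path file path.
#' @param im numeric matrix (rescaled to 0..255 on write).
#' @return \code{readPGM}: a numeric matrix in [0, 1].
#' @export
readPGM <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P2") stop("only plain (P2) PGM is supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / mx
}

#' @param im numeric matrix.
#' @rdname readPGM
#' @export
writePGM <- function(im, path) {
  rng <- range(im)
  scaled <- if (diff(rng) == 0) matrix(0L, nrow(im), ncol(im))
            else round((im - rng[1]) / diff(rng) * 255)
  lines <- c("P2", paste(ncol(im), nrow(im)), "255",
             apply(scaled, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
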