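# Experiment presets, configuration validation, and run orchestration.

# Full-scale parameter blocks exactly as used in the reference simulations.
presetTable <- list(
  "spontaneous-sequences" = list(
    epsilon = 0.006, cEta = 1.5, cKappa = 1.0, cZeta = 3.0,
    p0 = 0.05, pMax = 0.95, N = 50, tau = 15, Tavg = 50000),
  "avalanches" = list(
    list(epsilon = 0.02, cEta = 10.0, cKappa = 30.0, cZeta = 3.0,
         p0 = 0.01, pMax = c(0.2, 0.4, 0.8), N = 50, tau = 10, Tavg = 50000),
    list(epsilon = 0.01, cEta = 20.0, cKappa = 60.0, cZeta = 4.0,
         p0 = 0.005, pMax = 0.2, N = 100, tau = 15, Tavg = 50000),
    list(epsilon = 0.006, cEta = 40.0, cKappa = 100.0, cZeta = 6.0,
         p0 = 0.0025, pMax = 0.2, N = 200, tau = 20, Tavg = 50000),
    list(epsilon = 0.005, cEta = 3.0, cKappa = 1.0, cZeta = 10.0,
         p0 = 0.01, pMax = 0.95, N = 50, tau = 20, Tavg = 50000)),
  "evoked-replay" = list(
    epsilon = 0.01, cEta = 2.0, cKappa = 3.0, cZeta = 10.0,
    p0 = 0.02, pMax = 0.98, N = 50, tau = 15, Tavg = 50000,
    nExternal = 3, feedforwardInit = 100),
  "receptive-fields" = list(
    epsilon = 0.02, cEta = 250.0, cKappa = 150.0, cZeta = 1000.0,
    p0 = 0.0015, pMax = 0.95, N = 100, tau = 5, Tavg = 50000,
    patchSide = 12, nExternal = 288, xi = 1.65),
  "lif-check" = list(
    tauM = 15, theta = -50, vRest = -70, noiseCoef = 3, dt = 0.01,
    currents = seq(-200, 600, by = 25), tRef = c(1, 2, 3)))

#' Preset experiment parameters
#'
#' Returns the full-scale parameter block of a named preset experiment
#' (spontaneous sequence learning, avalanche learning with its four
#' published variants, evoked-replay learning with episodic inputs,
#' receptive-field learning on image patches, or the integrate-and-fire
#' transfer-function check).
#'
#' @param name preset name.
#' @param variant variant number for the avalanche preset (1-4).
#' @return named list of parameters.
#' @export
presetParameters <- function(name = c("spontaneous-sequences", "avalanches",
                                      "evoked-replay", "receptive-fields",
                                      "lif-check"), variant = 1) {
  name <- match.arg(name)
  p <- presetTable[[name]]
  if (name == "avalanches") p <- p[[variant]]
  p
}

#' Validate a raw configuration
#'
#' Checks every invariant of the network and learning configurations in a
#' raw configuration (a YAML/JSON file path or a named list), rejects
#' unknown keys, fills defaults and echoes them.  Violations are reported
#' with their field paths rather than thrown, so a caller can present the
#' full report.
#'
#' @param raw file path (YAML or JSON) or named list with elements
#'   \code{network}, \code{learning} and optionally \code{seed}.
#' @return list with \code{ok}, typed \code{network}/\code{learning} configs
#'   (when valid), \code{seed}, \code{errors}, \code{warnings} and the
#'   echoed \code{filled} configuration.
#' @export
validateConfig <- function(raw) {
  if (is.character(raw)) {
    raw <- if (grepl("\\.json$", raw)) jsonlite::read_json(raw, simplifyVector = TRUE)
           else yaml::read_yaml(raw)
  }
  errors <- character(0); warnings <- character(0)
  knownTop <- c("network", "learning", "seed")
  unknown <- setdiff(names(raw), knownTop)
  if (length(unknown))
    errors <- c(errors, paste0("unknown top-level key(s): ",
                               paste(unknown, collapse = ", ")))
  net <- raw$network
  knownNet <- c("nNeurons", "pMax", "p0", "nExternal")
  unknown <- setdiff(names(net), knownNet)
  if (length(unknown))
    errors <- c(errors, paste0("network: unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  if (is.null(net$nNeurons)) errors <- c(errors, "network.nNeurons: required")
  if (is.null(net$pMax)) net$pMax <- 0.95
  if (is.null(net$p0)) net$p0 <- 0.05
  if (is.null(net$nExternal)) net$nExternal <- 0
  if (!is.null(net$p0) && !is.null(net$pMax) && net$p0 >= net$pMax)
    errors <- c(errors, "network.p0: must satisfy 0 < p0 < pMax")
  if (!is.null(net$pMax) && (net$pMax <= 0 || net$pMax > 1))
    errors <- c(errors, "network.pMax: must lie in (0, 1]")
  lrn <- raw$learning
  knownLrn <- c("epsilon", "cKappa", "cEta", "cZeta", "tau", "Tavg", "delta",
                "variant")
  unknown <- setdiff(names(lrn), knownLrn)
  if (length(unknown))
    errors <- c(errors, paste0("learning: unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  required <- c("epsilon", "cKappa", "cEta", "cZeta", "tau", "Tavg")
  for (k in required)
    if (is.null(lrn[[k]])) errors <- c(errors, paste0("learning.", k, ": required"))
  if (is.null(lrn$delta)) lrn$delta <- 1e-3
  if (is.null(lrn$variant)) lrn$variant <- "standard"
  if (!is.null(lrn$tau) && lrn$tau < 1) errors <- c(errors, "learning.tau: must be >= 1")
  if (!is.null(lrn$tau) && !is.null(lrn$Tavg) && lrn$Tavg < 10 * lrn$tau)
    warnings <- c(warnings, "learning.Tavg: Tavg < 10*tau, long averages will track the eligibility time scale")
  if (is.null(raw$seed)) raw$seed <- 1L
  ok <- length(errors) == 0
  out <- list(ok = ok, errors = errors, warnings = warnings,
              seed = as.integer(raw$seed),
              filled = list(network = net, learning = lrn, seed = raw$seed))
  if (ok) {
    out$network <- networkConfig(net$nNeurons, net$pMax, net$p0, net$nExternal)
    out$learning <- suppressWarnings(
      learningConfig(out$network, epsilon = lrn$epsilon, cKappa = lrn$cKappa,
                     cEta = lrn$cEta, cZeta = lrn$cZeta, tau = lrn$tau,
                     Tavg = lrn$Tavg, delta = lrn$delta, variant = lrn$variant))
  }
  out
}

# default step counts: scaled presets change only durations and cadences
scaledSteps <- c("spontaneous-sequences" = 1e5, "avalanches" = 1e5,
                 "evoked-replay" = 1e5, "receptive-fields" = 2e4)
fullSteps <- 2e9

#' Run a preset experiment
#'
#' Executes the train / simulate / analyze pipeline of a named preset and
#' persists every stage under \code{outputDir}: the echoed configuration
#' (\code{config.yaml}), a reproducibility manifest (\code{manifest.json}),
#' training metrics (\code{metrics.csv}), the learned parameters
#' (\code{weights.json}, \code{weights.csv}, \code{thresholds.csv}), a
#' post-learning raster (\code{raster.tsv}) and the analysis exports under
#' \code{analysis/}.  Scaled runs alter only step counts and logging
#' cadence relative to the full-scale parameter blocks.
#'
#' @param name preset name (see \code{\link{presetParameters}}).
#' @param outputDir output directory (created if missing).
#' @param seed root seed.
#' @param scale \code{"scaled"} or \code{"full"}.
#' @param nSteps optional override of the training step count.
#' @param variant avalanche-preset variant (1-4).
#' @param pMax optional override of pMax where the legend lists several.
#' @return the run manifest, invisibly.
#' @export
runPreset <- function(name, outputDir, seed = 1L, scale = "scaled",
                      nSteps = NULL, variant = 1, pMax = NULL) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outputDir, "analysis"), showWarnings = FALSE)
  manifest <- list(preset = name, seed = seed, scale = scale,
                   package = "RecurrentInfomax",
                   version = as.character(utils::packageVersion("RecurrentInfomax")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  p <- presetParameters(name, variant = variant)

  if (name == "lif-check") {
    tabs <- lapply(p$tRef, function(tr)
      cbind(lifFICurve(p$currents, tauM = p$tauM, theta = p$theta,
                       vRest = p$vRest, noiseCoef = p$noiseCoef, tRef = tr,
                       dt = p$dt, duration = 20000,
                       seed = deriveStreamSeed(seed, tr)),
            tRef = tr))
    fi <- do.call(rbind, tabs)
    utils::write.csv(fi, file.path(outputDir, "analysis", "fi_curve.csv"),
                     row.names = FALSE)
    manifest$outputs <- "analysis/fi_curve.csv"
    manifest$configHash <- hashString(deparse(p))
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(manifest))
  }

  if (is.null(nSteps))
    nSteps <- if (scale == "full") fullSteps else scaledSteps[[name]]
  pm <- if (!is.null(pMax)) pMax
        else if (name == "avalanches" && variant == 1) 0.4  # default of the listed 0.2/0.4/0.8
        else p$pMax[1]
  nExt <- if (is.null(p$nExternal)) 0L else p$nExternal
  config <- networkConfig(p$N, pm, p$p0, nExt)
  lconfig <- learningConfig(config, epsilon = p$epsilon, cKappa = p$cKappa,
                            cEta = p$cEta, cZeta = p$cZeta, tau = p$tau,
                            Tavg = p$Tavg)

  init <- initializeNetwork(config, deriveStreamSeed(seed, 0L))
  stimulus <- NULL
  patches <- NULL
  if (name == "evoked-replay") {
    w <- init@weights
    w[cbind(1:3, p$N + 1:3)] <- p$feedforwardInit
    init <- synapticParameters(w, init@thresholds)
    stimulus <- episodicStimulus(nSteps, episodicSequenceConfig(),
                                 seed = deriveStreamSeed(seed, 2L))$stimulus
  } else if (name == "receptive-fields") {
    imgs <- whitenImages(syntheticImageFixture(10, 128,
                                               seed = deriveStreamSeed(seed, 4L)))
    xi <- calibrateXi(imgs, targetRate = 0.15, side = p$patchSide,
                      seed = deriveStreamSeed(seed, 5L))
    patches <- samplePatches(imgs, p$patchSide, nSteps + 1,
                             seed = deriveStreamSeed(seed, 2L))
    stimulus <- onOffEncodeStream(patches, onOffEncoderConfig(xi = xi),
                                  seed = deriveStreamSeed(seed, 3L))
    lconfig <- learningConfig(config, epsilon = p$epsilon, cKappa = p$cKappa,
                              cEta = p$cEta, cZeta = p$cZeta, tau = p$tau,
                              Tavg = p$Tavg, gammaScope = seq_len(p$N))
    manifest$xi <- xi
  }

  recordEvery <- max(1000, min(10000, nSteps / 10))
  fit <- trainNetwork(config, lconfig, nSteps,
                      stimulus = if (is.null(stimulus)) NULL
                                 else stimulus[seq_len(nSteps), , drop = FALSE],
                      seed = seed, init = init, recordEvery = recordEvery)

  # post-learning raster for the analyses
  window <- min(50000, nSteps)
  simStim <- NULL
  if (name == "evoked-replay")
    simStim <- episodicStimulus(window, episodicSequenceConfig(),
                                seed = deriveStreamSeed(seed, 6L))$stimulus
  if (name == "receptive-fields") {
    simPatches <- samplePatches(imgs, p$patchSide, window,
                                seed = deriveStreamSeed(seed, 7L))
    simStim <- onOffEncodeStream(simPatches, onOffEncoderConfig(xi = manifest$xi),
                                 seed = deriveStreamSeed(seed, 8L))
  }
  raster <- simulateNetwork(fit$params, config, window, stimulus = simStim,
                            seed = deriveStreamSeed(seed, 9L))

  # analyses
  rec <- spikes(raster)[, seq_len(p$N), drop = FALSE]
  utils::write.csv(fit$metrics, file.path(outputDir, "metrics.csv"),
                   row.names = FALSE)
  writeRasterTSV(raster, file.path(outputDir, "raster.tsv"))
  writeParametersJSON(fit$params, file.path(outputDir, "weights.json"),
                      config = config, seed = seed)
  writeParametersCSV(fit$params, file.path(outputDir, "weights.csv"),
                     file.path(outputDir, "thresholds.csv"))

  bursts <- detectBursts(rec)
  if (length(burstSizes(bursts))) {
    utils::write.csv(data.frame(size = burstSizes(bursts),
                                duration = burstDurations(bursts)),
                     file.path(outputDir, "analysis", "bursts.csv"),
                     row.names = FALSE)
    slope <- tryCatch(fitPowerLawSlope(bursts), error = function(e) NULL)
    if (!is.null(slope))
      manifest$burstSlope <- slope$slope
  }
  census <- countPatternsAndSequences(rec, lengths = c(2, 3, 5, 10))
  utils::write.csv(census@census,
                   file.path(outputDir, "analysis", "sequence_census.csv"),
                   row.names = FALSE)
  manifest$iGauss <- tryCatch(iGauss(rec), error = function(e) NA_real_)
  if (name == "evoked-replay") {
    graph <- extractStrongChains(fit$params, roots = p$N + 1:3)
    writeChainTSV(graph, file.path(outputDir, "analysis", "chains.tsv"))
  }
  if (name == "receptive-fields") {
    map <- spikeTriggeredAverage(raster, simPatches, nNeurons = p$N)
    writeReceptiveFieldPGM(map, file.path(outputDir, "analysis",
                                          "receptive_fields.pgm"))
  }

  cfg <- list(preset = name, scale = scale, nSteps = nSteps,
              network = list(nNeurons = config@nNeurons, pMax = config@pMax,
                             p0 = config@p0, nExternal = config@nExternal),
              learning = list(epsilon = lconfig@epsilon, cKappa = lconfig@cKappa,
                              cEta = lconfig@cEta, cZeta = lconfig@cZeta,
                              tau = lconfig@tau, Tavg = lconfig@Tavg,
                              delta = lconfig@delta, variant = lconfig@variant),
              seed = seed)
  yaml::write_yaml(cfg, file.path(outputDir, "config.yaml"))
  manifest$configHash <- hashString(yaml::as.yaml(cfg))
  manifest$stepsDone <- fit$stepsDone
  manifest$diverged <- fit$diverged
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest$outputs <- list.files(outputDir, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
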