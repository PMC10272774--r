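## End-to-end pipeline: simulate/load -> (preprocess) -> decompose ->
## train on day 1 -> predict later days -> evaluate accuracy and stability.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Unknown keys are
#' rejected. The configuration round-trips losslessly through JSON via
#' [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param ... named overrides of the defaults listed below.
#' @return a named list with class attribute "synergykitConfig".
#' @examples
#' cfg <- pipelineConfig(vafThreshold = 0.85)
#' cfg$vafThreshold
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    # synthetic protocol
    nSubjects = 1L, nDays = 5L, channels = 3L, r = 2L, nCycles = 30L,
    samplesPerCycle = 200L, noiseSigma = 0.05, samplingRate = 50,
    restSeconds = 1, groupSplit = 1, groupScale = 1.5,
    # preprocessing (raw-EMG inputs only; synthetic data are envelopes)
    bandLow = 20, bandHigh = 450, envCutoff = 4, normalize = "max",
    # decomposition
    method = "mcr_als", alpha = 0.03, qTol = 0.01, maxIter = 1000L,
    vafThreshold = 0.8, autoOrder = FALSE, nmfFreshSeeds = TRUE,
    # kinematics
    angleCutoff = 2,
    # regressor
    nLayers = 5L, hiddenUnits = 48L, dropout = 0.3, windowLength = 100L,
    stride = 20L, epochs = 30L, learningRate = 1e-3, batchSize = 32L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "synergykitConfig")
}

#' @rdname pipelineConfig
#' @param config a configuration list from [pipelineConfig()].
#' @param path JSON file path.
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, lst)
}

.decomposeSession <- function(D, cfg, seed) {
  # per-session amplitude normalization (default "max") makes channel
  # scales -- including the day-gain drift -- comparable across sessions
  D <- normalizeChannels(D, cfg$normalize)
  stop_ <- StoppingRule(cfg$qTol, cfg$maxIter)
  r <- cfg$r
  if (isTRUE(cfg$autoOrder))
    r <- selectOrder(D, method = cfg$method, vafThreshold = cfg$vafThreshold,
                     stop = stop_, alpha = cfg$alpha, seed = seed)
  switch(cfg$method,
         mcr_als = mcrAls(D, r, stop = stop_, alpha = cfg$alpha),
         nmf = nmfSynergy(D, r, stop = stop_, seed = seed),
         pca = pcaSynergy(D, r),
         stop("unknown method: ", cfg$method))
}

.referenceAngle <- function(rec, cfg) {
  sr <- rec$accel@samplingRate
  nRest <- max(2L, round(cfg$restSeconds * sr))
  static <- AccelTrace(rec$accel@ax[seq_len(nRest)],
                       rec$accel@ay[seq_len(nRest)],
                       rec$accel@az[seq_len(nRest)], sr)
  g <- calibrateGravity(static, minSeconds = min(cfg$restSeconds, 0.5))
  angleFromAccel(rec$accel, cutoff = cfg$angleCutoff, gRef = g)
}

#' Run the full analysis pipeline on a session set
#'
#' For every subject: decompose each recording into synergies, derive the
#' reference angle from the accelerometer, train the Bi-LSTM on the day-1
#' training set, predict every other recording, and score per-day accuracy
#' (correlation, MAE) plus cross-day synergy stability. MCR-ALS
#' decompositions are deterministic; with `nmfFreshSeeds = TRUE` each NMF
#' decomposition draws a fresh seeded initialisation, reproducing the
#' instability a random start induces across days.
#'
#' @param sessions a [SessionSet-class]; `NULL` simulates the configured
#'   protocol first.
#' @param config a [pipelineConfig()] list.
#' @param seed master integer seed; every stage seed derives from it.
#' @param outDir optional directory; when given, the resolved config and the
#'   reports are written there as JSON together with a manifest.
#' @return list with `accuracy` (per-subject list of [accuracyReport()]
#'   results, days >= 2 held out), `day1Accuracy` (the day-1 test set),
#'   `stability` (per-subject [synergyStability()] across days), `models`,
#'   and `config`.
#' @export
runPipeline <- function(sessions = NULL, config = pipelineConfig(),
                        seed = 1L, outDir = NULL) {
  if (is.null(sessions))
    sessions <- makeProtocol(nSubjects = config$nSubjects,
                             nDays = config$nDays, seed = seed,
                             groupSplit = config$groupSplit,
                             groupScale = config$groupScale,
                             channels = config$channels, r = config$r,
                             nCycles = config$nCycles,
                             samplesPerCycle = config$samplesPerCycle,
                             noiseSigma = config$noiseSigma,
                             samplingRate = config$samplingRate,
                             restSeconds = config$restSeconds)
  subjects <- sort(unique(vapply(sessions@recordings,
                                 function(r) r$subject, 1L)))
  accuracy <- list()
  day1Accuracy <- list()
  stability <- list()
  models <- list()
  for (s in subjects) {
    recs <- Filter(function(r) r$subject == s, sessions@recordings)
    train <- Filter(function(r) r$day == 1L && r$set == 1L, recs)[[1]]
    others <- Filter(function(r) !(r$day == 1L && r$set == 1L), recs)
    decompSeed <- function(rec) seed + 1000L * rec$day + rec$set
    dTrain <- .decomposeSession(train$emg, config, decompSeed(train))
    aTrain <- .referenceAngle(train, config)
    model <- trainAngleRegressor(dTrain, aTrain, nLayers = config$nLayers,
                                 hiddenUnits = config$hiddenUnits,
                                 dropout = config$dropout,
                                 windowLength = config$windowLength,
                                 stride = config$stride,
                                 epochs = config$epochs,
                                 learningRate = config$learningRate,
                                 batchSize = config$batchSize, seed = seed)
    pred <- numeric(0)
    actual <- numeric(0)
    dayLab <- integer(0)
    setLab <- integer(0)
    dayDecomps <- list(`1` = dTrain)
    for (rec in others) {
      dseed <- if (isTRUE(config$nmfFreshSeeds)) decompSeed(rec) else seed
      dec <- .decomposeSession(rec$emg, config, dseed)
      if (rec$set == 1L) dayDecomps[[as.character(rec$day)]] <- dec
      ref <- .referenceAngle(rec, config)
      p <- predictAngle(model, dec)
      pred <- c(pred, angleValues(p))
      actual <- c(actual, angleValues(ref))
      dayLab <- c(dayLab, rep(rec$day, length(angleValues(p))))
      setLab <- c(setLab, rep(rec$set, length(angleValues(p))))
    }
    heldOut <- dayLab >= 2L
    accuracy[[as.character(s)]] <-
      if (any(heldOut)) accuracyReport(pred[heldOut], actual[heldOut],
                                       dayLab[heldOut]) else NULL
    day1Test <- dayLab == 1L
    day1Accuracy[[as.character(s)]] <-
      if (any(day1Test)) accuracyReport(pred[day1Test], actual[day1Test],
                                        dayLab[day1Test]) else NULL
    stability[[as.character(s)]] <-
      if (length(dayDecomps) >= 2L) synergyStability(unname(dayDecomps))
      else NULL
    models[[as.character(s)]] <- model
  }
  result <- list(accuracy = accuracy, day1Accuracy = day1Accuracy,
                 stability = stability, models = models, config = config,
                 seed = seed)
  if (!is.null(outDir)) .writeRunArtifacts(result, outDir)
  result
}

.writeRunArtifacts <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writePipelineConfig(result$config, file.path(outDir, "config.json"))
  rep <- list(seed = result$seed,
              accuracy = lapply(result$accuracy, function(a)
                if (is.null(a)) NULL else a["perDay" != names(a)] |>
                  c(list(perDay = a$perDay))),
              stability = lapply(result$stability, function(s)
                if (is.null(s)) NULL
                else list(method = s$method, mean = s$mean, sd = s$sd)))
  jsonlite::write_json(rep, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  files <- c("config.json", "report.json")
  manifest <- list(seed = result$seed,
                   files = lapply(setNames(nm = files), function(f)
                     list(path = f,
                          md5 = unname(tools::md5sum(file.path(outDir, f))))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(outDir)
}
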