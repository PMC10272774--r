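## Synthetic multi-day sEMG + accelerometer sessions with known ground truth.
##
## The generator works at the envelope level: it composes the bilinear model
## D = diag(day gains) * C * S + E directly, because that is what synergy
## extraction consumes. Activation time courses are raised-cosine bursts
## phase-locked to a cyclic 0-90 degree elbow flexion/extension trajectory,
## with per-cycle amplitude and timing jitter, so that every synergy has a
## rest interval in every cycle (pure variables exist for SIMPLISMA).

# Run code with a private RNG state so generation is reproducible without
# clobbering the caller's stream.
.withSeed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Angle trajectory and burst activations for one block of cycles.
# Assumes the caller has set the RNG state. Returns angle (degrees) and the
# r x (nCycles*spc) activation matrix; with jitter = FALSE the trajectory is
# the nominal 0 -> 90 -> 0 raised-cosine cycle.
.cycleProfiles <- function(nCycles, spc, r, jitter = TRUE) {
  n <- nCycles * spc
  angle <- numeric(n)
  S <- matrix(0, r, n)
  tt <- (seq_len(spc) - 1) / spc
  for (cy in seq_len(nCycles)) {
    peak <- if (jitter) 90 * runif(1, 0.88, 1.0) else 90
    fl <- if (jitter) runif(1, 0.45, 0.55) else 0.5
    up <- tt < fl
    th <- numeric(spc)
    th[up] <- peak * 0.5 * (1 - cos(pi * tt[up] / fl))
    th[!up] <- peak * 0.5 * (1 + cos(pi * (tt[!up] - fl) / (1 - fl)))
    idx <- (cy - 1) * spc + seq_len(spc)
    angle[idx] <- th
    # phase boundaries: flexion/extension halves for r = 2, equal slices else
    bounds <- if (r == 2) c(0, fl, 1) else seq(0, 1, length.out = r + 1)
    for (k in seq_len(r)) {
      lo <- bounds[k]; hi <- bounds[k + 1]
      inside <- tt >= lo & tt < hi
      amp <- (peak / 90) * (if (jitter) runif(1, 0.85, 1.0) else 1)
      burst <- numeric(spc)
      burst[inside] <- amp * sin(pi * (tt[inside] - lo) / (hi - lo))^2
      S[k, idx] <- S[k, idx] + burst
    }
  }
  list(angle = angle, S = S)
}

#' Generate burst-shaped synergy activation profiles
#'
#' Builds `r` smooth, non-negative activation time courses phase-locked to a
#' cyclic elbow flexion/extension movement. Each synergy occupies one phase of
#' the cycle as a raised-cosine burst with per-cycle amplitude and timing
#' jitter, so each row returns to (near) zero in every cycle and no row is a
#' scalar multiple of another.
#'
#' @param nCycles number of movement cycles.
#' @param samplesPerCycle envelope samples per cycle (>= 20).
#' @param r number of synergies (>= 1).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return an `r x (nCycles * samplesPerCycle)` non-negative matrix.
#' @examples
#' S <- makeActivationProfiles(nCycles = 3, samplesPerCycle = 50, r = 2, seed = 1)
#' all(S >= 0)
#' @export
makeActivationProfiles <- function(nCycles, samplesPerCycle, r, seed = 1L) {
  if (nCycles < 1 || samplesPerCycle < 20 || r < 1)
    stop("nCycles >= 1, samplesPerCycle >= 20 and r >= 1 are required")
  .withSeed(seed, .cycleProfiles(nCycles, samplesPerCycle, r)$S)
}

# Default 3-muscle x 2-synergy weight template: a flexion synergy loading
# biceps/forearm flexor and an extension-phase synergy loading the deltoid.
.defaultC <- function(channels, r) {
  if (channels == 3 && r == 2) {
    matrix(c(0.20, 1.00, 0.70,
             0.90, 0.15, 0.35), nrow = 3, ncol = 2,
           dimnames = list(c("DA", "BI", "FCR"), NULL))
  } else {
    matrix(runif(channels * r, 0.1, 1), channels, r)
  }
}

#' Draw a synthetic subject's generating model
#'
#' Creates the ground truth of one subject: a perturbed copy of the template
#' synergy matrix, burst activation time courses tied to the cyclic angle
#' trajectory, per-day multiplicative channel gains (day 1 is the unit
#' reference), mild additive day perturbations of C, and the additive-noise
#' level. A short static rest (angle 0, silent muscles) is prepended so each
#' session carries its own gravity-calibration segment.
#'
#' @param channels number of EMG channels.
#' @param r number of generating synergies.
#' @param nCycles movement cycles per session.
#' @param samplesPerCycle envelope samples per cycle.
#' @param nDays number of recording days.
#' @param noiseSigma additive noise sd as a fraction of signal RMS.
#' @param samplingRate envelope sampling rate in Hz.
#' @param restSeconds static rest prepended to each session, in seconds.
#' @param groupScale amplitude scaling of the subject's group.
#' @param dayGainSd,dayShiftSd sd of the log-normal day gains and of the
#'   additive day perturbation of C (days after day 1).
#' @param seed integer seed.
#' @return a [GroundTruth-class] object.
#' @export
makeGroundTruth <- function(channels = 3L, r = 2L, nCycles = 30L,
                            samplesPerCycle = 200L, nDays = 5L,
                            noiseSigma = 0.05, samplingRate = 50,
                            restSeconds = 1, groupScale = 1,
                            dayGainSd = 0.1, dayShiftSd = 0.03, seed = 1L) {
  if (channels < 1 || r < 1 || nDays < 1) stop("non-positive dimensions")
  .withSeed(seed, {
    C <- .defaultC(channels, r) * exp(matrix(rnorm(channels * r, 0, 0.15),
                                             channels, r))
    C <- C * groupScale
    prof <- .cycleProfiles(nCycles, samplesPerCycle, r)
    nRest <- round(restSeconds * samplingRate)
    S <- cbind(matrix(0, r, nRest), prof$S)
    angle <- c(numeric(nRest), prof$angle)
    gains <- rbind(rep(1, channels),
                   if (nDays > 1)
                     matrix(exp(rnorm((nDays - 1) * channels, 0, dayGainSd)),
                            nDays - 1, channels))
    gains <- gains[seq_len(nDays), , drop = FALSE]
    shifts <- vector("list", nDays)
    shifts[[1]] <- matrix(0, channels, r)
    if (nDays > 1) for (d in 2:nDays) {
      sh <- matrix(rnorm(channels * r, 0, dayShiftSd), channels, r)
      shifts[[d]] <- pmax(sh, -C)   # keep C + shift non-negative
    }
    new("GroundTruth", CTrue = C, STrue = S, angleTrue = angle,
        dayGains = gains, dayShifts = shifts, noiseSigma = noiseSigma,
        samplingRate = samplingRate)
  })
}

#' Synthesize one recording session
#'
#' Composes the envelope matrix D = diag(g_day) (C + day shift) S + E with
#' zero-mean Gaussian noise scaled to `noiseSigma` times the signal RMS and
#' clipped at zero (envelopes are non-negative), and the matching tri-axial
#' accelerometer trace: Ax = g sin(theta) so that inverting
#' theta = 90 - arccos(Ax/g) recovers the angle, Az = g cos(theta), Ay = 0,
#' each plus noise truncated at three standard deviations.
#'
#' @param truth a [GroundTruth-class] object.
#' @param day day index within the truth's day-gain table.
#' @param seed integer seed for the noise draws.
#' @return a list with elements `emg` ([EnvelopeMatrix-class]),
#'   `accel` ([AccelTrace-class], uncalibrated) and `angle`
#'   ([AngleTrace-class], the ground-truth angle).
#' @examples
#' gt <- makeGroundTruth(nCycles = 3, samplesPerCycle = 40, noiseSigma = 0)
#' ses <- synthesizeSession(gt, day = 1, seed = 2)
#' ses$emg
#' @export
synthesizeSession <- function(truth, day, seed = 1L) {
  stopifnot(is(truth, "GroundTruth"))
  if (length(day) != 1L || day < 1 || day > nrow(truth@dayGains))
    stop("unknown day: ", day)
  .withSeed(seed, {
    Cd <- pmax(truth@CTrue + truth@dayShifts[[day]], 0)
    D0 <- (truth@dayGains[day, ] * Cd) %*% truth@STrue
    n <- ncol(D0)
    sig <- truth@noiseSigma
    if (sig > 0) {
      s <- sig * sqrt(mean(D0^2))
      D <- pmax(D0 + matrix(rnorm(length(D0), 0, s), nrow(D0), n), 0)
    } else D <- D0
    g <- 1
    thr <- truth@angleTrue * pi / 180
    clipNoise <- function(n, s) {
      if (s <= 0) return(numeric(n))
      pmin(pmax(rnorm(n, 0, s), -3 * s), 3 * s)
    }
    sa <- sig * g
    accel <- AccelTrace(ax = g * sin(thr) + clipNoise(n, sa),
                        ay = clipNoise(n, sa),
                        az = g * cos(thr) + clipNoise(n, sa),
                        samplingRate = truth@samplingRate)
    list(emg = EnvelopeMatrix(D, truth@samplingRate,
                              rownames(truth@CTrue)),
         accel = accel,
         angle = AngleTrace(truth@angleTrue, truth@samplingRate))
  })
}

#' Generate a full multi-subject, multi-day protocol
#'
#' Emulates the study design used throughout the package's evaluation:
#' each subject performs cyclic elbow flexion/extension on `nDays`
#' consecutive days; day 1 contributes two recording sets (train/test),
#' every later day one set. Subjects split into two amplitude groups
#' ("high"/"low", scaled by `groupScale`), mirroring the larger average sEMG
#' amplitude of one cohort group.
#'
#' @param nSubjects number of subjects (default 12).
#' @param nDays number of days (default 5).
#' @param seed integer seed.
#' @param groupSplit fraction of subjects in the high-amplitude group
#'   (default 7/12).
#' @param groupScale amplitude ratio between the two groups (default 1.5).
#' @param ... further arguments passed to [makeGroundTruth()]
#'   (channels, r, nCycles, samplesPerCycle, noiseSigma, ...).
#' @return a [SessionSet-class] with all recordings and per-subject truths.
#' @examples
#' ss <- makeProtocol(nSubjects = 1, nDays = 1, seed = 3,
#'                    nCycles = 2, samplesPerCycle = 40)
#' length(ss@recordings)  # day 1 has two sets
#' @export
makeProtocol <- function(nSubjects = 12L, nDays = 5L, seed = 1L,
                         groupSplit = 7 / 12, groupScale = 1.5, ...) {
  if (nSubjects < 1 || nDays < 1) stop("nSubjects and nDays must be >= 1")
  .withSeed(seed, {
    nHigh <- round(nSubjects * groupSplit)
    groups <- setNames(rep(c("high", "low"), c(nHigh, nSubjects - nHigh)),
                       paste0("S", seq_len(nSubjects)))
    subjSeeds <- sample.int(.Machine$integer.max, nSubjects)
    sesSeeds <- matrix(sample.int(.Machine$integer.max, nSubjects * (nDays + 1)),
                       nSubjects, nDays + 1)
    truths <- vector("list", nSubjects)
    recordings <- list()
    sr <- NULL
    for (s in seq_len(nSubjects)) {
      scale <- if (groups[s] == "high") groupScale else 1
      truths[[s]] <- makeGroundTruth(nDays = nDays, groupScale = scale,
                                     seed = subjSeeds[s], ...)
      sr <- truths[[s]]@samplingRate
      for (d in seq_len(nDays)) {
        nSets <- if (d == 1) 2L else 1L
        for (st in seq_len(nSets)) {
          ses <- synthesizeSession(truths[[s]], d,
                                   seed = sesSeeds[s, d + (st - 1) * nDays])
          recordings[[length(recordings) + 1L]] <-
            list(subject = s, day = d, set = st, emg = ses$emg,
                 accel = ses$accel, angle = ses$angle,
                 group = unname(groups[s]))
        }
      }
    }
    names(truths) <- names(groups)
    new("SessionSet", recordings = recordings, truths = truths,
        samplingRate = sr, groups = groups)
  })
}

#' Write a SessionSet to CSV files with a JSON sidecar
#'
#' One CSV per recording (columns time, ch1..chm, Ax, Ay, Az, angle), each
#' starting with a `# sampling_rate_hz=` header line, plus `manifest.json`
#' holding protocol metadata and the per-subject ground truth.
#'
#' @param sessions a [SessionSet-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths of the written CSV files.
#' @export
writeSessionSet <- function(sessions, dir) {
  stopifnot(is(sessions, "SessionSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  meta <- list(sampling_rate_hz = sessions@samplingRate,
               groups = as.list(sessions@groups), recordings = list())
  for (rec in sessions@recordings) {
    v <- envValues(rec$emg)
    df <- data.frame(time = (seq_len(ncol(v)) - 1) / rec$emg@samplingRate,
                     t(v),
                     Ax = rec$accel@ax, Ay = rec$accel@ay, Az = rec$accel@az,
                     angle = rec$angle@theta, check.names = FALSE)
    fn <- file.path(dir, sprintf("subject%02d_day%d_set%d.csv",
                                 rec$subject, rec$day, rec$set))
    con <- file(fn, "w")
    writeLines(sprintf("# sampling_rate_hz=%g", rec$emg@samplingRate), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    paths <- c(paths, fn)
    meta$recordings[[length(meta$recordings) + 1L]] <-
      list(file = basename(fn), subject = rec$subject, day = rec$day,
           set = rec$set, group = rec$group)
  }
  meta$truths <- lapply(sessions@truths, function(gt)
    list(C_true = gt@CTrue, S_true = gt@STrue, angle_true = gt@angleTrue,
         day_gains = gt@dayGains, noise_sigma = gt@noiseSigma))
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read one session CSV written by [writeSessionSet()]
#'
#' @param path CSV path; the first line must carry the sampling-rate header.
#' @return a list with `emg` ([EnvelopeMatrix-class]), `accel`
#'   ([AccelTrace-class]) and, when present in the file, `angle`
#'   ([AngleTrace-class]).
#' @export
readSessionCSV <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#\\s*sampling_rate_hz=", first))
    stop("missing sampling-rate header in ", path)
  sr <- as.numeric(sub("^#\\s*sampling_rate_hz=", "", first))
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  acols <- c("Ax", "Ay", "Az")
  chans <- setdiff(colnames(df), c("time", acols, "angle"))
  out <- list(
    emg = EnvelopeMatrix(t(as.matrix(df[, chans, drop = FALSE])), sr, chans),
    accel = AccelTrace(df$Ax, df$Ay, df$Az, sr))
  if ("angle" %in% colnames(df)) out$angle <- AngleTrace(df$angle, sr)
  out
}
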