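#' Standard 10-20 channel labels
#'
#' The 30-channel effective montage of a 32-electrode cap (mastoid
#' references excluded), in the electrode-index order used throughout:
#' index 1 is Fp1, 10 is FCz, 20 is CPz, 28 is O1.
#'
#' @param n number of channels (first n labels; generic names past 30).
#' @return Character vector of channel labels.
#' @export
montage1020 <- function(n = 30) {
  base <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "FT7", "FC3", "FCz", "FC4", "FT8",
            "T3", "C3", "Cz", "C4", "T4",
            "TP7", "CP3", "CPz", "CP4", "TP8",
            "T5", "P3", "Pz", "P4", "T6",
            "O1", "Oz", "O2")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("ch", seq.int(length(base) + 1L, n)))
}

#' Synthetic cohort configuration
#'
#' Parameters of the regularity-mixture generator. Each channel is
#' \code{x(t) = rho * osc(t) + (1 - rho) * noise(t)} with a unit-variance
#' sinusoid at a subject-specific alpha-band frequency and unit-variance
#' noise; \code{rho} (the regularity) is sex-dependent:
#' \code{rho_male = baseRegularity + effect},
#' \code{rho_female = baseRegularity - effect}, so at a positive effect size
#' female signals are the more irregular, higher-entropy ones. Defaults
#' emulate the study cohort: 13 male and 15 female subjects, 30 channels,
#' 1000 Hz, 300 s retained, 1 s epochs.
#'
#' @param nMale,nFemale subject counts.
#' @param nChannels number of channels.
#' @param fs sampling rate in Hz.
#' @param durationS recording length in seconds.
#' @param epochLenS epoch length in seconds.
#' @param baseRegularity baseline regularity rho0 in (0, 1).
#' @param effect sex offset delta; per-sex regularities are clipped into
#'   (0, 1).
#' @param subjectSd between-subject SD of regularity.
#' @param channelJitter per-channel regularity SD.
#' @param oscFreqRange oscillation frequency range in Hz.
#' @param noiseSpectrum \code{"pink"} (1/f spectral shaping) or
#'   \code{"white"}.
#' @param seed master seed; subject seeds are derived deterministically.
#' @return A list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nMale = 13, nFemale = 15, nChannels = 30,
                         fs = 1000, durationS = 300, epochLenS = 1.0,
                         baseRegularity = 0.5, effect = 0.3,
                         subjectSd = 0.05, channelJitter = 0.02,
                         oscFreqRange = c(8, 12),
                         noiseSpectrum = c("pink", "white"), seed = 1) {
  noiseSpectrum <- match.arg(noiseSpectrum)
  stopifnot(nMale >= 1, nFemale >= 1, nChannels >= 1, fs > 0,
            durationS > 0, epochLenS > 0,
            baseRegularity > 0, baseRegularity < 1,
            effect >= 0, subjectSd >= 0, channelJitter >= 0,
            length(oscFreqRange) == 2, oscFreqRange[1] > 0,
            oscFreqRange[2] < fs / 2, oscFreqRange[1] <= oscFreqRange[2])
  structure(list(nMale = as.integer(nMale), nFemale = as.integer(nFemale),
                 nChannels = as.integer(nChannels), fs = fs,
                 durationS = durationS, epochLenS = epochLenS,
                 baseRegularity = baseRegularity, effect = effect,
                 subjectSd = subjectSd, channelJitter = channelJitter,
                 oscFreqRange = oscFreqRange, noiseSpectrum = noiseSpectrum,
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Miniature cohort for fast end-to-end runs
#'
#' 2 male + 2 female subjects, 3 channels, 20 s at 250 Hz (high enough that
#' the standard 50 Hz notch and 0.15-45 Hz band-pass stay inside Nyquist);
#' all other parameters at their defaults.
#'
#' @param seed master seed.
#' @return A \code{"CohortConfig"}.
#' @export
fixtureCohortConfig <- function(seed = 1) {
  cohortConfig(nMale = 2, nFemale = 2, nChannels = 3, fs = 250,
               durationS = 20, seed = seed)
}

# deterministic per-subject seed derived from the master seed; kept < 2^31
subjectSeedFor <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) %% 1e6 * 2099 + i * 7919) %% 2147483629 + 1)
}

#' Unit-variance 1/f (pink) noise by spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain with a
#' 1/sqrt(f) amplitude weight (1/f power), the DC component removed, and the
#' result standardized. Draws from the current RNG stream.
#'
#' @param n number of samples.
#' @return Numeric vector of length n, mean 0, SD 1.
#' @export
pinkNoise <- function(n) {
  pinkNoiseW(n, pinkWeights(n))
}

# 1/sqrt(f) amplitude weights, DC zeroed; mirrored for the negative half
pinkWeights <- function(n) {
  f <- pmin(seq_len(n) - 1, n - seq_len(n) + 1)
  f[1] <- 1
  w <- 1 / sqrt(f)
  w[1] <- 0
  w
}

pinkNoiseW <- function(n, w) {
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * w, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

clip01 <- function(x, lo = 0.01, hi = 0.99) pmin(pmax(x, lo), hi)

#' Generate one synthetic subject recording
#'
#' Per channel c, \code{x_c(t) = rho_c * osc_c(t) + (1 - rho_c) * n_c(t)}:
#' \code{osc_c} a unit-variance sinusoid at the subject's frequency (drawn
#' once per subject from \code{oscFreqRange}) with a random per-channel
#' phase, \code{n_c} unit-variance noise of the configured spectrum, and
#' \code{rho_c = clip(rho_sex + subject effect + channel jitter, 0.01,
#' 0.99)}. Deterministic given \code{subjectSeed}.
#'
#' @param sex \code{"male"} or \code{"female"}.
#' @param cfg a [cohortConfig()].
#' @param subjectSeed per-subject RNG seed.
#' @param subjectId identifier for the resulting recording.
#' @return An [EEGRecording-class] of \code{durationS * fs} samples.
#' @export
generateSubject <- function(sex = c("male", "female"), cfg = cohortConfig(),
                            subjectSeed = 1, subjectId = "s01") {
  sex <- match.arg(sex)
  stopifnot(inherits(cfg, "CohortConfig"))
  n <- round(cfg$durationS * cfg$fs)
  rhoSex <- clip01(cfg$baseRegularity +
                     if (sex == "male") cfg$effect else -cfg$effect,
                   lo = .Machine$double.eps, hi = 1 - .Machine$double.eps)
  tt <- (seq_len(n) - 1) / cfg$fs
  sig <- matrix(0, cfg$nChannels, n)
  pw <- if (cfg$noiseSpectrum == "pink") pinkWeights(n)
  withr::with_seed(subjectSeed, {
    freq <- stats::runif(1, cfg$oscFreqRange[1], cfg$oscFreqRange[2])
    subjEff <- stats::rnorm(1, 0, cfg$subjectSd)
    for (c in seq_len(cfg$nChannels)) {
      phase <- stats::runif(1, 0, 2 * pi)
      jit <- stats::rnorm(1, 0, cfg$channelJitter)
      rho <- clip01(rhoSex + subjEff + jit)
      osc <- sqrt(2) * sin(2 * pi * freq * tt + phase)
      nz <- if (cfg$noiseSpectrum == "pink") pinkNoiseW(n, pw)
            else stats::rnorm(n)
      sig[c, ] <- rho * osc + (1 - rho) * nz
    }
  })
  EEGRecording(sig, fs = cfg$fs, channelNames = montage1020(cfg$nChannels),
               subjectId = subjectId, sex = sex)
}

#' Generate the full synthetic cohort
#'
#' Subject seeds are derived from the master seed, so the cohort is
#' reproducible bit-for-bit and subjects are independent. With \code{FUN}
#' each recording is handed to \code{FUN} as soon as it is generated and
#' only the results are kept — use this to stream the full-scale cohort
#' without holding 28 recordings in memory.
#'
#' @param cfg a [cohortConfig()].
#' @param FUN optional \code{function(recording)} applied per subject.
#' @return \code{list(recordings=, manifest=)}, or \code{list(results=,
#'   manifest=)} when \code{FUN} is given. The manifest is a
#'   \code{data.frame} with subject id, sex and seed.
#' @export
generateCohort <- function(cfg = cohortConfig(), FUN = NULL) {
  stopifnot(inherits(cfg, "CohortConfig"))
  ids <- c(sprintf("m%02d", seq_len(cfg$nMale)),
           sprintf("f%02d", seq_len(cfg$nFemale)))
  sexes <- rep(c("male", "female"), c(cfg$nMale, cfg$nFemale))
  seeds <- vapply(seq_along(ids), function(i) subjectSeedFor(cfg$seed, i),
                  integer(1))
  manifest <- data.frame(subject_id = ids, sex = sexes, seed = seeds,
                         stringsAsFactors = FALSE)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    rec <- generateSubject(sexes[i], cfg, seeds[i], ids[i])
    out[[i]] <- if (is.null(FUN)) rec else FUN(rec)
  }
  if (is.null(FUN)) list(recordings = out, manifest = manifest)
  else list(results = out, manifest = manifest)
}

#' Write a cohort to disk in the delimited dialect
#'
#' One \code{<subject>.csv} (+ JSON sidecar) per subject and a
#' \code{manifest.json} listing ids, sexes and seeds.
#'
#' @param cfg a [cohortConfig()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- generateCohort(cfg, FUN = function(rec) {
    writeRecording(rec, file.path(dir, paste0(subjectId(rec), ".csv")))
  })
  manifest <- res$manifest
  manifest$file <- paste0(manifest$subject_id, ".csv")
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(config = unclass(cfg), subjects = manifest),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
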