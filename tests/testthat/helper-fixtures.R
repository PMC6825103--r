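# Small in-code fixtures shared across test files.

toyRecording <- function(nChannels = 2, nSamples = 1000, fs = 100,
                         seed = 1, sex = "male", subjectId = "s01") {
  withr::with_seed(seed, {
    EEGRecording(matrix(rnorm(nChannels * nSamples), nChannels),
                 fs = fs, channelNames = paste0("ch", seq_len(nChannels)),
                 subjectId = subjectId, sex = sex)
  })
}

# tiny feature setup for classifier tests: two well separated 2-D Gaussian
# classes (centres +-3, unit variance)
gaussXy <- function(n = 500, centre = 3, seed = 1) {
  withr::with_seed(seed, {
    nf <- n %/% 2; nm <- n - nf
    X <- rbind(matrix(rnorm(nf * 2, mean = centre), nf),
               matrix(rnorm(nm * 2, mean = -centre), nm))
    colnames(X) <- c("f1", "f2")
    y <- factor(rep(c("female", "male"), c(nf, nm)),
                levels = c("male", "female"))
    list(X = X, y = y)
  })
}

# small entropy feature matrix from the miniature cohort, cached per session
tinyFeatureCache <- new.env(parent = emptyenv())
tinyFeatures <- function(seed = 5) {
  key <- paste0("s", seed)
  if (is.null(tinyFeatureCache[[key]])) {
    cfg <- fixtureCohortConfig(seed = seed)
    coh <- generateCohort(cfg)
    ep <- do.call(bindEpochSets, lapply(coh$recordings, segmentEpochs))
    tinyFeatureCache[[key]] <- extractFeatures(ep)
  }
  tinyFeatureCache[[key]]
}
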