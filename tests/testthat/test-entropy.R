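test_that("tolerance is rCoeff times the population SD", {
  expect_identical(computeTolerance(c(0, 2), 0.25), 0.25)
  withr::with_seed(1, {
    x <- rnorm(50)
    expect_equal(computeTolerance(x), 0.25 * popSd(x))
    for (a in c(0.5, 3, 10))
      expect_equal(computeTolerance(a * x), a * computeTolerance(x))
  })
  expect_warning(r0 <- computeTolerance(rep(4, 10)), "constant")
  expect_identical(r0, 0)
})

test_that("estimators give exact closed-form values on degenerate series", {
  const <- rep(2.5, 100)
  expect_identical(approxEntropy(const, 2, 0.1), 0)
  expect_identical(sampleEntropy(const, 2, 0.1), 0)
  expect_identical(fuzzyEntropy(const, 2, 0.1), 0)
  # widely separated increasing steps: no template pair ever matches
  expect_true(is.na(sampleEntropy(seq(0, 990, by = 10), 2, 0.5)))
  # single ordinal pattern
  expect_identical(permutationEntropy(1:50, 4), 0)
  # alternating series: 50 rising + 50 falling patterns, uniform over 2!
  expect_equal(permutationEntropy(rep_len(c(0, 1), 101), 2), 1)
})

test_that("compiled estimators match the naive oracles", {
  withr::with_seed(101, {
    for (i in 1:10) {
      n <- sample(c(60, 120, 200), 1)
      x <- rnorm(n)
      r <- 0.25 * popSd(x)
      expect_equal(approxEntropy(x, 2, r), apenRef(x, 2, r),
                   tolerance = 1e-10)
      expect_equal(sampleEntropy(x, 2, r), sampenRef(x, 2, r),
                   tolerance = 1e-10)
      expect_equal(fuzzyEntropy(x, 2, r, 2), fuzzyRef(x, 2, r, 2),
                   tolerance = 1e-10)
      expect_equal(permutationEntropy(x, 4), permRef(x, 4),
                   tolerance = 1e-10)
    }
    # ordinal tie handling on a series with many repeated values
    x <- sample(0:2, 300, replace = TRUE)
    expect_equal(permutationEntropy(x, 3), permRef(x, 3), tolerance = 1e-12)
  })
})

test_that("AE/SE/FE are affine invariant when r tracks 0.25 SD", {
  withr::with_seed(7, {
    x <- rnorm(150)
    r <- computeTolerance(x)
    for (ab in list(c(2.5, 1), c(0.3, -4), c(7, 100))) {
      y <- ab[1] * x + ab[2]
      ry <- computeTolerance(y)
      expect_equal(approxEntropy(y, 2, ry), approxEntropy(x, 2, r),
                   tolerance = 1e-12)
      expect_equal(sampleEntropy(y, 2, ry), sampleEntropy(x, 2, r),
                   tolerance = 1e-12)
      expect_equal(fuzzyEntropy(y, 2, ry), fuzzyEntropy(x, 2, r),
                   tolerance = 1e-12)
    }
  })
})

test_that("PE is invariant under strictly monotone transforms, in [0,1]", {
  withr::with_seed(8, {
    x <- rnorm(400)
    h <- permutationEntropy(x, 4)
    expect_gte(h, 0); expect_lte(h, 1)
    expect_identical(permutationEntropy(exp(x), 4), h)
    expect_identical(permutationEntropy(2 * x + 5, 4), h)
    expect_identical(permutationEntropy(x^3, 4), h)
  })
})

test_that("ApEn and SampEn increase as the tolerance shrinks (white noise)", {
  x <- withr::with_seed(20, rnorm(1000))
  sdx <- popSd(x)
  se <- vapply(c(0.5, 0.35, 0.25, 0.15) * sdx,
               function(r) sampleEntropy(x, 2, r), numeric(1))
  expect_true(all(diff(se) > 0))
  # ApEn is only monotone down to ~0.25 SD: below that the self-match bias
  # dominates and the statistic turns over
  ae <- vapply(c(0.5, 0.35, 0.25) * sdx,
               function(r) approxEntropy(x, 2, r), numeric(1))
  expect_true(all(diff(ae) > 0))
})

test_that("a pure tone has lower entropy than white noise", {
  tone <- sin(2 * pi * 10 * (0:999) / 1000)
  noise <- withr::with_seed(21, rnorm(1000))
  for (f in list(approxEntropy, sampleEntropy, fuzzyEntropy)) {
    expect_lt(f(tone, 2, 0.25 * popSd(tone)),
              f(noise, 2, 0.25 * popSd(noise)))
  }
})

test_that("extractFeatures lays out channel-major blocks with stable names", {
  # 30 channels x 4 measures = 120 features per epoch
  arr <- withr::with_seed(30, array(rnorm(2 * 30 * 50), c(2, 30, 50)))
  ep <- new("EpochSet", epochs = arr, subjectIds = rep("a", 2),
            labels = factor(c("male", "male"), levels = c("male", "female")),
            epochLenS = 1, fs = 50, channelNames = montage1020(30))
  fm <- suppressMessages(extractFeatures(ep))
  expect_identical(dim(featureValues(fm)), c(2L, 120L))
  info <- featureInfo(fm)
  expect_identical(info$channel[1:8],
                   rep(montage1020(2), each = 4))
  expect_identical(info$measure[1:8], rep(c("FE", "SE", "AE", "PE"), 2))
  expect_identical(rownames(info)[1], "Fp1_FE")
  expect_false(isNormalized(fm))

  fe <- suppressMessages(extractFeatures(ep, measures = "FE"))
  expect_identical(nrow(featureValues(fe)), 2L)
  expect_identical(ncol(featureValues(fe)), 30L)
  expect_error(extractFeatures(ep, measures = character(0)), "at least one")
})

test_that("identical epochs give identical feature rows", {
  one <- withr::with_seed(31, matrix(rnorm(3 * 60), 3))
  arr <- array(0, c(2, 3, 60))
  arr[1, , ] <- one; arr[2, , ] <- one
  ep <- new("EpochSet", epochs = arr, subjectIds = c("a", "a"),
            labels = factor(c("male", "male"), levels = c("male", "female")),
            epochLenS = 1, fs = 60, channelNames = c("c1", "c2", "c3"))
  v <- featureValues(suppressMessages(extractFeatures(ep)))
  expect_identical(v[1, ], v[2, ])
})

test_that("min-max normalization maps to [-1,1] with the stated conventions", {
  mk <- function(vals, subjects) {
    entrosex:::newEntropyFeatures(
      vals, matrix(TRUE, nrow(vals), ncol(vals)),
      channel = paste0("c", seq_len(ncol(vals))),
      measure = rep("FE", ncol(vals)),
      subjectIds = subjects,
      labels = rep(c("male", "female"), length.out = length(subjects)))
  }
  fm <- mk(cbind(c(1, 3, 5), c(2, 2, 2)), rep("s1", 3))
  nm <- minmaxNormalize(fm, "global")
  expect_identical(featureValues(nm)[, 1], c(-1, 0, 1))
  expect_identical(featureValues(nm)[, 2], c(0, 0, 0))  # constant -> 0
  expect_true(isNormalized(nm))
  expect_error(minmaxNormalize(nm, "global"), "already normalized")

  # test-time reuse of training stats clips out-of-range values
  test <- mk(cbind(c(0, 6), c(1, 3)), rep("s1", 2))
  reused <- minmaxNormalize(test, "global", fitStats = normStats(nm))
  expect_identical(featureValues(reused)[, 1], c(-1, 1))

  # per-subject grouping normalizes within each subject separately
  fm2 <- mk(cbind(c(1, 3, 10, 30)), c("a", "a", "b", "b"))
  nm2 <- minmaxNormalize(fm2, "per_subject")
  expect_identical(featureValues(nm2)[, 1], c(-1, 1, -1, 1))
})

test_that("undefined sample-entropy cells are flagged and droppable", {
  # epoch 1: a short scattered series whose template pairs all sit farther
  # apart than r = 0.25 SD, so SampEn has no matches and is undefined
  scattered <- c(58, 11, 68, 99, 53, 97, 67, 29, 36, 18, 55, 51)
  expect_true(is.na(sampleEntropy(scattered, 2, computeTolerance(scattered))))
  arr <- array(0, c(2, 1, 12))
  arr[1, 1, ] <- scattered
  arr[2, 1, ] <- rep(c(0, 1), 6)     # exact repeats: SampEn well defined
  ep <- new("EpochSet", epochs = arr, subjectIds = c("a", "a"),
            labels = factor(c("male", "male"), levels = c("male", "female")),
            epochLenS = 1, fs = 12, channelNames = "c1")
  fm <- suppressMessages(extractFeatures(ep, measures = c("SE", "FE")))
  expect_true(nanMask(fm)[1, 1])
  expect_false(any(nanMask(fm)[2, ]))
  kept <- suppressMessages(dropUndefinedEpochs(fm))
  expect_identical(nEpochs(kept), 1L)
})

test_that("feature tables round-trip through the delimited serialization", {
  fm <- tinyFeatures()
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(fm, path)
  back <- readFeatureTable(path)
  expect_equal(featureValues(back), featureValues(fm),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(as.character(epochLabels(back)),
                   as.character(epochLabels(fm)))
  expect_identical(featureInfo(back)$channel, featureInfo(fm)$channel)
  expect_identical(isNormalized(back), isNormalized(fm))
})
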