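test_that("stratified folds partition evenly and preserve class balance", {
  y <- rep(c("male", "female"), each = 50)
  f <- stratifiedFolds(y, k = 10, seed = 1)
  expect_identical(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 10))
  expect_true(all(table(f[y == "male"]) == 5))
  expect_true(all(table(f[y == "female"]) == 5))
  expect_identical(stratifiedFolds(y, 10, 1), f)
  expect_false(identical(stratifiedFolds(y, 10, 2), f))
  # uneven counts: overall fold sizes still differ by <= 1
  y2 <- rep(c("male", "female"), c(23, 34))
  f2 <- stratifiedFolds(y2, k = 5, seed = 3)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(stratifiedFolds(rep(c("male", "female"), c(3, 50)), 10),
               "at least k")
})

test_that("grid search scores every cell and breaks ties toward simplicity", {
  d <- gaussXy(n = 120, centre = 3, seed = 20)
  oneCell <- paramGrid(forestNt = 20, forestMd = 2,
                       linearPenalty = "l1", linearC = 1)
  gs <- gridSearch(d$X, d$y, oneCell, k = 4, seed = 1, classifier = "hybrid")
  expect_identical(nrow(gs$table), 1L)
  expect_identical(gs$best$nt, 20L)
  expect_true(gs$score >= 0 && gs$score <= 1)

  grid <- paramGrid(forestNt = c(5, 10), forestMd = c(1, 5),
                    linearPenalty = c("l1", "l2"), linearC = c(0.1, 1))
  gs2 <- gridSearch(d$X, d$y, grid, k = 4, seed = 2, classifier = "hybrid")
  expect_identical(nrow(gs2$table), 2L * 2L * 2L * 2L)
  # the chosen cell achieves the maximum of the exhaustive score table
  expect_equal(gs2$score, max(gs2$table$accuracy))
  # tie-break: re-run with a constant stub so that every cell ties
  stub <- list(fit = function(X, y, p) NULL,
               score = function(m, X) rep(1, nrow(X)))
  gs3 <- gridSearch(d$X, d$y, grid, k = 4, seed = 2, classifier = stub)
  expect_identical(gs3$best, list())   # stubs have a single empty cell
})

test_that("RF grid tie-breaking prefers smaller nt then smaller md", {
  # trivially separable data: every cell reaches accuracy 1, tie-break decides
  d <- gaussXy(n = 80, centre = 5, seed = 24)
  grid <- paramGrid(forestNt = c(50, 10), forestMd = c(4, 2),
                    linearPenalty = "l1", linearC = 1)
  gs <- gridSearch(d$X, d$y, grid, k = 3, seed = 1, classifier = "RF")
  expect_true(all(gs$table$accuracy == 1))
  expect_identical(gs$best$nt, 10L)
  expect_identical(gs$best$md, 2L)
})

test_that("ROC/AUC matches the pair-counting oracle and edge cases", {
  perfect <- rocCurveAuc(c(0.9, 0.8, 0.2, 0.1),
                         c("female", "female", "male", "male"))
  expect_identical(perfect$auc, 1)
  expect_error(rocCurveAuc(1:3, rep("male", 3)), "both classes")
  withr::with_seed(40, {
    for (i in 1:20) {
      n <- sample(20:80, 1)
      sc <- round(runif(n), 1)           # heavy ties on purpose
      lb <- sample(c("male", "female"), n, replace = TRUE,
                   prob = c(0.4, 0.6))
      if (length(unique(lb)) < 2) next
      expect_equal(rocCurveAuc(sc, lb)$auc, aucPairRef(sc, lb),
                   tolerance = 1e-12)
    }
    # independence between scores and labels gives AUC near 1/2
    sc <- runif(2000); lb <- sample(c("male", "female"), 2000, TRUE)
    expect_lt(abs(rocCurveAuc(sc, lb)$auc - 0.5), 0.03)
  })
})

test_that("AUC agrees with an independent library implementation", {
  withr::with_seed(41, {
    sc <- runif(300); lb <- sample(c("male", "female"), 300, TRUE)
  })
  expect_equal(rocCurveAuc(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(
                 response = lb, predictor = sc, levels = c("male", "female"),
                 direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("nested CV partitions test folds, never leaks, and scores a stub analytically", {
  d <- gaussXy(n = 140, centre = 0.5, seed = 21)
  # constant-score stub always predicts the positive class
  stub <- list(fit = function(X, y, p) NULL,
               score = function(m, X) rep(1, nrow(X)))
  rep <- suppressWarnings(
    nestedCV(d$X, d$y, classifier = stub, outerK = 7, seed = 5))
  # outer test folds are disjoint and cover all samples
  expect_identical(sort(unique(rep$fold)), 1:7)
  expect_identical(length(rep$fold), 140L)
  # inner loop never touches the outer test fold
  for (f in 1:7)
    expect_length(intersect(rep$innerIndexSets[[f]], which(rep$fold == f)), 0)
  # per-fold accuracy of the constant classifier is that fold's female share
  for (f in 1:7) {
    expect_identical(rep$perFold$accuracy[f],
                     mean(d$y[rep$fold == f] == "female"))
  }
  expect_identical(rep$meanAccuracy, mean(rep$perFold$accuracy))
})

test_that("nested CV with an inner grid is deterministic and self-consistent", {
  d <- gaussXy(n = 120, centre = 2, seed = 22)
  grid <- paramGrid(forestNt = 10, forestMd = c(1, 3),
                    linearPenalty = "l1", linearC = 1)
  r1 <- nestedCV(d$X, d$y, classifier = "hybrid", grid = grid,
                 outerK = 4, innerK = 3, seed = 9)
  r2 <- nestedCV(d$X, d$y, classifier = "hybrid", grid = grid,
                 outerK = 4, innerK = 3, seed = 9)
  expect_identical(r1$perFold, r2$perFold)
  expect_true(all(r1$perFold$accuracy >= 0 & r1$perFold$accuracy <= 1))
  expect_true(all(r1$perFold$auc >= 0 & r1$perFold$auc <= 1))
  expect_identical(r1$meanAuc, mean(r1$perFold$auc))
})

test_that("subject-grouped folds keep each subject on one side", {
  d <- gaussXy(n = 120, centre = 2, seed = 23)
  groups <- rep(sprintf("s%02d", 1:12), each = 10)
  # make group labels consistent (each subject one class)
  y <- factor(rep(rep(c("male", "female"), 6), each = 10),
              levels = c("male", "female"))
  rep <- nestedCV(d$X, y, classifier = "LR", outerK = 4, seed = 2,
                  groups = groups)
  for (f in 1:4) {
    inTest <- unique(groups[rep$fold == f])
    inTrain <- unique(groups[rep$fold != f])
    expect_length(intersect(inTest, inTrain), 0)
  }
})

test_that("Welch comparison matches closed-form and library results", {
  fm <- tinyFeatures()
  cg <- compareGroups(fm)
  expect_identical(nrow(cg), 12L)
  expect_true(all(cg$p >= 0 & cg$p <= 1))
  expect_identical(cg$significant, cg$p < 0.01)
  # hand computation on a 6-value toy table: female {1,2,3}, male {2,4,6}
  f <- c(1, 2, 3); m <- c(2, 4, 6)
  se2 <- var(f) / 3 + var(m) / 3
  tHand <- (mean(f) - mean(m)) / sqrt(se2)
  dfHand <- se2^2 / ((var(f) / 3)^2 / 2 + (var(m) / 3)^2 / 2)
  pHand <- 2 * pt(-abs(tHand), dfHand)
  w <- entrosex:::welch(f, m)
  expect_equal(w[["t"]], tHand, tolerance = 1e-12)
  expect_equal(w[["p"]], pHand, tolerance = 1e-12)
  tt <- t.test(f, m)
  expect_equal(w[["t"]], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w[["p"]], tt$p.value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1, not significant
  w0 <- entrosex:::welch(c(1, 1), c(1, 1))
  expect_identical(w0[["t"]], 0)
  expect_identical(w0[["p"]], 1)
})

test_that("robustness sweeps have the documented shapes and determinism", {
  fm <- tinyFeatures()
  sw <- channelSubsetSweep(fm, mRange = c(1, 3), repeats = 2, seed = 1,
                           classifiers = c("LR", "hybrid"),
                           fp = forestParams(nt = 20, md = 3))
  expect_identical(nrow(sw), 4L)      # one row per (m, classifier)
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
  sw2 <- channelSubsetSweep(fm, mRange = c(1, 3), repeats = 2, seed = 1,
                            classifiers = c("LR", "hybrid"),
                            fp = forestParams(nt = 20, md = 3))
  expect_identical(sw, sw2)

  tf <- testFractionSweep(fm, fractions = c(0.2, 0.5), repeats = 2, seed = 1,
                          classifiers = "LR")
  expect_identical(nrow(tf), 2L)
  expect_true(all(tf$accuracy >= 0 & tf$accuracy <= 1))
  expect_warning(
    testFractionSweep(fm, fractions = 0.999, repeats = 1, seed = 1,
                      classifiers = "LR"),
    "infeasible")
})

test_that("the 27 protocol sex-ratio cases are enumerated correctly", {
  cases <- defaultRatioCases()
  expect_length(cases, 27)
  expect_identical(cases[[1]], c(13L, 1L))
  expect_identical(cases[[15]], c(13L, 15L))
  expect_identical(cases[[27]], c(1L, 15L))
  # counts never exceed the protocol cohort
  expect_true(all(vapply(cases, function(x) x[1] <= 13 && x[2] <= 15,
                         logical(1))))
})

test_that("sex-ratio sweep samples subjects without replacement and validates counts", {
  fm <- tinyFeatures()
  sw <- classRatioSweep(fm, ratios = list(c(1L, 1L), c(2L, 2L)), repeats = 2,
                        seed = 1, classifiers = "LR", testFraction = 0.2)
  expect_identical(nrow(sw), 2L)
  expect_true(all(is.finite(sw$accuracy)))
  expect_error(
    classRatioSweep(fm, ratios = list(c(5L, 5L)), repeats = 1,
                    classifiers = "LR"),
    "more subjects")
})

test_that("mean ROC vertical averaging uses the fixed 101-point grid", {
  curves <- list(data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                 data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1)))
  m <- meanRocCurve(curves)
  expect_identical(nrow(m), 101L)
  expect_identical(m$fpr, seq(0, 1, length.out = 101))
  # average of the diagonal and the perfect curve
  expect_equal(m$tpr[51], (0.5 + 1) / 2)
})
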