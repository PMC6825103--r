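#' Hyperparameter search grid
#'
#' Default lists mirror the printed sensitivity sweeps: tree counts
#' \{1, 10, 20, 50, 100, 200, 500, 1000, 2000\}, depths \{1..10, 20\},
#' penalties \{l1, l2\}, C \{0.001, 0.01, 0.1, 1, 10\}.
#'
#' @param forestNt integer tree counts.
#' @param forestMd integer maximum depths.
#' @param linearPenalty subset of \code{c("l1", "l2")}.
#' @param linearC positive inverse regularization strengths.
#' @return A list of class \code{"ParamGrid"}.
#' @export
paramGrid <- function(forestNt = c(1, 10, 20, 50, 100, 200, 500, 1000, 2000),
                      forestMd = c(1:10, 20),
                      linearPenalty = c("l1", "l2"),
                      linearC = c(0.001, 0.01, 0.1, 1, 10)) {
  stopifnot(length(forestNt) > 0, length(forestMd) > 0,
            length(linearPenalty) > 0, length(linearC) > 0,
            all(linearPenalty %in% c("l1", "l2")), all(linearC > 0))
  structure(list(forestNt = as.integer(forestNt),
                 forestMd = as.integer(forestMd),
                 linearPenalty = linearPenalty, linearC = linearC),
            class = "ParamGrid")
}

#' Stratified fold assignment
#'
#' Assigns every sample to one of \code{k} folds so that fold sizes differ by
#' at most one and each class is spread across folds within one sample.
#' Deterministic given \code{seed}.
#'
#' @param labels label vector.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return Integer fold index (1..k) per sample.
#' @export
stratifiedFolds <- function(labels, k = 10, seed = 1) {
  stopifnot(k >= 2)
  k <- as.integer(k)
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("every class must have at least k samples; smallest has ",
         min(counts))
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

# stratified holdout: TRUE = test. Guarantees >= 1 test and >= 1 train
# sample per class; returns NULL when a class cannot give 2 to each side.
stratifiedSplit <- function(labels, testFraction, seed, minPerSide = 2L) {
  labels <- as.factor(labels)
  isTest <- logical(length(labels))
  ok <- TRUE
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      nTest <- round(length(idx) * testFraction)
      if (nTest < minPerSide || length(idx) - nTest < minPerSide) {
        ok <- FALSE
      } else {
        isTest[sample(idx, nTest)] <- TRUE
      }
    }
  })
  if (!ok) return(NULL)
  isTest
}

# ---- classifier adapter -----------------------------------------------------
# A classifier is either one of "LR", "RF", "hybrid", or a
# list(fit = function(X, y, params), score = function(model, X)) stub.

cellParams <- function(cell, fp, lp, seed) {
  if (!is.null(cell$nt)) fp$nt <- as.integer(cell$nt)
  if (!is.null(cell$md)) fp$md <- as.integer(cell$md)
  if (!is.null(cell$penalty)) lp$penalty <- cell$penalty
  if (!is.null(cell$C)) lp$C <- cell$C
  fp$seed <- as.integer(seed)
  list(fp = fp, lp = lp)
}

clfFit <- function(classifier, X, y, fp, lp) {
  if (is.list(classifier) && !is.null(classifier$fit))
    return(classifier$fit(X, y, list(fp = fp, lp = lp)))
  switch(classifier,
    LR = fitLogistic(X, y, lp),
    RF = fitForest(as.matrix(X), y, fp),
    hybrid = fitHybrid(X, y, fp, lp),
    stop("unknown classifier kind: ", classifier))
}

clfScore <- function(classifier, model, X) {
  if (is.list(classifier) && !is.null(classifier$score))
    return(classifier$score(model, X))
  switch(classifier,
    LR = scoreLogistic(model, X),
    RF = {
      nodesX <- as.matrix(X)
      colnames(nodesX) <- model$featureNames
      stats::predict(model$ranger, data = nodesX,
                     num.threads = 1)$predictions[, POSITIVE_CLASS]
    },
    hybrid = predictScores(model, X))
}

gridCells <- function(grid, classifier) {
  if (is.list(classifier)) return(list(list()))
  switch(classifier,
    LR = {
      df <- expand.grid(C = grid$linearC, penalty = grid$linearPenalty,
                        stringsAsFactors = FALSE)
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    },
    RF = {
      df <- expand.grid(md = grid$forestMd, nt = grid$forestNt)
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    },
    hybrid = {
      df <- expand.grid(C = grid$linearC, penalty = grid$linearPenalty,
                        md = grid$forestMd, nt = grid$forestNt,
                        stringsAsFactors = FALSE)
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    })
}

# tie-break: smaller nt, smaller md, l2 before l1, larger C
cellOrderKey <- function(cells) {
  nt <- vapply(cells, function(c) c$nt %||% 0, numeric(1))
  md <- vapply(cells, function(c) c$md %||% 0, numeric(1))
  pen <- vapply(cells, function(c) (c$penalty %||% "l2") == "l1", logical(1))
  C <- vapply(cells, function(c) c$C %||% 0, numeric(1))
  order(nt, md, pen, -C)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exhaustive grid search by k-fold cross-validation
#'
#' Scores every cell of the grid relevant to the classifier kind by
#' stratified k-fold CV accuracy on \code{(X, y)} and returns the best cell.
#' Ties break toward the simpler model: smaller \code{nt}, then smaller
#' \code{md}, l2 before l1, larger \code{C}.
#'
#' @param X feature matrix.
#' @param y labels (male/female).
#' @param grid a [paramGrid()].
#' @param k inner folds (default 10).
#' @param seed RNG seed (folds and forest fits).
#' @param classifier \code{"LR"}, \code{"RF"}, \code{"hybrid"}, or a
#'   \code{list(fit=, score=)} stub.
#' @param fp,lp base parameters for fields the grid does not vary.
#' @return \code{list(best = <param cell>, score = <mean accuracy>,
#'   table = <one row per cell>)}.
#' @export
gridSearch <- function(X, y, grid = paramGrid(), k = 10, seed = 1,
                       classifier = "hybrid",
                       fp = forestParams(), lp = linearParams()) {
  X <- as.matrix(X)
  y <- asLabelFactor(y)
  cells <- gridCells(grid, classifier)
  fold <- stratifiedFolds(y, k, seed)
  acc <- numeric(length(cells))
  for (ci in seq_along(cells)) {
    p <- cellParams(cells[[ci]], fp, lp, seed)
    hits <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      model <- clfFit(classifier, X[tr, , drop = FALSE], y[tr], p$fp, p$lp)
      s <- clfScore(classifier, model, X[!tr, , drop = FALSE])
      pred <- ifelse(s >= 0.5, POSITIVE_CLASS, "male")
      hits <- hits + sum(pred == as.character(y[!tr]))
    }
    acc[ci] <- hits / length(y)
  }
  pref <- cellOrderKey(cells)
  best <- pref[which.max(acc[pref])]
  tab <- do.call(rbind, lapply(seq_along(cells), function(i) {
    cl <- cells[[i]]
    data.frame(nt = cl$nt %||% NA, md = cl$md %||% NA,
               penalty = cl$penalty %||% NA, C = cl$C %||% NA,
               accuracy = acc[i])
  }))
  list(best = cells[[best]], score = acc[best], table = tab)
}

#' ROC curve and AUC
#'
#' Sweeps all distinct score thresholds (tied scores grouped) and integrates
#' by the trapezoidal rule, which makes the AUC identical to the normalized
#' Mann-Whitney U statistic (ties counted 1/2).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels labels; both classes must be present.
#' @param positive the positive class (default \code{"female"}).
#' @return \code{list(points = data.frame(fpr, tpr), auc = <number>)}.
#' @export
rocCurveAuc <- function(scores, labels, positive = POSITIVE_CLASS) {
  yv <- as.character(labels) == positive
  if (!any(yv) || all(yv))
    stop("ROC requires both classes in 'labels'")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yo <- yv[o]
  tp <- cumsum(yo); fp <- cumsum(!yo)
  keep <- which(c(s[-1] != s[-length(s)], TRUE))   # last index of each tie group
  tpr <- c(0, tp[keep] / sum(yv))
  fpr <- c(0, fp[keep] / sum(!yv))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Nested cross-validation
#'
#' Outer stratified k-fold loop estimates generalization; inside each outer
#' training set an inner k-fold [gridSearch()] (when \code{grid} is given)
#' selects hyperparameters, so tuning never sees the held-out fold. With
#' \code{grid = NULL} the supplied \code{fp}/\code{lp} defaults are used
#' directly, with no inner search. With \code{groups} (e.g. subject ids)
#' folds are assigned at the group level, the leakage-safe protocol when
#' epochs of one subject must not straddle train and test.
#'
#' @inheritParams gridSearch
#' @param grid a [paramGrid()] or \code{NULL} for fixed defaults.
#' @param outerK,innerK outer and inner fold counts.
#' @param groups optional per-sample grouping for grouped fold assignment.
#' @param threshold decision threshold for accuracy.
#' @return A \code{"CVReport"}: per-fold accuracy/AUC/ROC/chosen params, the
#'   fold assignment, and their means.
#' @export
nestedCV <- function(X, y, classifier = "hybrid", grid = NULL,
                     outerK = 10, innerK = 10, seed = 1,
                     fp = forestParams(), lp = linearParams(),
                     groups = NULL, threshold = 0.5) {
  X <- as.matrix(X)
  y <- asLabelFactor(y)
  if (is.null(groups)) {
    fold <- stratifiedFolds(y, outerK, seed)
  } else {
    stopifnot(length(groups) == length(y))
    gids <- unique(as.character(groups))
    glab <- vapply(gids, function(g) as.character(y[groups == g][1]),
                   character(1))
    gfold <- stratifiedFolds(glab, outerK, seed)
    fold <- gfold[match(as.character(groups), gids)]
  }
  perFold <- vector("list", outerK)
  rocs <- vector("list", outerK)
  innerIndexSets <- vector("list", outerK)
  for (f in seq_len(outerK)) {
    tr <- which(fold != f); te <- which(fold == f)
    innerIndexSets[[f]] <- tr
    if (!is.null(grid)) {
      gs <- gridSearch(X[tr, , drop = FALSE], y[tr], grid, k = innerK,
                       seed = seed + f, classifier = classifier,
                       fp = fp, lp = lp)
      cell <- gs$best
    } else {
      cell <- list()
    }
    p <- cellParams(cell, fp, lp, seed + f)
    model <- clfFit(classifier, X[tr, , drop = FALSE], y[tr], p$fp, p$lp)
    s <- clfScore(classifier, model, X[te, , drop = FALSE])
    pred <- ifelse(s >= threshold, POSITIVE_CLASS, "male")
    acc <- mean(pred == as.character(y[te]))
    auc <- if (nlevels(droplevels(y[te])) == 2)
      rocCurveAuc(s, y[te])$auc else NA_real_
    rocs[[f]] <- if (is.na(auc)) NULL else rocCurveAuc(s, y[te])$points
    perFold[[f]] <- data.frame(
      fold = f, accuracy = acc, auc = auc,
      nt = cell$nt %||% fp$nt, md = cell$md %||% fp$md,
      penalty = cell$penalty %||% lp$penalty, C = cell$C %||% lp$C)
  }
  perFold <- do.call(rbind, perFold)
  structure(list(
    classifier = if (is.list(classifier)) "custom" else classifier,
    perFold = perFold,
    meanAccuracy = mean(perFold$accuracy),
    meanAuc = mean(perFold$auc, na.rm = TRUE),
    roc = rocs, fold = fold, innerIndexSets = innerIndexSets,
    seed = seed, grouped = !is.null(groups)),
    class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("Nested CV report [%s]%s: mean accuracy %.4f, mean AUC %.4f over %d folds\n",
              x$classifier, if (x$grouped) " (subject-grouped)" else "",
              x$meanAccuracy, x$meanAuc, nrow(x$perFold)))
  invisible(x)
}

#' Average ROC curves on a common false-positive grid
#'
#' Vertical averaging of fold/round ROC curves over a fixed grid of 101
#' false-positive rates.
#'
#' @param rocList list of \code{data.frame(fpr, tpr)} curves.
#' @return \code{data.frame(fpr, tpr)} of the mean curve.
#' @export
meanRocCurve <- function(rocList) {
  rocList <- Filter(Negate(is.null), rocList)
  stopifnot(length(rocList) > 0)
  grid <- seq(0, 1, length.out = 101)
  tprs <- vapply(rocList, function(pts) {
    stats::approx(pts$fpr, pts$tpr, xout = grid, ties = max,
                  yleft = 0, yright = 1)$y
  }, numeric(101))
  data.frame(fpr = grid, tpr = rowMeans(tprs))
}

# ---- group comparison -------------------------------------------------------

welch <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
    return(c(t = t, p = p))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  c(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Per-feature comparison of female vs male epochs
#'
#' Welch's two-sample t test per feature (the two sexes contribute unequal,
#' unpaired epoch sets, so an unpaired unequal-variance test is the
#' appropriate one), with group means and SDs and a significance flag at
#' alpha = 0.01. The t statistic is signed female minus male.
#'
#' @param fm an [EntropyFeatures-class] with both sexes present.
#' @param alpha significance level for the flag (default 0.01).
#' @return A \code{data.frame} (class \code{"GroupComparison"}), one row per
#'   feature.
#' @export
compareGroups <- function(fm, alpha = 0.01) {
  stopifnot(is(fm, "EntropyFeatures"))
  vals <- featureValues(fm)
  sex <- epochLabels(fm)
  if (sum(sex == "female", na.rm = TRUE) < 2 ||
      sum(sex == "male", na.rm = TRUE) < 2)
    stop("each sex needs at least 2 epochs")
  info <- featureInfo(fm)
  rows <- lapply(seq_len(ncol(vals)), function(j) {
    f <- vals[sex == "female", j]; m <- vals[sex == "male", j]
    f <- f[!is.na(f)]; m <- m[!is.na(m)]
    wt <- welch(f, m)
    data.frame(feature = rownames(info)[j], channel = info$channel[j],
               measure = info$measure[j],
               meanMale = mean(m), sdMale = stats::sd(m),
               meanFemale = mean(f), sdFemale = stats::sd(f),
               t = wt[["t"]], p = wt[["p"]],
               significant = wt[["p"]] < alpha)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("GroupComparison", class(out))
  out
}

# ---- robustness sweeps ------------------------------------------------------

fmToXy <- function(fm) {
  fm <- dropUndefinedEpochs(fm)
  list(X = featureValues(fm), y = epochLabels(fm),
       subjects = epochSubjects(fm), info = featureInfo(fm))
}

evalHoldout <- function(X, y, classifier, fp, lp, testFraction, seed) {
  isTest <- stratifiedSplit(y, testFraction, seed)
  if (is.null(isTest)) return(NULL)
  p <- cellParams(list(), fp, lp, seed)
  model <- clfFit(classifier, X[!isTest, , drop = FALSE], y[!isTest],
                  p$fp, p$lp)
  s <- clfScore(classifier, model, X[isTest, , drop = FALSE])
  pred <- ifelse(s >= 0.5, POSITIVE_CLASS, "male")
  yTest <- y[isTest]
  auc <- if (nlevels(droplevels(yTest)) == 2) rocCurveAuc(s, yTest)$auc
         else NA_real_
  c(accuracy = mean(pred == as.character(yTest)), auc = auc)
}

#' Electrode-count robustness sweep
#'
#' For each electrode count m, draws \code{repeats} uniform random channel
#' subsets, evaluates each classifier on the subset's features with a
#' stratified holdout split at the default parameters, and averages.
#'
#' @param fm an [EntropyFeatures-class].
#' @param mRange electrode counts to test (default 1..n_channels).
#' @param repeats random subsets per count (default 10).
#' @param seed RNG seed.
#' @param classifiers classifier kinds to evaluate.
#' @param testFraction holdout test proportion (default 0.2).
#' @param fp,lp model parameters.
#' @return \code{data.frame}: one row per (m, classifier) with mean accuracy
#'   and AUC.
#' @export
channelSubsetSweep <- function(fm, mRange = NULL, repeats = 10, seed = 1,
                               classifiers = c("LR", "RF", "hybrid"),
                               testFraction = 0.2,
                               fp = forestParams(), lp = linearParams()) {
  dat <- fmToXy(fm)
  chans <- unique(dat$info$channel)
  if (is.null(mRange)) mRange <- seq_along(chans)
  if (any(mRange < 1 | mRange > length(chans)))
    stop("mRange must lie in 1..", length(chans))
  out <- list()
  for (m in mRange) {
    res <- array(NA_real_, c(repeats, length(classifiers), 2))
    for (rep in seq_len(repeats)) {
      sub <- withr::with_seed(seed + 1000L * m + rep,
                              sample(chans, m))
      cols <- dat$info$channel %in% sub
      for (ci in seq_along(classifiers)) {
        # split seed fixed per m: the repeat-level randomness is the
        # channel combination, so repeats with the same subset coincide
        r <- evalHoldout(dat$X[, cols, drop = FALSE], dat$y,
                         classifiers[ci], fp, lp, testFraction, seed + m)
        if (!is.null(r)) res[rep, ci, ] <- r
      }
    }
    for (ci in seq_along(classifiers)) {
      out[[length(out) + 1L]] <- data.frame(
        m = m, classifier = classifiers[ci],
        accuracy = mean(res[, ci, 1], na.rm = TRUE),
        auc = mean(res[, ci, 2], na.rm = TRUE))
    }
  }
  do.call(rbind, out)
}

#' Test-fraction robustness sweep
#'
#' For each test proportion, performs \code{repeats} stratified random
#' splits, trains on the remainder and evaluates on the test side.
#' Fractions that cannot leave two samples per class on both sides are
#' skipped with a warning.
#'
#' @inheritParams channelSubsetSweep
#' @param fractions test proportions in (0, 1).
#' @return \code{data.frame}: one row per (fraction, classifier).
#' @export
testFractionSweep <- function(fm, fractions, repeats = 10, seed = 1,
                              classifiers = c("LR", "RF", "hybrid"),
                              fp = forestParams(), lp = linearParams()) {
  stopifnot(all(fractions > 0 & fractions < 1))
  dat <- fmToXy(fm)
  out <- list()
  for (fr in fractions) {
    res <- array(NA_real_, c(repeats, length(classifiers), 2))
    feasible <- TRUE
    for (rep in seq_len(repeats)) {
      for (ci in seq_along(classifiers)) {
        r <- evalHoldout(dat$X, dat$y, classifiers[ci], fp, lp, fr,
                         seed + round(100000 * fr) + rep)
        if (is.null(r)) { feasible <- FALSE; break }
        res[rep, ci, ] <- r
      }
      if (!feasible) break
    }
    if (!feasible) {
      warning(sprintf("test fraction %g infeasible; skipped", fr))
      next
    }
    for (ci in seq_along(classifiers)) {
      out[[length(out) + 1L]] <- data.frame(
        fraction = fr, classifier = classifiers[ci],
        accuracy = mean(res[, ci, 1]),
        auc = mean(res[, ci, 2], na.rm = TRUE))
    }
  }
  do.call(rbind, out)
}

#' The 27 male:female subject-count cases
#'
#' \{13:1 .. 13:15\} then \{12:15 .. 1:15\}.
#'
#' @return List of \code{c(male, female)} subject-count pairs, length 27.
#' @export
defaultRatioCases <- function() {
  c(lapply(1:15, function(f) c(13L, f)),
    lapply(12:1, function(m) c(m, 15L)))
}

#' Sex-ratio robustness sweep
#'
#' For each (n_male, n_female) subject-count pair, samples that many subjects
#' of each sex without replacement, keeps all their epochs, and evaluates
#' each classifier with a stratified holdout split; averaged over
#' \code{repeats} draws.
#'
#' @inheritParams channelSubsetSweep
#' @param ratios list of \code{c(male, female)} subject counts (default the
#'   27 protocol cases).
#' @param testFraction holdout test proportion (default 0.1).
#' @return \code{data.frame}: one row per (ratio, classifier).
#' @export
classRatioSweep <- function(fm, ratios = defaultRatioCases(), repeats = 10,
                            seed = 1, classifiers = c("LR", "RF", "hybrid"),
                            testFraction = 0.1,
                            fp = forestParams(), lp = linearParams()) {
  dat <- fmToXy(fm)
  subjSex <- vapply(split(as.character(dat$y), dat$subjects),
                    function(s) s[1], character(1))
  males <- names(subjSex)[subjSex == "male"]
  females <- names(subjSex)[subjSex == "female"]
  out <- list()
  for (ri in seq_along(ratios)) {
    nm <- ratios[[ri]][1]; nf <- ratios[[ri]][2]
    if (nm > length(males) || nf > length(females))
      stop(sprintf("ratio %d:%d needs more subjects than available (%d M, %d F)",
                   nm, nf, length(males), length(females)))
    res <- array(NA_real_, c(repeats, length(classifiers), 2))
    for (rep in seq_len(repeats)) {
      pick <- withr::with_seed(seed + 1000L * ri + rep,
                               c(sample(males, nm), sample(females, nf)))
      keep <- dat$subjects %in% pick
      for (ci in seq_along(classifiers)) {
        r <- evalHoldout(dat$X[keep, , drop = FALSE], dat$y[keep],
                         classifiers[ci], fp, lp, testFraction,
                         seed + 1000L * ri + rep)
        if (!is.null(r)) res[rep, ci, ] <- r
      }
    }
    for (ci in seq_along(classifiers)) {
      out[[length(out) + 1L]] <- data.frame(
        nMale = nm, nFemale = nf, classifier = classifiers[ci],
        accuracy = mean(res[, ci, 1], na.rm = TRUE),
        auc = mean(res[, ci, 2], na.rm = TRUE))
    }
  }
  do.call(rbind, out)
}
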