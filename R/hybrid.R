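#' Random-forest parameters
#'
#' Defaults are the protocol settings: 200 trees of maximum depth 5, Gini
#' splits, unweighted classes.
#'
#' @param nt number of trees (>= 1).
#' @param md maximum tree depth (>= 1).
#' @param splitCriterion split quality criterion (\code{"gini"}).
#' @param minSamplesSplit minimal node size eligible for splitting.
#' @param minSamplesLeaf minimal terminal node size.
#' @param seed RNG seed for bootstrap resampling and feature subsetting.
#' @return A list of class \code{"ForestParams"}.
#' @export
forestParams <- function(nt = 200, md = 5, splitCriterion = "gini",
                         minSamplesSplit = 2, minSamplesLeaf = 1, seed = 1) {
  stopifnot(nt >= 1, md >= 1, minSamplesSplit >= 1, minSamplesLeaf >= 1)
  structure(list(nt = as.integer(nt), md = as.integer(md),
                 splitCriterion = match.arg(splitCriterion, "gini"),
                 minSamplesSplit = as.integer(minSamplesSplit),
                 minSamplesLeaf = as.integer(minSamplesLeaf),
                 seed = as.integer(seed)),
            class = "ForestParams")
}

#' Logistic-regression parameters
#'
#' Defaults are the protocol settings: l1 penalty with inverse regularization
#' strength \code{C = 1}. \code{C} maps onto the glmnet scale as
#' \code{lambda = 1 / (n * C)}.
#'
#' @param penalty \code{"l1"} or \code{"l2"}.
#' @param C inverse regularization strength (> 0).
#' @param tol coordinate-descent convergence threshold.
#' @param maxit iteration cap (a warning is logged if hit).
#' @param seed stored for provenance (the solver is deterministic).
#' @return A list of class \code{"LinearParams"}.
#' @export
linearParams <- function(penalty = c("l1", "l2"), C = 1.0, tol = 1e-4,
                         maxit = 1000, seed = 1) {
  penalty <- match.arg(penalty)
  stopifnot(C > 0, tol > 0, maxit >= 1)
  structure(list(penalty = penalty, C = C, tol = tol,
                 maxit = as.integer(maxit), seed = as.integer(seed)),
            class = "LinearParams")
}

asLabelFactor <- function(y) {
  y <- factor(as.character(y), levels = SEX_LEVELS)
  if (anyNA(y)) stop("labels must be 'male' or 'female'")
  if (nlevels(droplevels(y)) < 2)
    stop("both classes must be present in y")
  y
}

# depth-first leaf enumeration, left child first, from a ranger treeInfo table
dfsLeafOrder <- function(ti) {
  left <- ti$leftChild; right <- ti$rightChild; term <- ti$terminal
  leaves <- integer(0)
  stack <- 0L
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    row <- nd + 1L
    if (term[row]) {
      leaves <- c(leaves, nd)
    } else {
      stack <- c(stack, right[row], left[row])  # left popped first
    }
  }
  leaves
}

#' Fit a random forest on a feature matrix
#'
#' Trains a \code{ranger} probability forest on bootstrap resamples with
#' random feature subsetting, and enumerates every leaf of every tree
#' (depth-first, left child first) into a stable column map used by
#' [leafEncode()].
#'
#' @param X numeric feature matrix (epochs x features).
#' @param y labels (coerced to factor male/female); both classes required.
#' @param params a [forestParams()].
#' @return A list of class \code{"entForest"}: the fitted ensemble, the
#'   per-tree leaf map, the total leaf-column count and the training feature
#'   names.
#' @export
fitForest <- function(X, y, params = forestParams()) {
  stopifnot(inherits(params, "ForestParams"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- asLabelFactor(y)
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  rf <- ranger::ranger(
    x = X, y = y,
    num.trees = params$nt,
    max.depth = params$md,
    splitrule = "gini",
    min.node.size = params$minSamplesSplit,
    min.bucket = params$minSamplesLeaf,
    probability = TRUE,
    seed = params$seed,
    num.threads = 1)
  leafMap <- vector("list", params$nt)
  for (t in seq_len(params$nt)) {
    leaves <- dfsLeafOrder(ranger::treeInfo(rf, t))
    leafMap[[t]] <- stats::setNames(seq_along(leaves), leaves)
  }
  structure(list(ranger = rf, leafMap = leafMap,
                 nEncoded = sum(lengths(leafMap)),
                 featureNames = colnames(X), params = params),
            class = "entForest")
}

forestLeafNodes <- function(forest, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(forest$featureNames))
    stop(sprintf("feature-count mismatch: forest was trained on %d features, got %d",
                 length(forest$featureNames), ncol(X)))
  colnames(X) <- forest$featureNames
  stats::predict(forest$ranger, data = X, type = "terminalNodes",
                 num.threads = 1)$predictions
}

#' One-hot leaf encoding of samples under a fitted forest
#'
#' Row i carries a single 1 per tree, in the column of the leaf sample i
#' reaches; columns are laid out tree-major with the stable depth-first leaf
#' order fixed at fit time. Every row therefore sums to the number of trees.
#'
#' @param forest an \code{"entForest"} from [fitForest()] (or a
#'   [HybridModel-class], whose forest is used).
#' @param X feature matrix with the training feature count.
#' @return A sparse binary \code{dgCMatrix}, n_samples x n_encoded.
#' @export
leafEncode <- function(forest, X) {
  if (is(forest, "HybridModel")) forest <- forest@forest
  stopifnot(inherits(forest, "entForest"))
  nodes <- forestLeafNodes(forest, X)
  n <- nrow(nodes)
  nt <- ncol(nodes)
  offsets <- c(0L, cumsum(lengths(forest$leafMap)))
  js <- integer(n * nt)
  for (t in seq_len(nt)) {
    js[((t - 1L) * n + 1L):(t * n)] <-
      offsets[t] + forest$leafMap[[t]][as.character(nodes[, t])]
  }
  Matrix::sparseMatrix(i = rep.int(seq_len(n), nt), j = js, x = 1,
                       dims = c(n, forest$nEncoded))
}

# glmnet with a fixed target lambda; a short decreasing path is supplied for
# warm starts, coefficients are read off exactly at the target.
glmnetAt <- function(X, y, lp, nEff = nrow(X)) {
  lam <- 1 / (nEff * lp$C)
  fit <- glmnet::glmnet(
    X, y, family = "binomial",
    alpha = if (lp$penalty == "l1") 1 else 0,
    lambda = lam * c(64, 16, 4, 1),
    standardize = FALSE,
    thresh = lp$tol * 1e-3,
    maxit = lp$maxit * 100)
  list(fit = fit, lambda = lam)
}

fitLogistic <- function(X, y, lp = linearParams()) {
  y <- asLabelFactor(y)
  X <- methods::as(as.matrix(X), "CsparseMatrix")
  g <- glmnetAt(X, y, lp)
  structure(list(fit = g$fit, lambda = g$lambda, nFeatures = ncol(X)),
            class = "entLogistic")
}

scoreLogistic <- function(model, X) {
  X <- methods::as(as.matrix(X), "CsparseMatrix")
  if (ncol(X) != model$nFeatures)
    stop("feature-count mismatch in logistic predictor")
  as.numeric(stats::predict(model$fit, X, s = model$lambda,
                            type = "response"))
}

#' Fit the hybrid forest + logistic model
#'
#' Fits a random forest on \code{(X, y)}, encodes every sample as the one-hot
#' vector of its leaf indices, and fits a penalized logistic regression on
#' the column concatenation \code{[leaf indicators | original features]}.
#' Scores are the logistic probability of the positive class
#' (\code{"female"}). Deterministic given the seeds in \code{fp}.
#'
#' @param X numeric feature matrix (epochs x features).
#' @param y labels (male/female), both classes present.
#' @param fp a [forestParams()].
#' @param lp a [linearParams()].
#' @return A fitted [HybridModel-class].
#' @export
fitHybrid <- function(X, y, fp = forestParams(), lp = linearParams()) {
  X <- as.matrix(X)
  y <- asLabelFactor(y)
  forest <- fitForest(X, y, fp)
  enc <- leafEncode(forest, X)
  design <- cbind(enc, methods::as(X, "CsparseMatrix"))
  g <- glmnetAt(design, y, lp)
  new("HybridModel", forest = forest, leafIndexMap = forest$leafMap,
      linear = g$fit, lambda = g$lambda,
      nOriginal = ncol(X), nEncoded = forest$nEncoded,
      featureNames = forest$featureNames,
      forestParams = unclass(fp), linearParams = unclass(lp))
}

#' Score samples with a fitted hybrid model
#'
#' @param model a [HybridModel-class].
#' @param X feature matrix with the training feature count.
#' @return Probability of the positive class (\code{"female"}) per sample,
#'   in [0, 1].
#' @export
predictScores <- function(model, X) {
  stopifnot(is(model, "HybridModel"))
  X <- as.matrix(X)
  if (ncol(X) != model@nOriginal)
    stop(sprintf("feature-count mismatch: model expects %d features, got %d",
                 model@nOriginal, ncol(X)))
  design <- cbind(leafEncode(model@forest, X),
                  methods::as(X, "CsparseMatrix"))
  as.numeric(stats::predict(model@linear, design, s = model@lambda,
                            type = "response"))
}

#' Threshold scores into hard labels
#'
#' @inheritParams predictScores
#' @param threshold decision threshold in (0, 1); a score exactly at the
#'   threshold is positive (boundary inclusive).
#' @return Factor of predicted labels (male/female).
#' @export
predictLabels <- function(model, X, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie strictly inside (0, 1)")
  s <- predictScores(model, X)
  factor(ifelse(s >= threshold, POSITIVE_CLASS, "male"), levels = SEX_LEVELS)
}

#' Persist / restore a fitted hybrid model
#'
#' Writes the forest structure, leaf map, linear coefficients, parameters
#' and a version stamp into a single archive file.
#'
#' @param model a [HybridModel-class].
#' @param path archive path.
#' @return \code{path} (save) or the restored model (load).
#' @export
saveHybridModel <- function(model, path) {
  stopifnot(is(model, "HybridModel"))
  saveRDS(list(format = "entrosex-hybrid-1",
               version = as.character(utils::packageVersion("entrosex")),
               model = model),
          path)
  invisible(path)
}

#' @rdname saveHybridModel
#' @export
loadHybridModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "entrosex-hybrid-1"))
    stop("not an entrosex hybrid model archive: ", path)
  validObject(obj$model)
  obj$model
}
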