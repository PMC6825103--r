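#' Entropy estimator configuration
#'
#' Bundles all parameters of the four entropy estimators. Defaults are the
#' standard choices for short physiological windows: embedding dimension
#' \code{m = 2} and tolerance \code{r = 0.25 * SD} for the template-matching
#' estimators, fuzzy membership exponent 2, ordinal order 4 with delay 1
#' (normalized) for permutation entropy.
#'
#' @param m embedding dimension (positive integer).
#' @param rCoeff tolerance coefficient multiplying the per-series population
#'   standard deviation.
#' @param fuzzyN fuzzy membership exponent (positive).
#' @param peOrder ordinal pattern order (integer >= 2).
#' @param peDelay ordinal delay (positive integer).
#' @param peNormalized divide permutation entropy by \code{log(peOrder!)}?
#' @return A validated list of class \code{"EntropyConfig"}.
#' @export
entropyConfig <- function(m = 2, rCoeff = 0.25, fuzzyN = 2,
                          peOrder = 4, peDelay = 1, peNormalized = TRUE) {
  stopifnot(m >= 1, m == round(m), rCoeff > 0, fuzzyN > 0,
            peOrder >= 2, peOrder == round(peOrder),
            peDelay >= 1, peDelay == round(peDelay),
            is.logical(peNormalized))
  structure(list(m = as.integer(m), rCoeff = rCoeff, fuzzyN = fuzzyN,
                 peOrder = as.integer(peOrder), peDelay = as.integer(peDelay),
                 peNormalized = peNormalized),
            class = "EntropyConfig")
}

#' Template-matching tolerance from the series spread
#'
#' \code{r = rCoeff * SD(x)} with the population standard deviation
#' (denominator n). A constant series gives \code{r = 0} with a warning;
#' downstream estimators handle the degenerate case.
#'
#' @param x numeric series (length >= 2).
#' @param rCoeff tolerance coefficient (default 0.25).
#' @return Non-negative tolerance.
#' @export
computeTolerance <- function(x, rCoeff = 0.25) {
  stopifnot(length(x) >= 2, rCoeff > 0)
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) warning("constant series: tolerance r = 0")
  rCoeff * s
}

checkSeries <- function(x, minLen, what) {
  if (!is.numeric(x) || length(x) < minLen)
    stop(what, " requires a numeric series of length >= ", minLen)
  if (!all(is.finite(x))) stop(what, " requires finite values")
}

#' Approximate entropy (ApEn)
#'
#' \code{Phi^m(r) - Phi^(m+1)(r)} with Chebyshev template distance and
#' self-matches included, natural logarithm. Always finite: the self-match
#' guarantees non-zero match fractions.
#'
#' @param x numeric series (length >= m + 2).
#' @param m embedding dimension.
#' @param r tolerance (>= 0), typically from [computeTolerance()].
#' @return Entropy in nats.
#' @export
approxEntropy <- function(x, m = 2, r) {
  checkSeries(x, m + 2, "approximate entropy")
  stopifnot(r >= 0)
  .apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Sample entropy (SampEn)
#'
#' \code{-log(A/B)} where B counts template pairs (i != j) of length m within
#' r and A the same at length m + 1 (Chebyshev distance, self-matches
#' excluded, both lengths over the same N - m templates). When no pairs match
#' at either length the statistic is undefined and \code{NA} is returned.
#'
#' @inheritParams approxEntropy
#' @return Entropy in nats, or \code{NA} when undefined.
#' @export
sampleEntropy <- function(x, m = 2, r) {
  checkSeries(x, m + 2, "sample entropy")
  stopifnot(r >= 0)
  ab <- .sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  if (ab[1] == 0 || ab[2] == 0) return(NA_real_)
  -log(ab[1] / ab[2])
}

#' Fuzzy entropy (FuzzyEn)
#'
#' Like sample entropy but each template is centred on its own mean and the
#' hard threshold is replaced by the graded membership
#' \code{exp(-(d/r)^n)} (Chebyshev d). The dimensionless \code{d/r} makes
#' the statistic exactly affine invariant when \code{r} tracks the series
#' SD. Always finite for \code{r > 0}.
#'
#' @inheritParams approxEntropy
#' @param n membership exponent (default 2).
#' @return Entropy in nats.
#' @export
fuzzyEntropy <- function(x, m = 2, r, n = 2) {
  checkSeries(x, m + 2, "fuzzy entropy")
  if (r <= 0) stop("fuzzy entropy requires r > 0 (membership undefined at 0)")
  .fuzzyen_cpp(as.numeric(x), as.integer(m), r, n)
}

#' Permutation entropy (PE)
#'
#' Shannon entropy (nats) of the empirical distribution of ordinal patterns.
#' Ties rank by order of appearance (the earlier index ranks lower). With
#' \code{normalized = TRUE} the value is divided by \code{log(order!)} and
#' lies in [0, 1].
#'
#' @param x numeric series.
#' @param order ordinal pattern order (default 4).
#' @param delay ordinal delay (default 1).
#' @param normalized normalize to [0, 1]?
#' @return Entropy value.
#' @export
permutationEntropy <- function(x, order = 4, delay = 1, normalized = TRUE) {
  checkSeries(x, (order - 1) * delay + 2, "permutation entropy")
  counts <- .perm_counts_cpp(as.numeric(x), as.integer(order),
                             as.integer(delay))
  p <- counts[counts > 0] / sum(counts)
  h <- -sum(p * log(p))
  if (normalized) h <- h / log(factorial(order))
  h
}

# ---- Feature matrix ---------------------------------------------------------

#' Epochs-by-features entropy matrix
#'
#' Extends \code{SummarizedExperiment}: the \code{"entropy"} assay is
#' features x epochs, \code{rowData} records the (channel, measure) pair of
#' each feature, \code{colData} the per-epoch subject and sex. The
#' \code{"defined"} assay flags cells where the estimate exists (sample
#' entropy can be undefined). \code{metadata(x)$normalized} records the
#' normalization state.
#'
#' @seealso [extractFeatures()], [minmaxNormalize()], [featureValues()]
#' @exportClass EntropyFeatures
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata 'metadata<-'
setClass("EntropyFeatures", contains = "SummarizedExperiment")

setValidity("EntropyFeatures", function(object) {
  msg <- character()
  if (!all(c("entropy", "defined") %in% assayNames(object)))
    msg <- c(msg, "needs 'entropy' and 'defined' assays")
  if (!all(c("channel", "measure") %in% colnames(rowData(object))))
    msg <- c(msg, "rowData needs 'channel' and 'measure'")
  if (!all(c("subject_id", "sex") %in% colnames(colData(object))))
    msg <- c(msg, "colData needs 'subject_id' and 'sex'")
  if (is.null(metadata(object)$normalized))
    msg <- c(msg, "metadata needs a 'normalized' flag")
  if (isTRUE(metadata(object)$normalized)) {
    v <- assay(object, "entropy")[assay(object, "defined")]
    if (length(v) && (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9))
      msg <- c(msg, "normalized values must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

newEntropyFeatures <- function(values, defined, channel, measure,
                               subjectIds, labels, normalized = FALSE,
                               normStats = NULL) {
  # values: epochs x features
  featNames <- paste(channel, measure, sep = "_")
  se <- SummarizedExperiment(
    assays = list(entropy = t(values), defined = t(defined)),
    rowData = DataFrame(channel = channel, measure = measure,
                        row.names = featNames),
    colData = DataFrame(subject_id = subjectIds,
                        sex = factor(as.character(labels),
                                     levels = SEX_LEVELS)))
  metadata(se)$normalized <- normalized
  metadata(se)$normStats <- normStats
  as(se, "EntropyFeatures")
}

#' @describeIn accessors epochs x features numeric matrix (undefined cells
#'   are \code{NA}).
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
setMethod("featureValues", "EntropyFeatures", function(object) {
  t(assay(object, "entropy"))
})

#' @describeIn accessors data.frame of per-feature channel and measure.
#' @export
setGeneric("featureInfo", function(object) standardGeneric("featureInfo"))
setMethod("featureInfo", "EntropyFeatures", function(object) {
  as.data.frame(rowData(object))
})

#' @describeIn accessors epochs x features logical matrix, \code{TRUE} where
#'   the estimate is undefined.
#' @export
setGeneric("nanMask", function(object) standardGeneric("nanMask"))
setMethod("nanMask", "EntropyFeatures", function(object) {
  !t(assay(object, "defined"))
})

#' @describeIn accessors has the matrix been min-max normalized?
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
setMethod("isNormalized", "EntropyFeatures", function(object) {
  isTRUE(metadata(object)$normalized)
})

#' @describeIn accessors stored min/max normalization statistics (or NULL).
#' @export
setGeneric("normStats", function(object) standardGeneric("normStats"))
setMethod("normStats", "EntropyFeatures", function(object) {
  metadata(object)$normStats
})

setMethod("epochLabels", "EntropyFeatures", function(object) {
  colData(object)$sex
})
setMethod("epochSubjects", "EntropyFeatures", function(object) {
  colData(object)$subject_id
})
setMethod("nEpochs", "EntropyFeatures", function(object) ncol(object))

setMethod("show", "EntropyFeatures", function(object) {
  cat(sprintf(
    "EntropyFeatures: %d epochs x %d features (%s), %s, %d undefined cells\n",
    ncol(object), nrow(object),
    paste(unique(rowData(object)$measure), collapse = "+"),
    if (isNormalized(object)) "normalized [-1,1]" else "unnormalized",
    sum(!assay(object, "defined"))))
})

#' Compute entropy features for every epoch and channel
#'
#' For each (epoch, channel) series the tolerance is computed as
#' \code{rCoeff * SD} of that series (population SD, after filtering, before
#' normalization), then each requested measure is estimated. Columns are laid
#' out channel-major: all measures of channel 1, then channel 2, ...
#' Undefined sample-entropy cells are flagged, not imputed.
#'
#' @param epochs an [EpochSet-class].
#' @param cfg an [entropyConfig()].
#' @param measures subset of \code{c("FE", "SE", "AE", "PE")}; the default
#'   order matches the combined feature set.
#' @return An unnormalized [EntropyFeatures-class].
#' @export
extractFeatures <- function(epochs, cfg = entropyConfig(),
                            measures = c("FE", "SE", "AE", "PE")) {
  stopifnot(is(epochs, "EpochSet"), inherits(cfg, "EntropyConfig"))
  if (length(measures) == 0) stop("at least one entropy measure is required")
  measures <- match.arg(measures, c("FE", "SE", "AE", "PE"),
                        several.ok = TRUE)
  d <- dim(epochs@epochs)
  if (d[1] == 0) stop("empty EpochSet")
  nper <- d[3]
  if ("PE" %in% measures &&
      factorial(cfg$peOrder) > nper - (cfg$peOrder - 1) * cfg$peDelay)
    warning("epoch length is small for the chosen ordinal order: ",
            "pattern census will be sparse")

  chans <- channelNames(epochs)
  nf <- d[2] * length(measures)
  vals <- matrix(NA_real_, d[1], nf)
  def <- matrix(TRUE, d[1], nf)
  channel <- rep(chans, each = length(measures))
  measure <- rep(measures, times = d[2])

  for (c in seq_len(d[2])) {
    base <- (c - 1L) * length(measures)
    for (e in seq_len(d[1])) {
      x <- epochs@epochs[e, c, ]
      r <- suppressWarnings(computeTolerance(x, cfg$rCoeff))
      for (j in seq_along(measures)) {
        v <- switch(measures[j],
          AE = approxEntropy(x, cfg$m, r),
          SE = sampleEntropy(x, cfg$m, r),
          FE = if (r > 0) fuzzyEntropy(x, cfg$m, r, cfg$fuzzyN) else 0,
          PE = permutationEntropy(x, cfg$peOrder, cfg$peDelay,
                                  cfg$peNormalized))
        if (is.na(v)) def[e, base + j] <- FALSE
        vals[e, base + j] <- v
      }
    }
  }
  nUndef <- sum(!def)
  if (nUndef > 0)
    message(sprintf("extractFeatures: %d undefined estimate(s) flagged",
                    nUndef))
  newEntropyFeatures(vals, def, channel, measure,
                     epochSubjects(epochs), epochLabels(epochs))
}

#' Min-max normalize features to [-1, 1]
#'
#' Per feature, \code{x' = 2 (x - min) / (max - min) - 1}. With
#' \code{grouping = "per_subject"} (the protocol default) the min/max are
#' computed within each subject's epochs; \code{"global"} uses all epochs and
#' is the leakage-safe mode when fitted on training folds only. A constant
#' feature maps to 0. When \code{fitStats} (from a previous call, see
#' [normStats()]) is supplied, those min/max are applied and results are
#' clipped to [-1, 1].
#'
#' @param fm an unnormalized [EntropyFeatures-class].
#' @param grouping \code{"per_subject"} or \code{"global"}.
#' @param fitStats stats from a previous normalization to reuse at test time.
#' @return The normalized [EntropyFeatures-class]; retrieve the fitted stats
#'   with [normStats()].
#' @export
minmaxNormalize <- function(fm, grouping = c("per_subject", "global"),
                            fitStats = NULL) {
  stopifnot(is(fm, "EntropyFeatures"))
  grouping <- match.arg(grouping)
  if (isNormalized(fm))
    stop("feature matrix is already normalized")
  vals <- featureValues(fm)           # epochs x features
  groups <- if (grouping == "per_subject") as.character(epochSubjects(fm))
            else rep("__global__", nrow(vals))
  if (!is.null(fitStats)) {
    if (!identical(fitStats$grouping, grouping))
      stop("fitStats were computed under grouping '", fitStats$grouping, "'")
    missing <- setdiff(unique(groups), names(fitStats$stats))
    if (length(missing))
      stop("fitStats lack groups: ", paste(missing, collapse = ", "))
  }
  stats <- if (is.null(fitStats)) list() else fitStats$stats
  out <- vals
  for (g in unique(groups)) {
    idx <- which(groups == g)
    block <- vals[idx, , drop = FALSE]
    if (is.null(fitStats)) {
      lo <- apply(block, 2, function(col) suppressWarnings(min(col, na.rm = TRUE)))
      hi <- apply(block, 2, function(col) suppressWarnings(max(col, na.rm = TRUE)))
      lo[!is.finite(lo)] <- 0; hi[!is.finite(hi)] <- 0
      stats[[g]] <- list(min = lo, max = hi)
    } else {
      lo <- fitStats$stats[[g]]$min; hi <- fitStats$stats[[g]]$max
    }
    rng <- hi - lo
    scaled <- sweep(block, 2, lo, "-")
    scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/") * 2 - 1
    for (j in which(rng <= 0))          # constant feature -> 0, keep NA cells
      scaled[, j] <- ifelse(is.na(block[, j]), NA_real_, 0)
    if (!is.null(fitStats)) scaled <- pmin(pmax(scaled, -1), 1)
    out[idx, ] <- scaled
  }
  assay(fm, "entropy") <- t(out)
  metadata(fm)$normalized <- TRUE
  metadata(fm)$normStats <- list(grouping = grouping, stats = stats)
  validObject(fm)
  fm
}

#' Drop epochs containing undefined estimates
#'
#' @param fm an [EntropyFeatures-class].
#' @return \code{fm} restricted to fully-defined epochs; logs the count.
#' @export
dropUndefinedEpochs <- function(fm) {
  stopifnot(is(fm, "EntropyFeatures"))
  bad <- colSums(!assay(fm, "defined")) > 0
  if (any(bad))
    message(sprintf("dropping %d epoch(s) with undefined estimates", sum(bad)))
  fm[, !bad]
}

#' Write / read a feature table
#'
#' Serializes the matrix as a delimited table (columns \code{subject_id},
#' \code{label}, then one column per feature) with a JSON sidecar
#' \code{<path>.json} holding the channel/measure map and normalization
#' state.
#'
#' @param fm an [EntropyFeatures-class].
#' @param path output path.
#' @return \code{path} (write) or the reconstructed object (read).
#' @export
writeFeatureTable <- function(fm, path) {
  stopifnot(is(fm, "EntropyFeatures"))
  df <- data.frame(subject_id = epochSubjects(fm),
                   label = as.character(epochLabels(fm)),
                   featureValues(fm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(channel = featureInfo(fm)$channel,
         measure = featureInfo(fm)$measure,
         normalized = isNormalized(fm)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  newEntropyFeatures(vals, !is.na(vals), meta$channel, meta$measure,
                     df$subject_id, df$label, normalized = meta$normalized)
}
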