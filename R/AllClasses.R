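#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib entrosex, .registration = TRUE
NULL

SEX_LEVELS <- c("male", "female")
# the positive class for scores/AUC throughout the package
POSITIVE_CLASS <- "female"

#' Multichannel EEG recording for one subject
#'
#' Container for a single subject's continuous multichannel signal together
#' with the metadata the downstream pipeline needs: subject identifier, sex
#' label, sampling rate and ordered channel names (10-20 system labels).
#' Rows of \code{signal} are channels, columns are samples.
#'
#' @slot subjectId single subject identifier.
#' @slot sex \code{"male"} or \code{"female"}.
#' @slot fs sampling rate in Hz (positive scalar).
#' @slot channelNames unique channel labels, one per signal row.
#' @slot signal numeric matrix, channels x samples, all finite.
#'
#' @seealso [EEGRecording()] for the user-facing constructor.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    subjectId = "character",
    sex = "character",
    fs = "numeric",
    channelNames = "character",
    signal = "matrix"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a single non-empty string")
  if (length(object@sex) != 1L || !object@sex %in% SEX_LEVELS)
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a positive finite scalar")
  if (nrow(object@signal) != length(object@channelNames))
    msg <- c(msg, sprintf(
      "signal has %d rows but %d channel names",
      nrow(object@signal), length(object@channelNames)))
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (!all(is.finite(object@signal)))
    msg <- c(msg, "all samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channelNames channel labels; default \code{rownames(signal)} or
#'   \code{"ch1"..}.
#' @param subjectId subject identifier.
#' @param sex \code{"male"} or \code{"female"}.
#' @return A validated [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(200), 2), fs = 100,
#'                     channelNames = c("Fp1", "Fp2"),
#'                     subjectId = "s01", sex = "female")
#' samplingRate(rec)
#' @export
EEGRecording <- function(signal, fs, channelNames = NULL,
                         subjectId = "s01", sex = c("male", "female")) {
  sex <- match.arg(sex)
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (is.null(channelNames)) {
    channelNames <- rownames(signal)
    if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nrow(signal)))
  }
  if (length(channelNames) != nrow(signal))
    stop(sprintf("signal has %d rows but %d channel names were given",
                 nrow(signal), length(channelNames)))
  rownames(signal) <- channelNames
  new("EEGRecording", subjectId = as.character(subjectId), sex = sex,
      fs = as.numeric(fs), channelNames = as.character(channelNames),
      signal = signal)
}

#' Set of fixed-length epochs cut from recordings
#'
#' Non-overlapping windows of equal length, each tagged with the subject and
#' sex label it came from. \code{epochs} is an array
#' n_epochs x n_channels x n_samples_per_epoch.
#'
#' @slot epochs numeric array, epochs x channels x samples.
#' @slot subjectIds per-epoch subject identifier.
#' @slot labels per-epoch factor with levels \code{male}, \code{female}.
#' @slot epochLenS epoch length in seconds.
#' @slot fs sampling rate in Hz.
#' @slot channelNames channel labels.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    epochs = "array",
    subjectIds = "character",
    labels = "factor",
    epochLenS = "numeric",
    fs = "numeric",
    channelNames = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L)
    return("epochs must be a 3-d array (epochs x channels x samples)")
  if (d[3] != round(object@epochLenS * object@fs))
    msg <- c(msg, "samples per epoch must equal round(epochLenS * fs)")
  if (length(object@subjectIds) != d[1])
    msg <- c(msg, "subjectIds must have one entry per epoch")
  if (length(object@labels) != d[1])
    msg <- c(msg, "labels must have one entry per epoch")
  if (!identical(levels(object@labels), SEX_LEVELS))
    msg <- c(msg, "labels must be a factor with levels male, female")
  if (d[2] != length(object@channelNames))
    msg <- c(msg, "channelNames must have one entry per channel")
  if (length(msg)) msg else TRUE
})

#' Fitted hybrid forest + logistic model
#'
#' Holds a fitted random forest, the per-tree leaf-to-column map used for the
#' one-hot leaf encoding, and the logistic model fitted on
#' \code{[leaf indicators | original features]}.
#'
#' @slot forest fitted \code{ranger} ensemble.
#' @slot leafIndexMap list, one integer vector per tree mapping ranger leaf
#'   nodeIDs to column offsets (depth-first, left child first).
#' @slot linear fitted \code{glmnet} object.
#' @slot lambda the glmnet lambda at which coefficients are taken
#'   (\code{1/(n * C)}).
#' @slot nOriginal number of original feature columns.
#' @slot nEncoded total number of leaf columns over all trees.
#' @slot featureNames training feature names (order enforced at predict time).
#' @slot forestParams,linearParams the parameter bundles used for fitting.
#' @exportClass HybridModel
setClass("HybridModel",
  representation(
    forest = "ANY",
    leafIndexMap = "list",
    linear = "ANY",
    lambda = "numeric",
    nOriginal = "integer",
    nEncoded = "integer",
    featureNames = "character",
    forestParams = "list",
    linearParams = "list"
  )
)

setValidity("HybridModel", function(object) {
  msg <- character()
  nleaf <- sum(vapply(object@leafIndexMap, length, integer(1)))
  if (nleaf != object@nEncoded)
    msg <- c(msg, "nEncoded must equal the total leaf count of the forest")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
    object@subjectId, object@sex, nrow(object@signal), ncol(object@signal),
    object@fs, ncol(object@signal) / object@fs))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf(
    "EpochSet: %d epochs x %d channels x %d samples (%g s @ %g Hz), %d subjects\n",
    d[1], d[2], d[3], object@epochLenS, object@fs,
    length(unique(object@subjectIds))))
  print(table(object@labels))
})

setMethod("show", "HybridModel", function(object) {
  cat(sprintf(
    "HybridModel: %d trees (max depth %s), %d leaf columns + %d original features\n",
    object@forestParams$nt, object@forestParams$md,
    object@nEncoded, object@nOriginal))
  cat(sprintf("  logistic penalty %s, C = %g\n",
              object@linearParams$penalty, object@linearParams$C))
})
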