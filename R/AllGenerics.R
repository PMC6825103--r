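#' @name accessors
#' @title Accessors for entrosex data classes
#' @description Slot accessors for [EEGRecording-class], [EpochSet-class] and
#'   [EntropyFeatures-class] objects. Use these instead of \code{@}.
#' @param object an entrosex data object.
#' @return The corresponding component (see each generic's description).
NULL

#' @describeIn accessors subject identifier(s).
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @describeIn accessors sex label(s).
#' @export
setGeneric("sexLabel", function(object) standardGeneric("sexLabel"))

#' @describeIn accessors sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @describeIn accessors ordered channel names.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @describeIn accessors channels x samples signal matrix.
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))

#' @describeIn accessors number of epochs.
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @describeIn accessors per-epoch sex labels (factor male/female).
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))

#' @describeIn accessors per-epoch subject identifiers.
#' @export
setGeneric("epochSubjects", function(object) standardGeneric("epochSubjects"))

setMethod("subjectId", "EEGRecording", function(object) object@subjectId)
setMethod("sexLabel", "EEGRecording", function(object) object@sex)
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
setMethod("channelNames", "EEGRecording", function(object) object@channelNames)
setMethod("signalData", "EEGRecording", function(object) object@signal)

setMethod("samplingRate", "EpochSet", function(object) object@fs)
setMethod("channelNames", "EpochSet", function(object) object@channelNames)
setMethod("nEpochs", "EpochSet", function(object) dim(object@epochs)[1])
setMethod("epochLabels", "EpochSet", function(object) object@labels)
setMethod("epochSubjects", "EpochSet", function(object) object@subjectIds)
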