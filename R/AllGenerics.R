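#' @describeIn EEGRecording-class sampling rate in Hz.
#' @param object,x an object.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @describeIn EEGRecording-class ordered channel labels.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @describeIn EEGRecording-class sample matrix (samples x channels, uV).
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))

#' @describeIn EEGRecording-class subject identifier.
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))

#' @describeIn EEGRecording-class diagnostic group label.
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))

#' @describeIn EEGRecording-class number of samples per channel.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @describeIn EEGRecording-class recording duration in seconds.
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @describeIn Montage-class rostral (frontal) channel labels.
#' @export
setGeneric("rostralChannels", function(object) standardGeneric("rostralChannels"))

#' @describeIn Montage-class caudal (posterior) channel labels.
#' @export
setGeneric("caudalChannels", function(object) standardGeneric("caudalChannels"))

#' @describeIn Montage-class all 19 montage labels, in order.
#' @export
setGeneric("montageChannels", function(object) standardGeneric("montageChannels"))

#' @describeIn DFAResult-class named per-channel DFA scaling exponents.
#' @export
setGeneric("dfaExponents", function(object) standardGeneric("dfaExponents"))

#' @describeIn KmaxScan-class kmax selected by the median rule.
#' @export
setGeneric("selectedKmax", function(object) standardGeneric("selectedKmax"))

setMethod("samplingRate", "EEGRecording", function(object) object@fs)
setMethod("channelNames", "EEGRecording", function(object) colnames(object@data))
setMethod("signalData", "EEGRecording", function(object) object@data)
setMethod("subjectID", "EEGRecording", function(object) object@subjectID)
setMethod("groupLabel", "EEGRecording", function(object) object@group)
setMethod("nSamples", "EEGRecording", function(object) nrow(object@data))
setMethod("duration", "EEGRecording",
          function(object) nrow(object@data) / object@fs)

setMethod("rostralChannels", "Montage", function(object) object@rostral)
setMethod("caudalChannels", "Montage", function(object) object@caudal)
setMethod("montageChannels", "Montage", function(object) object@all19)

setMethod("dfaExponents", "DFAResult", function(object) object@exponents)
setMethod("selectedKmax", "KmaxScan", function(object) object@selectedKmax)

# internal: rebuild a recording with new sample data, keeping metadata
replaceData <- function(rec, newdata) {
  rec@data <- newdata
  validObject(rec)
  rec
}
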