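#' @import methods
NULL

GROUP_LEVELS <- c("control", "AD", "FTD", "unknown")

#' Multichannel EEG recording
#'
#' Container for a multichannel scalp EEG time series. Samples are stored as
#' a numeric matrix (rows = samples, columns = channels, in microvolts) with
#' the channel labels as column names, together with the sampling rate and
#' subject metadata.
#'
#' @slot data numeric matrix, samples x channels, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot subjectID subject identifier.
#' @slot group diagnostic group, one of `"control"`, `"AD"`, `"FTD"`,
#'   `"unknown"`.
#'
#' @seealso [EEGRecording()] for the user-facing constructor,
#'   [readRecording()] to read one from disk.
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    subjectID = "character",
    group = "character"
  ),
  prototype(
    data = matrix(numeric(0), 0, 0),
    fs = 500,
    subjectID = NA_character_,
    group = "unknown"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@data))
    msg <- c(msg, "'data' must be a numeric matrix")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  ch <- colnames(object@data)
  if (ncol(object@data) > 0L && is.null(ch))
    msg <- c(msg, "'data' must carry channel labels as column names")
  if (!is.null(ch) && anyDuplicated(ch))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@group) != 1L || !(object@group %in% GROUP_LEVELS))
    msg <- c(msg, sprintf("'group' must be one of: %s",
                          paste(GROUP_LEVELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Epoch extracted from a recording
#'
#' An [EEGRecording-class] plus the offset (in seconds) at which the epoch
#' was cut from its parent recording. Channel order is inherited from the
#' parent.
#'
#' @slot sourceOffset offset into the parent recording, seconds.
#' @export
setClass("EEGEpoch",
  contains = "EEGRecording",
  representation(sourceOffset = "numeric"),
  prototype(sourceOffset = 0)
)

setValidity("EEGEpoch", function(object) {
  if (length(object@sourceOffset) != 1L || !is.finite(object@sourceOffset) ||
      object@sourceOffset < 0)
    return("'sourceOffset' must be a single non-negative number")
  TRUE
})

#' 10-20 montage with rostral/caudal channel groups
#'
#' The fixed 19-channel 10-20 montage used throughout the package, with the
#' frontal (rostral) and posterior (caudal) 7-channel regions used for
#' regional averaging. The five mid-chain channels (T3, C3, Cz, C4, T4)
#' belong to neither region.
#'
#' @slot all19 ordered labels of the 19 montage channels.
#' @slot rostral labels of the 7 frontal channels.
#' @slot caudal labels of the 7 posterior channels.
#' @seealso [standardMontage()]
#' @export
setClass("Montage",
  representation(
    all19 = "character",
    rostral = "character",
    caudal = "character"
  )
)

setValidity("Montage", function(object) {
  msg <- character(0)
  if (length(object@all19) != 19L || anyDuplicated(object@all19))
    msg <- c(msg, "'all19' must hold 19 unique labels")
  if (length(intersect(object@rostral, object@caudal)) > 0L)
    msg <- c(msg, "rostral and caudal sets must be disjoint")
  if (!all(object@rostral %in% object@all19) ||
      !all(object@caudal %in% object@all19))
    msg <- c(msg, "regional sets must be subsets of 'all19'")
  if (length(msg)) msg else TRUE
})

#' Per-channel DFA result
#'
#' Result of detrended fluctuation analysis of one recording: the
#' per-channel scaling exponent together with the full fluctuation function
#' and the settings that produced it.
#'
#' @slot exponents named numeric, one scaling exponent per channel.
#' @slot windowSizes window sizes in seconds (strictly increasing).
#' @slot fluctuation matrix of F(n), rows = window sizes, cols = channels
#'   (microvolts).
#' @slot fitInterval numeric(2), window-size interval (s) used for the
#'   log-log fit.
#' @slot calcInterval numeric(2), window-size interval (s) over which F(n)
#'   was computed.
#' @slot overlap window overlap fraction in `[0, 0.9]`.
#' @slot residuals named numeric, per-channel RMS residual of the log-log
#'   fit (goodness of fit).
#' @slot subjectID subject identifier.
#' @export
setClass("DFAResult",
  representation(
    exponents = "numeric",
    windowSizes = "numeric",
    fluctuation = "matrix",
    fitInterval = "numeric",
    calcInterval = "numeric",
    overlap = "numeric",
    residuals = "numeric",
    subjectID = "character"
  )
)

setValidity("DFAResult", function(object) {
  msg <- character(0)
  if (is.unsorted(object@windowSizes, strictly = TRUE))
    msg <- c(msg, "'windowSizes' must be strictly increasing")
  if (length(object@fitInterval) != 2L || length(object@calcInterval) != 2L)
    msg <- c(msg, "fit and calculation intervals must have length 2")
  if (nrow(object@fluctuation) != length(object@windowSizes))
    msg <- c(msg, "'fluctuation' rows must match 'windowSizes'")
  if (length(msg)) msg else TRUE
})

#' kmax scan for the Higuchi fractal dimension
#'
#' Cohort-level scan of the Higuchi kmax parameter: the 19-channel-average
#' HFD of every subject at every tested kmax, the per-group mean +/- SEM
#' curves, and the kmax selected by the median rule.
#'
#' @slot kmaxValues tested kmax values (strictly increasing integers >= 2).
#' @slot subjectMeans matrix, subjects x kmax, of channel-average HFD.
#' @slot groups diagnostic group per subject (row).
#' @slot selectedKmax the kmax whose across-subject mean HFD is closest to
#'   the median of the across-subject mean HFD curve.
#' @slot groupCurves data.frame with columns kmax, group, mean, sem.
#' @export
setClass("KmaxScan",
  representation(
    kmaxValues = "integer",
    subjectMeans = "matrix",
    groups = "character",
    selectedKmax = "integer",
    groupCurves = "data.frame"
  )
)

setValidity("KmaxScan", function(object) {
  msg <- character(0)
  if (any(object@kmaxValues < 2L) ||
      is.unsorted(object@kmaxValues, strictly = TRUE))
    msg <- c(msg, "'kmaxValues' must be strictly increasing integers >= 2")
  if (ncol(object@subjectMeans) != length(object@kmaxValues))
    msg <- c(msg, "'subjectMeans' columns must match 'kmaxValues'")
  if (nrow(object@subjectMeans) != length(object@groups))
    msg <- c(msg, "'groups' must label every subject row")
  if (length(msg)) msg else TRUE
})

#' Construct an EEG recording
#'
#' @param data numeric matrix (samples x channels) or data.frame; column
#'   names are channel labels.
#' @param fs sampling rate, Hz.
#' @param channels optional channel labels overriding column names.
#' @param subjectID subject identifier.
#' @param group diagnostic group (`"control"`, `"AD"`, `"FTD"`,
#'   `"unknown"`).
#' @return An [EEGRecording-class].
#' @examples
#' x <- matrix(rnorm(1000), ncol = 2, dimnames = list(NULL, c("Fp1", "Fp2")))
#' rec <- EEGRecording(x, fs = 500, subjectID = "s01")
#' @export
EEGRecording <- function(data, fs, channels = NULL, subjectID = NA_character_,
                         group = "unknown") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.null(channels)) colnames(data) <- channels
  new("EEGRecording", data = data, fs = as.numeric(fs),
      subjectID = as.character(subjectID), group = as.character(group))
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              class(object), ncol(object@data), nrow(object@data),
              object@fs, nrow(object@data) / object@fs))
  cat(sprintf("  subject: %s  group: %s\n", object@subjectID, object@group))
  ch <- colnames(object@data)
  if (!is.null(ch))
    cat("  channels:", paste(ch, collapse = " "), "\n")
  if (is(object, "EEGEpoch"))
    cat(sprintf("  source offset: %g s\n", object@sourceOffset))
})

setMethod("show", "Montage", function(object) {
  cat("10-20 montage (19 channels)\n")
  cat("  rostral:", paste(object@rostral, collapse = " "), "\n")
  cat("  caudal: ", paste(object@caudal, collapse = " "), "\n")
  cat("  midline:", paste(setdiff(object@all19,
                                  c(object@rostral, object@caudal)),
                          collapse = " "), "\n")
})

setMethod("show", "DFAResult", function(object) {
  cat(sprintf("DFAResult: %d channels, fit %g-%g s (calc %g-%g s, overlap %g%%)\n",
              length(object@exponents), object@fitInterval[1],
              object@fitInterval[2], object@calcInterval[1],
              object@calcInterval[2], 100 * object@overlap))
  cat(sprintf("  exponent range: %.3f .. %.3f (mean %.3f)\n",
              min(object@exponents), max(object@exponents),
              mean(object@exponents)))
})

setMethod("show", "KmaxScan", function(object) {
  cat(sprintf("KmaxScan: %d subjects x %d kmax values (%d..%d)\n",
              nrow(object@subjectMeans), length(object@kmaxValues),
              min(object@kmaxValues), max(object@kmaxValues)))
  cat(sprintf("  selected kmax: %d\n", object@selectedKmax))
})
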