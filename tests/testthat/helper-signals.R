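# fixture builders shared across test files

# wrap a numeric matrix as an epoch (channels named or auto-labelled)
makeEpoch <- function(data, fs, channels = NULL, subjectID = "test",
                      group = "unknown") {
  data <- as.matrix(data)
  if (is.null(colnames(data)))
    colnames(data) <- if (!is.null(channels)) channels
      else paste0("ch", seq_len(ncol(data)))
  new("EEGEpoch", data = data, fs = fs, subjectID = subjectID,
      group = group, sourceOffset = 0)
}

# single-channel epoch from a signal vector
signalEpoch <- function(x, fs, channel = "Pz", ...) {
  makeEpoch(matrix(x, ncol = 1, dimnames = list(NULL, channel)), fs, ...)
}

# full 19-channel recording with iid Gaussian channels
whiteRecording <- function(fs, durationS, seed, group = "unknown",
                           subjectID = "white") {
  genSignalRecording("white", fs, durationS, seed, group = group,
                     subjectID = subjectID)
}
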