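#' Band-pass filter a recording
#'
#' Zero-phase band-pass filtering of every channel. The broadband variant
#' (default, e.g. 1-45 Hz before band-power and fractal-dimension analysis)
#' uses a 4th-order Butterworth applied forward-backward; the narrowband
#' variant (e.g. the 8-13 Hz alpha filter feeding the Hilbert envelope)
#' uses a window-method linear-phase FIR with a 2 Hz transition width,
#' applied by FFT convolution with the group delay compensated so the
#' output is delay-free.
#'
#' @param rec an [EEGRecording-class] (or [EEGEpoch-class]).
#' @param lowHz high-pass edge, Hz.
#' @param highHz low-pass edge, Hz.
#' @param kind `"broadband"` (Butterworth, zero-phase) or `"narrowband"`
#'   (FIR).
#' @return filtered object of the same class and length.
#' @examples
#' rec <- genSignalRecording("white", fs = 250, durationS = 4, seed = 1)
#' filt <- bandpass(rec, 1, 45)
#' @export
bandpass <- function(rec, lowHz, highHz,
                     kind = c("broadband", "narrowband")) {
  kind <- match.arg(kind)
  fs <- samplingRate(rec)
  if (!(lowHz > 0 && lowHz < highHz && highHz < fs / 2))
    stop(sprintf("invalid filter edges: need 0 < %g < %g < fs/2 = %g",
                 lowHz, highHz, fs / 2))
  x <- signalData(rec)
  y <- if (kind == "broadband") {
    bf <- signal::butter(4, c(lowHz, highHz) / (fs / 2), type = "pass")
    apply(x, 2, function(ch) signal::filtfilt(bf, ch))
  } else {
    firFilterZeroPhaseMatrix(x, firBandpassTaps(lowHz, highHz, fs))
  }
  dimnames(y) <- dimnames(x)
  replaceData(rec, y)
}

# linear-phase FIR band-pass taps, Hamming window method, 2 Hz transition
firBandpassTaps <- function(lowHz, highHz, fs, transitionHz = 2) {
  L <- ceiling(3.3 * fs / transitionHz)
  if (L %% 2 == 0) L <- L + 1            # odd length => integer group delay
  signal::fir1(L - 1, c(lowHz, highHz) / (fs / 2), type = "pass")
}

# apply symmetric FIR by FFT convolution; shift by the (L-1)/2 group delay
# so the result is zero-phase
firFilterZeroPhase <- function(x, h) {
  firFilterZeroPhaseMatrix(matrix(x, ncol = 1), h)[, 1]
}

# matrix variant: all channels in one mvfft pass, taps transformed once
firFilterZeroPhaseMatrix <- function(x, h) {
  n <- nrow(x)
  L <- length(h)
  m <- stats::nextn(n + L - 1, 2)
  H <- stats::fft(c(h, numeric(m - L)))
  X <- stats::mvfft(rbind(x, matrix(0, m - n, ncol(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / m
  y[((L - 1) / 2) + seq_len(n), , drop = FALSE]
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' that at every sample the channel mean is zero.
#'
#' @param rec an [EEGRecording-class] with at least 2 channels.
#' @return re-referenced object of the same class.
#' @export
commonAverageReference <- function(rec) {
  x <- signalData(rec)
  if (ncol(x) < 2) stop("common average reference needs >= 2 channels")
  replaceData(rec, x - rowMeans(x))
}

#' Select the earliest artifact-free epoch
#'
#' Scans the recording for the earliest contiguous window of the requested
#' duration in which no sample on any channel exceeds the amplitude limit,
#' and returns it as an [EEGEpoch-class] carrying its offset into the
#' parent recording. The default 100 uV limit is the conventional
#' scalp-EEG rejection threshold; the data this pipeline expects have
#' already had large artifacts removed upstream, so this is a guard rather
#' than a cleaning step.
#'
#' @param rec an [EEGRecording-class].
#' @param durationS epoch duration, seconds (default 15).
#' @param ampLimitUv rejection threshold, microvolts (default 100).
#' @return An [EEGEpoch-class].
#' @export
selectEpoch <- function(rec, durationS = 15, ampLimitUv = 100) {
  fs <- samplingRate(rec)
  x <- signalData(rec)
  n <- as.integer(round(durationS * fs))
  if (n > nrow(x))
    stop(sprintf("recording (%.1f s) shorter than requested epoch (%g s)",
                 duration(rec), durationS))
  bad <- as.integer(rowSums(abs(x) > ampLimitUv) > 0L)
  cs <- c(0L, cumsum(bad))
  nWin <- nrow(x) - n + 1L
  badInWin <- cs[(n + 1):(n + nWin)] - cs[seq_len(nWin)]
  start <- which(badInWin == 0L)[1]
  if (is.na(start)) {
    runs <- rle(bad == 0L)
    maxClean <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    stop(sprintf(paste0("no artifact-free window of %g s found ",
                        "(longest clean stretch: %.2f s)"),
                 durationS, maxClean / fs))
  }
  new("EEGEpoch",
      data = x[start:(start + n - 1L), , drop = FALSE],
      fs = fs, subjectID = subjectID(rec), group = groupLabel(rec),
      sourceOffset = (start - 1L) / fs)
}

# analytic-signal magnitude of one channel via the frequency-domain
# Hilbert transformer
analyticEnvelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[c(1, n / 2 + 1)] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * w, inverse = TRUE) / n)
}

#' Hilbert amplitude envelope
#'
#' Per-channel magnitude of the analytic signal, with `trimS` seconds
#' removed from each end to suppress filter and transform edge effects.
#' The input is expected to be narrowband filtered already (see
#' [bandpass()] with `kind = "narrowband"`).
#'
#' @param rec an [EEGRecording-class], narrowband filtered.
#' @param trimS seconds trimmed from each end (default 1).
#' @return object of the same class holding the envelope, shortened by
#'   `2 * trimS` seconds.
#' @export
hilbertEnvelope <- function(rec, trimS = 1) {
  fs <- samplingRate(rec)
  x <- signalData(rec)
  nTrim <- as.integer(round(trimS * fs))
  if (2 * nTrim >= nrow(x))
    stop("trim removes the whole recording")
  n <- nrow(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[c(1, n / 2 + 1)] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::mvfft(stats::mvfft(x) * w, inverse = TRUE) / n)
  keep <- (nTrim + 1):(n - nTrim)
  env <- env[keep, , drop = FALSE]
  colnames(env) <- colnames(x)
  replaceData(rec, env)
}
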