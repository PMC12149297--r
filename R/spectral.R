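#' Canonical EEG frequency bands
#'
#' The five canonical bands tiling 1-45 Hz: delta [1,4), theta [4,8),
#' alpha [8,13), beta [13,30), gamma [30,45]. Edges are half-open (gamma
#' closed at 45) so band powers tile the broadband range with no double
#' counting.
#'
#' @return data.frame with columns `name`, `lowHz`, `highHz`.
#' @export
canonicalBands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lowHz = c(1, 4, 8, 13, 30),
    highHz = c(4, 8, 13, 30, 45)
  )
}

# Welch-averaged one-sided PSD of one channel: Hamming windows of
# `nSeg` samples, 50% overlap, window power compensated so that
# sum(psd) * df = signal variance for broadband signals.
welchPsd <- function(x, fs, nSeg) {
  n <- length(x)
  if (nSeg > n) stop("Welch segment longer than the signal")
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nSeg - 1) / (nSeg - 1))
  U <- sum(w^2) / nSeg
  hop <- max(1L, nSeg %/% 2L)
  starts <- seq(1L, n - nSeg + 1L, by = hop)
  acc <- numeric(nSeg %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nSeg - 1L)] * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_along(acc)]
  }
  psd <- acc / (length(starts) * fs * nSeg * U)
  scale <- rep(2, length(psd))
  scale[1] <- 1
  if (nSeg %% 2 == 0) scale[length(psd)] <- 1
  list(freq = (seq_along(psd) - 1) * fs / nSeg, psd = psd * scale)
}

#' Per-channel power spectrum of an epoch
#'
#' Welch-style averaged periodogram (Hamming windows, 50% overlap) with the
#' stated FFT window length, reported on a regular frequency-step grid by
#' summing the native bins falling into each step (power per bin, uV^2).
#' With the default 2 s window the native resolution is 0.5 Hz, re-gridded
#' to 1 Hz steps.
#'
#' @param epoch an [EEGEpoch-class] (or [EEGRecording-class]).
#' @param windowS FFT window length, seconds (default 2).
#' @param stepHz output grid step, Hz (default 1).
#' @return list with `freq` (bin centres, Hz) and `power` (matrix,
#'   bins x channels, uV^2 per bin).
#' @export
powerSpectrum <- function(epoch, windowS = 2, stepHz = 1) {
  fs <- samplingRate(epoch)
  if (windowS > duration(epoch))
    stop("FFT window longer than the epoch")
  nSeg <- as.integer(round(windowS * fs))
  x <- signalData(epoch)
  first <- welchPsd(x[, 1], fs, nSeg)
  df <- first$freq[2] - first$freq[1]
  grid <- seq(stepHz, fs / 2, by = stepHz)
  bin <- findInterval(first$freq, grid - stepHz / 2)
  keep <- bin >= 1 & bin <= length(grid)
  power <- matrix(0, length(grid), ncol(x),
                  dimnames = list(NULL, colnames(x)))
  for (j in seq_len(ncol(x))) {
    p <- if (j == 1) first else welchPsd(x[, j], fs, nSeg)
    sums <- rowsum((p$psd * df)[keep], bin[keep])
    power[as.integer(rownames(sums)), j] <- sums
  }
  list(freq = grid, power = power)
}

# absolute band power per channel from the native Welch grid
bandPowerMatrix <- function(epoch, bands, windowS) {
  fs <- samplingRate(epoch)
  nSeg <- as.integer(round(windowS * fs))
  x <- signalData(epoch)
  out <- matrix(NA_real_, nrow = ncol(x), ncol = nrow(bands),
                dimnames = list(colnames(x), bands$name))
  for (j in seq_len(ncol(x))) {
    p <- welchPsd(x[, j], fs, nSeg)
    df <- p$freq[2] - p$freq[1]
    for (b in seq_len(nrow(bands))) {
      hi <- bands$highHz[b]
      # half-open [low, high) except the last band, closed at its edge
      inBand <- p$freq >= bands$lowHz[b] &
        (if (b == nrow(bands)) p$freq <= hi else p$freq < hi)
      out[j, b] <- sum(p$psd[inBand]) * df
    }
  }
  out
}

#' Relative band power per channel
#'
#' Welch band-integrated power in each canonical band divided by the
#' broadband power (the union of the five bands, 1-45 Hz), per channel.
#' The five relative powers tile: they sum to 1 per channel.
#'
#' @param epoch an [EEGEpoch-class], already broadband filtered (1-45 Hz).
#' @param bands band definition data.frame as from [canonicalBands()].
#' @param windowS Welch window length, seconds (default 2).
#' @return data.frame, one row per channel: `subject_id`, `channel`, one
#'   column per band (relative power, unitless), `broadband_abs` (uV^2).
#' @examples
#' rec <- genSignalRecording("white", fs = 250, durationS = 16, seed = 1)
#' rbp <- relativeBandPower(selectEpoch(rec, 15, Inf))
#' rowSums(rbp[, canonicalBands()$name])   # == 1
#' @export
relativeBandPower <- function(epoch, bands = canonicalBands(), windowS = 2) {
  if (nrow(bands) < 1) stop("empty band set")
  if (any(bands$lowHz >= bands$highHz)) stop("invalid band edges")
  abs_power <- bandPowerMatrix(epoch, bands, windowS)
  broadband <- rowSums(abs_power)
  rel <- abs_power / broadband
  out <- data.frame(subject_id = subjectID(epoch),
                    channel = rownames(abs_power),
                    rel, broadband_abs = broadband,
                    row.names = NULL, check.names = FALSE)
  out
}
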