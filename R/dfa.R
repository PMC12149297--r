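#' Log-spaced DFA window sizes
#'
#' The default window-size grid: `nWindows` sizes spaced logarithmically
#' (base 10) across the calculation interval, inclusive at both ends.
#'
#' @param calcInterval numeric(2), calculation interval in seconds
#'   (default 0.8-30 s).
#' @param nWindows number of window sizes (default 10).
#' @return numeric vector of window sizes, seconds.
#' @export
dfaWindowSizes <- function(calcInterval = c(0.8, 30), nWindows = 10) {
  10^seq(log10(calcInterval[1]), log10(calcInterval[2]),
         length.out = nWindows)
}

#' DFA fluctuation function
#'
#' Classical detrended fluctuation analysis of one signal (typically a
#' narrowband amplitude envelope): the mean-centred signal is cumulatively
#' summed into a profile; for each window size the profile is cut into
#' windows with the stated overlap, each window is linearly detrended, the
#' RMS of the residuals is taken per window, and F(n) is the mean RMS over
#' windows.
#'
#' @param envelope numeric vector (e.g. a Hilbert amplitude envelope), uV.
#' @param fs sampling rate, Hz.
#' @param windowSizesS window sizes in seconds (default: 10 log-spaced
#'   sizes over 0.8-30 s).
#' @param overlap overlap fraction between successive windows, in
#'   `[0, 0.9]` (default 0.5).
#' @return list with `sizes` (realised window sizes, seconds) and
#'   `F` (fluctuation values, uV). Sizes under 4 samples are skipped with
#'   a warning.
#' @export
dfaFluctuation <- function(envelope, fs, windowSizesS = dfaWindowSizes(),
                           overlap = 0.5) {
  if (overlap < 0 || overlap > 0.9) stop("overlap must be in [0, 0.9]")
  n <- length(envelope)
  maxWin <- as.integer(round(max(windowSizesS) * fs))
  if (n < maxWin) stop("signal shorter than the largest DFA window")
  profile <- cumsum(envelope - mean(envelope))
  sizes <- numeric(0); F <- numeric(0)
  for (s in windowSizesS) {
    win <- as.integer(round(s * fs))
    if (win < 4) {
      warning(sprintf("window size %.3g s (< 4 samples) skipped", s))
      next
    }
    F <- c(F, dfaOneScale(profile, win, overlap))
    sizes <- c(sizes, win / fs)
  }
  if (!length(sizes)) stop("all DFA window sizes were skipped")
  list(sizes = sizes, F = F)
}

# mean RMS of linearly detrended profile windows at one scale;
# closed-form per-window regression via column sums
dfaOneScale <- function(profile, win, overlap) {
  n <- length(profile)
  hop <- max(1L, as.integer(round(win * (1 - overlap))))
  starts <- seq(1L, n - win + 1L, by = hop)
  idx <- outer(seq_len(win) - 1L, starts, "+")
  Y <- matrix(profile[idx], nrow = win)
  tc <- seq_len(win) - (win + 1) / 2
  Stt <- sum(tc^2)
  Sy <- colSums(Y)
  Sty <- as.numeric(crossprod(tc, Y))
  Syy <- colSums(Y^2)
  rss <- pmax(Syy - Sy^2 / win - Sty^2 / Stt, 0)
  mean(sqrt(rss / win))
}

#' DFA scaling exponent from a fluctuation function
#'
#' Least-squares slope of log10 F(n) vs log10 n restricted to window sizes
#' inside the fit interval; the RMS residual of the fit is reported as a
#' goodness-of-fit diagnostic.
#'
#' @param sizes window sizes, seconds.
#' @param F fluctuation values.
#' @param fitInterval numeric(2), fit interval in seconds (default 2-25 s).
#' @return list with `alpha` (the scaling exponent) and `residual`
#'   (RMS log10 residual).
#' @export
dfaExponent <- function(sizes, F, fitInterval = c(2, 25)) {
  sel <- sizes >= fitInterval[1] & sizes <= fitInterval[2] & F > 0
  if (sum(sel) < 3)
    stop("fewer than 3 window sizes inside the fit interval")
  lx <- log10(sizes[sel]); ly <- log10(F[sel])
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  fitted <- mean(ly) + slope * (lx - mean(lx))
  list(alpha = slope, residual = sqrt(mean((ly - fitted)^2)))
}

#' Alpha-band long-range temporal correlations of a recording
#'
#' The full LRTC pipeline for one recording: the first `durationS` seconds
#' are narrowband FIR filtered to the alpha band (8-13 Hz), the Hilbert
#' amplitude envelope is extracted (1 s trimmed at each end), and DFA is
#' run per channel with 10 log-spaced window sizes spanning the 0.8-30 s
#' calculation interval at 50% overlap, fitting the exponent over 2-25 s.
#'
#' @param rec an [EEGRecording-class], at least `durationS` long.
#' @param durationS analysis duration, seconds (default 300).
#' @param lowHz,highHz narrowband edges, Hz (default 8 and 13).
#' @param calcInterval,nWindows,overlap,fitInterval DFA settings, see
#'   [dfaFluctuation()] and [dfaExponent()].
#' @param trimS envelope edge trim, seconds.
#' @return A [DFAResult-class].
#' @export
alphaLrtcPipeline <- function(rec, durationS = 300, lowHz = 8, highHz = 13,
                              calcInterval = c(0.8, 30), nWindows = 10,
                              overlap = 0.5, fitInterval = c(2, 25),
                              trimS = 1) {
  fs <- samplingRate(rec)
  if (duration(rec) < durationS)
    stop(sprintf("recording (%.1f s) shorter than the %g s DFA duration",
                 duration(rec), durationS))
  x <- signalData(rec)[seq_len(as.integer(round(durationS * fs))), ,
                       drop = FALSE]
  seg <- replaceData(rec, x)
  narrow <- bandpass(seg, lowHz, highHz, kind = "narrowband")
  env <- signalData(hilbertEnvelope(narrow, trimS = trimS))
  sizesS <- dfaWindowSizes(calcInterval, nWindows)
  exps <- numeric(ncol(env)); resid <- numeric(ncol(env))
  Fmat <- NULL; sizes <- NULL
  for (j in seq_len(ncol(env))) {
    fl <- dfaFluctuation(env[, j], fs, sizesS, overlap)
    if (is.null(Fmat))
      Fmat <- matrix(NA_real_, length(fl$sizes), ncol(env),
                     dimnames = list(NULL, colnames(env)))
    sizes <- fl$sizes
    Fmat[, j] <- fl$F
    fit <- dfaExponent(fl$sizes, fl$F, fitInterval)
    exps[j] <- fit$alpha
    resid[j] <- fit$residual
  }
  names(exps) <- names(resid) <- colnames(env)
  new("DFAResult", exponents = exps, windowSizes = sizes,
      fluctuation = Fmat, fitInterval = fitInterval,
      calcInterval = calcInterval, overlap = overlap,
      residuals = resid, subjectID = subjectID(rec))
}
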