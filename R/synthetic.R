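# evaluate expr under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# fractional Gaussian noise by circulant embedding (Davies-Harte):
# exact target autocovariance, unit variance; assumes the RNG is seeded
genFgnRaw <- function(n, H) {
  stopifnot(H > 0, H < 1)
  M <- stats::nextn(2 * n, 2)
  k <- 0:(M / 2)
  g <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  row <- c(g, rev(g[2:(M / 2)]))
  lambda <- Re(stats::fft(row))
  lambda[lambda < 0] <- 0                  # numerically tiny negatives
  half <- M / 2
  W <- complex(length.out = M)
  W[1] <- sqrt(lambda[1]) * stats::rnorm(1)
  W[half + 1] <- sqrt(lambda[half + 1]) * stats::rnorm(1)
  u <- stats::rnorm(half - 1); v <- stats::rnorm(half - 1)
  W[2:half] <- sqrt(lambda[2:half] / 2) * complex(real = u, imaginary = v)
  W[M:(half + 2)] <- Conj(W[2:half])
  Re(stats::fft(W))[seq_len(n)] / sqrt(M)
}

# Gaussian noise with an arbitrary one-sided amplitude profile amp(f),
# synthesized spectrally and scaled to unit expected standard deviation;
# RNG must be seeded. Independent components can be fused into one call by
# combining their profiles in quadrature.
synthSpectralRaw <- function(n, fs, ampOf, normalize = TRUE) {
  m <- stats::nextn(n, 2)
  half <- m / 2
  freqs <- (0:half) * fs / m
  amp <- ampOf(freqs)
  amp[1] <- 0
  re <- stats::rnorm(half + 1); im <- stats::rnorm(half + 1)
  spec <- complex(real = re, imaginary = im) * amp
  spec[half + 1] <- complex(real = re[half + 1]) * amp[half + 1]
  full <- c(spec, Conj(rev(spec[2:half])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)] / m
  if (!normalize) return(x)
  expSd <- sqrt(4 * sum(amp[2:half]^2) + amp[half + 1]^2) / m
  if (expSd > 0) x / expSd else x
}

# power-law (amplitude ~ f^(-beta/2)), optionally band-limited
genPowerLawRaw <- function(n, fs, beta = 0, lowHz = NULL, highHz = NULL) {
  synthSpectralRaw(n, fs, function(f) {
    a <- numeric(length(f))
    pos <- f > 0
    a[pos] <- f[pos]^(-beta / 2)
    if (!is.null(lowHz)) a[f < lowHz | f > highHz] <- 0
    a
  })
}

#' Generate a seeded single-channel test signal
#'
#' Deterministic (given the seed) generator for the signal families used to
#' calibrate and test the estimators: `white` (i.i.d. Gaussian), `pink`
#' (1/f), `power_law` (amplitude ~ f^(-beta/2)), `fgn` / `fbm`
#' (fractional Gaussian noise / Brownian motion with Hurst exponent `H`,
#' synthesized by circulant embedding so the autocovariance is exact),
#' `tone` (pure sinusoid), and `mixture` (weighted sum of component
#' specs). Noise kinds are normalized to unit standard deviation.
#'
#' @param kind signal family (see above).
#' @param fs sampling rate, Hz.
#' @param durationS duration, seconds.
#' @param seed integer seed; the same seed always yields the same signal.
#' @param H Hurst exponent in (0,1) for `fgn` / `fbm`.
#' @param beta spectral exponent >= 0 for `power_law`.
#' @param freq,amp tone frequency (Hz, < fs/2) and amplitude for `tone`.
#' @param components for `mixture`: list of lists, each holding `kind`,
#'   an optional `weight` (default 1), and any of the parameters above.
#' @return numeric vector of `round(fs * durationS)` samples.
#' @examples
#' x <- genSignal("fgn", fs = 250, durationS = 10, seed = 7, H = 0.8)
#' @export
genSignal <- function(kind = c("white", "pink", "power_law", "fgn", "fbm",
                               "tone", "mixture"),
                      fs, durationS, seed, H = 0.7, beta = 1,
                      freq = 10, amp = 1, components = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(round(fs * durationS))
  if (n < 2) stop("duration too short")
  if (kind == "tone") {
    if (freq >= fs / 2) stop("tone frequency must be below Nyquist")
    return(amp * sin(2 * pi * freq * seq(0, n - 1) / fs))
  }
  withSeed(seed, switch(kind,
    white = stats::rnorm(n),
    pink = genPowerLawRaw(n, fs, beta = 1),
    power_law = {
      if (beta < 0) stop("beta must be >= 0")
      genPowerLawRaw(n, fs, beta = beta)
    },
    fgn = genFgnRaw(n, H),
    fbm = cumsum(genFgnRaw(n, H)),
    mixture = {
      if (is.null(components) || !length(components))
        stop("mixture needs a non-empty 'components' list")
      out <- numeric(n)
      for (i in seq_along(components)) {
        comp <- components[[i]]
        w <- if (is.null(comp$weight)) 1 else comp$weight
        args <- comp[setdiff(names(comp), "weight")]
        args$fs <- fs; args$durationS <- durationS
        args$seed <- seed + 1000003L * i
        out <- out + w * do.call(genSignal, args)
      }
      out
    }))
}

#' Generate a multichannel recording of independent test signals
#'
#' Convenience wrapper building an [EEGRecording-class] whose channels are
#' independent realizations of one [genSignal()] family (per-channel seeds
#' derived from `seed`).
#'
#' @inheritParams genSignal
#' @param channels channel labels (default: the 19-channel 10-20 montage).
#' @param ... further parameters passed to [genSignal()].
#' @param subjectID,group recording metadata.
#' @return An [EEGRecording-class].
#' @export
genSignalRecording <- function(kind, fs, durationS, seed,
                               channels = CANONICAL_19, ...,
                               subjectID = "synthetic", group = "unknown") {
  data <- vapply(seq_along(channels),
                 function(j) genSignal(kind, fs, durationS,
                                       seed = seed + 101L * (j - 1L), ...),
                 numeric(as.integer(round(fs * durationS))))
  colnames(data) <- channels
  EEGRecording(data, fs = fs, subjectID = subjectID, group = group)
}

# strictly positive amplitude modulator carrying the scaling of fgn(H):
# 1 + depth * z, floored well above zero so clipping is rare
lrtcModulator <- function(n, H, depth = 0.4, floor = 0.1) {
  pmax(1 + depth * genFgnRaw(n, H), floor)
}

#' Alpha carrier with a long-range-correlated amplitude envelope
#'
#' A 10 Hz (by default) carrier amplitude-modulated by a strictly positive
#' affine transform of fractional Gaussian noise with Hurst exponent `H`,
#' so that the amplitude envelope recovered by the LRTC pipeline
#' (narrowband filter, Hilbert transform, DFA) has scaling exponent
#' approximately `H`.
#'
#' @param H target Hurst exponent of the envelope, in (0,1).
#' @param fs sampling rate, Hz.
#' @param durationS duration, seconds.
#' @param seed integer seed.
#' @param carrierHz carrier frequency, Hz (default 10, mid-alpha).
#' @param carrierAmp carrier amplitude, uV.
#' @param modDepth modulation depth (default 0.4).
#' @return numeric vector of samples (uV).
#' @export
genAlphaLrtcChannel <- function(H, fs, durationS, seed, carrierHz = 10,
                                carrierAmp = 10, modDepth = 0.4) {
  stopifnot(H > 0, H < 1)
  n <- as.integer(round(fs * durationS))
  env <- withSeed(seed, lrtcModulator(n, H, depth = modDepth))
  carrier <- sin(2 * pi * carrierHz * seq(0, n - 1) / fs)
  carrierAmp * env * carrier
}

# rostrocaudal position of each montage channel, 0 = frontal pole,
# 1 = occipital
channelAxisPosition <- function(channels = CANONICAL_19) {
  rowOf <- c(Fp1 = 0, Fp2 = 0,
             F7 = 0.25, F3 = 0.25, Fz = 0.25, F4 = 0.25, F8 = 0.25,
             T3 = 0.5, C3 = 0.5, Cz = 0.5, C4 = 0.5, T4 = 0.5,
             T5 = 0.75, P3 = 0.75, Pz = 0.75, P4 = 0.75, T6 = 0.75,
             O1 = 1, O2 = 1)
  rowOf[channels]
}

# long-range-correlated modulator sampled cheaply: fGn synthesized at a
# low rate (its scaling at the DFA fit scales is what matters) and
# linearly upsampled to the signal rate
lrtcModulatorLowRate <- function(n, fs, H, depth, envFs = 25,
                                 floor = 0.1) {
  nLow <- max(16L, as.integer(ceiling(n / fs * envFs)) + 1L)
  z <- genFgnRaw(nLow, H)
  zi <- stats::approx(seq(0, by = 1 / envFs, length.out = nLow), z,
                      xout = seq(0, by = 1 / fs, length.out = n),
                      rule = 2)$y
  pmax(1 + depth * zi, floor)
}

#' Default synthetic cohort specification
#'
#' Study conditions emulated by [genCohort()]: three diagnostic groups of
#' 20 subjects each, 19 montage channels, 300 s at 500 Hz. Group profiles
#' plant the qualitative pattern the analysis is designed to detect:
#' patient-like groups have raised delta/theta and suppressed alpha band
#' amplitudes, a stronger low-frequency-weighted complexity component
#' lowering broadband fractal dimension, and weaker alpha-envelope
#' persistence (lower Hurst exponent, caudally accentuated); the AD-like
#' profile plants a rostral-dominant fractal-dimension gradient and the
#' FTD-like profile the opposite. Effect magnitudes are set to give
#' Cohen's d near 1 against controls at n = 20.
#'
#' @param n named integer vector: subjects per group.
#' @param fs sampling rate, Hz.
#' @param durationS recording length, seconds.
#' @param masterSeed master seed; per-subject seeds are derived from it.
#' @return list understood by [genCohort()].
#' @export
defaultCohortSpec <- function(n = c(control = 20, AD = 20, FTD = 20),
                              fs = 500, durationS = 300, masterSeed = 42) {
  profile <- function(bandAmps, cxAmp, cxH, envH) {
    list(bandAmps = bandAmps, cxAmp = cxAmp,
         cxHRostral = cxH[1], cxHCaudal = cxH[2],
         envHRostral = envH[1], envHCaudal = envH[2])
  }
  list(
    n = n, fs = fs, durationS = durationS, masterSeed = masterSeed,
    scaleUv = 3, modDepth = 0.8,
    profiles = list(
      control = profile(
        c(delta = 1.0, theta = 0.7, alpha = 2.0, beta = 0.8, gamma = 0.35),
        cxAmp = 1.8, cxH = c(0.50, 0.50), envH = c(0.80, 0.84)),
      AD = profile(
        c(delta = 1.17, theta = 0.96, alpha = 1.71, beta = 0.8,
          gamma = 0.35),
        cxAmp = 3.60, cxH = c(0.38, 0.62), envH = c(0.71, 0.69)),
      FTD = profile(
        c(delta = 1.15, theta = 0.94, alpha = 1.70, beta = 0.8,
          gamma = 0.35),
        cxAmp = 3.50, cxH = c(0.62, 0.38), envH = c(0.72, 0.70))
    ),
    jitter = list(ampSdLog = 0.12, cxSdLog = 0.10, cxHurstSd = 0.03,
                  envHurstSd = 0.06)
  )
}

#' Generate a synthetic multi-subject EEG cohort
#'
#' Builds seeded 19-channel recordings for each diagnostic group of the
#' cohort specification. Every channel is a sum of band-limited Gaussian
#' noise components scaled to the group's band-amplitude profile (the
#' alpha component amplitude-modulated by a long-range-correlated envelope
#' with the group's Hurst exponent) plus a fractional-Brownian-like
#' complexity component: 1-45 Hz band-limited noise with spectral density
#' proportional to 1/f^(2H+1), whose in-band fractal dimension is 2 - H
#' and whose Hurst exponent varies along the rostrocaudal axis according
#' to the group's gradient. The unmodulated components are fused into a
#' single spectral synthesis per channel (their amplitude profiles
#' combined in quadrature), which keeps cohort generation fast. Subject-
#' level jitter is applied with per-subject seeds derived from the master
#' seed, so regeneration from the same spec is bit-identical.
#'
#' @param spec cohort specification, see [defaultCohortSpec()].
#' @return named list of [EEGRecording-class] objects with group labels.
#' @examples
#' spec <- defaultCohortSpec(n = c(control = 2, AD = 2, FTD = 2),
#'                           fs = 128, durationS = 20)
#' cohort <- genCohort(spec)
#' @export
genCohort <- function(spec = defaultCohortSpec()) {
  stopifnot(all(c("n", "fs", "durationS", "masterSeed", "profiles")
                %in% names(spec)))
  if (any(spec$n < 2)) stop("every group needs n >= 2")
  fs <- spec$fs; nSamp <- as.integer(round(fs * spec$durationS))
  bands <- canonicalBands()
  pos <- channelAxisPosition()
  jit <- list(ampSdLog = 0, cxSdLog = 0, cxHurstSd = 0, envHurstSd = 0)
  jit[names(spec$jitter)] <- spec$jitter
  scaleUv <- if (is.null(spec$scaleUv)) 3 else spec$scaleUv
  modDepth <- if (is.null(spec$modDepth)) 0.8 else spec$modDepth
  clampH <- function(h) pmin(pmax(h, 0.05), 0.95)
  # unit-RMS normalization constants for the pieces of the fused profile
  unitConst <- function(ampOf) {
    m <- stats::nextn(nSamp, 2); half <- m / 2
    f <- (0:half) * fs / m
    a <- ampOf(f); a[1] <- 0
    sqrt(4 * sum(a[2:half]^2) + a[half + 1]^2) / m
  }
  bandProfile <- function(lo, hi) function(f) as.numeric(f >= lo & f <= hi)
  cBand <- vapply(seq_len(nrow(bands)), function(b)
    unitConst(bandProfile(bands$lowHz[b], bands$highHz[b])), numeric(1))
  names(cBand) <- bands$name
  cxProfile <- function(H) function(f) {
    a <- numeric(length(f))
    inb <- f >= 1 & f <= 45
    a[inb] <- f[inb]^(-(2 * H + 1) / 2)
    a
  }
  recs <- list()
  subjIdx <- 0L
  for (g in names(spec$n)) {
    prof <- spec$profiles[[g]]
    if (is.null(prof)) stop("no profile for group ", g)
    for (i in seq_len(spec$n[[g]])) {
      subjIdx <- subjIdx + 1L
      sid <- sprintf("sub-%03d", subjIdx)
      subjSeed <- (as.numeric(spec$masterSeed) * 7919 +
                   subjIdx * 104729) %% 2147483647
      data <- withSeed(subjSeed, {
        amps <- prof$bandAmps *
          exp(stats::rnorm(length(prof$bandAmps), 0, jit$ampSdLog))
        cxAmp <- prof$cxAmp * exp(stats::rnorm(1, 0, jit$cxSdLog))
        cxH <- clampH(c(prof$cxHRostral, prof$cxHCaudal) +
                        stats::rnorm(2, 0, jit$cxHurstSd))
        envH <- clampH(c(prof$envHRostral, prof$envHCaudal) +
                         stats::rnorm(2, 0, jit$envHurstSd))
        out <- matrix(0, nSamp, length(CANONICAL_19),
                      dimnames = list(NULL, CANONICAL_19))
        isAlpha <- bands$name == "alpha"
        for (ch in seq_along(CANONICAL_19)) {
          p <- pos[ch]
          hCx <- clampH(cxH[1] + p * (cxH[2] - cxH[1]))
          hEnv <- clampH(envH[1] + p * (envH[2] - envH[1]))
          cCx <- unitConst(cxProfile(hCx))
          # amplitude profiles of independent Gaussian components combine
          # in quadrature, so one synthesis draws their sum
          fused <- synthSpectralRaw(nSamp, fs, function(f) {
            a2 <- numeric(length(f))
            for (b in which(!isAlpha))
              a2 <- a2 + (amps[[b]] / cBand[b] *
                          bandProfile(bands$lowHz[b],
                                      bands$highHz[b])(f))^2
            sqrt(a2 + (cxAmp / cCx * cxProfile(hCx)(f))^2)
          }, normalize = FALSE)
          alphaNoise <- genPowerLawRaw(nSamp, fs, beta = 0,
                                       lowHz = bands$lowHz[isAlpha],
                                       highHz = bands$highHz[isAlpha])
          mod <- lrtcModulatorLowRate(nSamp, fs, hEnv, depth = modDepth)
          out[, ch] <- scaleUv *
            (fused + amps[["alpha"]] * alphaNoise * mod)
        }
        out
      })
      recs[[sid]] <- EEGRecording(data, fs = fs, subjectID = sid,
                                  group = g)
    }
  }
  attr(recs, "spec") <- spec
  recs
}
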