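#' Box-counting fractal dimension of a time series
#'
#' Normalizes the signal graph to the unit square (time to [0,1], amplitude
#' min-max to [0,1]), lays dyadic grids of box size eps = 2^-j for
#' j = 1..floor(log2(N))-2, counts the boxes crossed by the linearly
#' interpolated curve, and returns the least-squares slope of
#' log N(eps) vs log(1/eps), clamped to [1, 2]. A smooth curve scores near
#' 1; white noise approaches 2.
#'
#' @param x numeric vector, >= 256 samples.
#' @return FD estimate in [1, 2]; a constant signal returns 1 with
#'   attribute `degenerate = TRUE`.
#' @seealso [higuchiFD()] for the curve-length-based estimator.
#' @export
boxCountingFD <- function(x) {
  n <- length(x)
  if (n < 256) stop("box-counting FD needs >= 256 samples")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tt <- seq(0, 1, length.out = n)
  y <- (x - rng[1]) / (rng[2] - rng[1])
  jmax <- floor(log2(n)) - 2
  js <- seq_len(jmax)
  counts <- vapply(js, function(j) boxCount(tt, y, 2^-j), numeric(1))
  fd <- sum((js * log(2) - mean(js * log(2))) *
            (log(counts) - mean(log(counts)))) /
        sum((js * log(2) - mean(js * log(2)))^2)
  min(max(fd, 1), 2)
}

# boxes crossed by the interpolated curve on a grid of size eps:
# per time-column min/max of the curve (samples plus interpolated values at
# column boundaries), then count the vertical boxes spanned
boxCount <- function(tt, y, eps) {
  ncols <- as.integer(round(1 / eps))
  col <- pmin(findInterval(tt, seq(0, 1, by = eps), rightmost.closed = TRUE),
              ncols)
  lo <- tapply(y, col, min)
  hi <- tapply(y, col, max)
  idx <- as.integer(names(lo))
  mins <- rep(Inf, ncols); maxs <- rep(-Inf, ncols)
  mins[idx] <- lo; maxs[idx] <- hi
  if (ncols > 1) {
    bt <- seq_len(ncols - 1) * eps
    bv <- stats::approx(tt, y, xout = bt)$y
    mins[1:(ncols - 1)] <- pmin(mins[1:(ncols - 1)], bv)
    maxs[1:(ncols - 1)] <- pmax(maxs[1:(ncols - 1)], bv)
    mins[2:ncols] <- pmin(mins[2:ncols], bv)
    maxs[2:ncols] <- pmax(maxs[2:ncols], bv)
  }
  bmin <- pmin(floor(mins / eps), ncols - 1)
  bmax <- pmin(floor(maxs / eps), ncols - 1)
  sum(bmax - bmin + 1)
}

# Higuchi step-size grid: exhaustive up to 64, otherwise 1..16 plus
# ~25 log-spaced values up to kmax
higuchiKGrid <- function(kmax) {
  if (kmax <= 64) return(seq_len(kmax))
  sort(unique(c(1:16,
                round(exp(seq(log(17), log(kmax), length.out = 25))))))
}

# mean normalized curve length L(k) for each step size k
higuchiCurveLengths <- function(x, ks) {
  n <- length(x)
  vapply(ks, function(k) {
    d <- abs(x[(k + 1):n] - x[1:(n - k)])
    m0 <- (seq_len(n - k) - 1L) %% k          # 0-based offset class
    sums <- rowsum(d, m0)
    m <- as.integer(rownames(sums)) + 1L
    nm <- (n - m) %/% k                        # intervals per offset
    mean(sums[, 1] * (n - 1) / (nm * k) / k)
  }, numeric(1))
}

#' Higuchi fractal dimension
#'
#' Higuchi's curve-length estimator: for each step size k (and each of the
#' k possible offsets) the normalized curve length L_m(k) is computed with
#' the standard (N-1)/(floor((N-m)/k) k^2) factor, averaged over offsets,
#' and the FD is the least-squares slope of log L(k) vs log(1/k). Step
#' sizes run over all integers up to `kmax` when `kmax <= 64`, otherwise
#' over 1..16 plus ~25 log-spaced values up to `kmax`.
#'
#' @param x numeric vector; length must exceed `2 * kmax`.
#' @param kmax maximum step size, >= 2.
#' @return FD estimate (dimensionless; ~1 for a smooth curve, ~2 for white
#'   noise).
#' @export
higuchiFD <- function(x, kmax) {
  kmax <- as.integer(kmax)
  if (kmax < 2) stop("kmax must be >= 2")
  n <- length(x)
  if (n <= 2 * kmax)
    stop(sprintf("signal too short (%d samples) for kmax = %d", n, kmax))
  if (max(x) == min(x)) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ks <- higuchiKGrid(kmax)
  L <- higuchiCurveLengths(x, ks)
  fitLogLogSlope(log(1 / ks), log(L))
}

fitLogLogSlope <- function(lx, ly) {
  ok <- is.finite(ly)
  lx <- lx[ok]; ly <- ly[ok]
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Windowed Higuchi fractal dimension of an epoch
#'
#' Per channel, the mean [higuchiFD()] over non-overlapping windows of
#' `windowS` seconds (default 1 s); a trailing partial window is dropped.
#'
#' @param epoch an [EEGEpoch-class] or [EEGRecording-class], broadband
#'   filtered.
#' @param kmax maximum Higuchi step size (default 126, the value used at
#'   500 Hz; use 32 at 128 Hz).
#' @param windowS window length, seconds.
#' @return data.frame, one row per channel: `subject_id`, `channel`,
#'   `method` ("higuchi"), `fd`, `kmax`, `n_windows`.
#' @export
windowedHFD <- function(epoch, kmax = 126, windowS = 1) {
  fs <- samplingRate(epoch)
  nWin <- as.integer(round(windowS * fs))
  if (nWin <= 2 * kmax)
    stop(sprintf("window of %d samples too short for kmax = %d",
                 nWin, kmax))
  x <- signalData(epoch)
  nWindows <- nrow(x) %/% nWin
  if (nWindows < 1) stop("epoch shorter than one window")
  ks <- higuchiKGrid(kmax)
  lk <- log(1 / ks)
  fd <- vapply(seq_len(ncol(x)), function(j) {
    vals <- vapply(seq_len(nWindows), function(w) {
      seg <- x[((w - 1) * nWin + 1):(w * nWin), j]
      fitLogLogSlope(lk, log(higuchiCurveLengths(seg, ks)))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  data.frame(subject_id = subjectID(epoch), channel = colnames(x),
             method = "higuchi", fd = fd, kmax = kmax,
             n_windows = nWindows, row.names = NULL)
}

#' Box-counting fractal dimension of every channel of an epoch
#'
#' Applies [boxCountingFD()] to each channel of the full epoch (no
#' sub-windowing).
#'
#' @inheritParams windowedHFD
#' @return data.frame, one row per channel: `subject_id`, `channel`,
#'   `method` ("box_counting"), `fd`.
#' @export
boxCountingTable <- function(epoch) {
  x <- signalData(epoch)
  fd <- vapply(seq_len(ncol(x)), function(j) as.numeric(boxCountingFD(x[, j])),
               numeric(1))
  data.frame(subject_id = subjectID(epoch), channel = colnames(x),
             method = "box_counting", fd = fd, row.names = NULL)
}

# the tested kmax whose across-subject mean HFD is closest to the median
# of the mean-HFD curve; ties resolve toward the smaller kmax
kmaxMedianRule <- function(kmaxValues, meanCurve) {
  med <- stats::median(meanCurve)
  kmaxValues[which.min(abs(meanCurve - med))]
}

#' Scan Higuchi kmax values over a cohort
#'
#' For every subject and every tested kmax, computes the 19-channel-average
#' windowed HFD, then selects the kmax whose across-subject mean HFD is
#' closest to the median of the across-subject mean HFD curve over all
#' tested kmax values (ties resolved toward the smaller kmax). Group
#' mean +/- SEM curves are returned for plotting. Curve lengths are
#' computed once per window over the union of all step-size grids, so
#' scanning many kmax values costs little more than the largest one.
#'
#' @param epochs list of [EEGEpoch-class] objects carrying group labels.
#' @param kmaxValues integer vector of kmax values to test (each >= 2).
#' @param windowS HFD window length, seconds.
#' @return A [KmaxScan-class].
#' @export
kmaxScan <- function(epochs, kmaxValues, windowS = 1) {
  if (!length(kmaxValues)) stop("empty kmax list")
  kmaxValues <- sort(unique(as.integer(kmaxValues)))
  if (any(kmaxValues < 2)) stop("kmax values must be >= 2")
  if (length(epochs) < 2) stop("kmax scan needs >= 2 subjects")
  grids <- lapply(kmaxValues, higuchiKGrid)
  ksAll <- sort(unique(unlist(grids)))
  subjectMeans <- matrix(NA_real_, nrow = length(epochs),
                         ncol = length(kmaxValues))
  groups <- character(length(epochs))
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    groups[i] <- groupLabel(ep)
    fs <- samplingRate(ep)
    nWin <- as.integer(round(windowS * fs))
    if (nWin <= 2 * max(kmaxValues))
      stop("window too short for the largest kmax tested")
    x <- signalData(ep)
    nWindows <- nrow(x) %/% nWin
    # L(k) accumulated per channel x window over the union grid
    fdPerKmax <- matrix(0, ncol(x), length(kmaxValues))
    for (j in seq_len(ncol(x))) {
      for (w in seq_len(nWindows)) {
        seg <- x[((w - 1) * nWin + 1):(w * nWin), j]
        L <- higuchiCurveLengths(seg, ksAll)
        for (q in seq_along(kmaxValues)) {
          sel <- match(grids[[q]], ksAll)
          fdPerKmax[j, q] <- fdPerKmax[j, q] +
            fitLogLogSlope(log(1 / ksAll[sel]), log(L[sel]))
        }
      }
    }
    subjectMeans[i, ] <- colMeans(fdPerKmax / nWindows)
  }
  selected <- kmaxMedianRule(kmaxValues, colMeans(subjectMeans))
  curves <- do.call(rbind, lapply(unique(groups), function(g) {
    rows <- subjectMeans[groups == g, , drop = FALSE]
    data.frame(kmax = kmaxValues, group = g, mean = colMeans(rows),
               sem = apply(rows, 2, stats::sd) / sqrt(nrow(rows)))
  }))
  new("KmaxScan", kmaxValues = kmaxValues, subjectMeans = subjectMeans,
      groups = groups, selectedKmax = as.integer(selected),
      groupCurves = curves)
}
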