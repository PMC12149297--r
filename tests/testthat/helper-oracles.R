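# Independent brute-force oracles used to cross-check the estimators.
# These deliberately use naive direct-summation implementations, not the
# package's vectorized code paths.

# DFA with non-overlapping segments, per-segment lm() detrending
naiveDFA <- function(x, fs, sizesS) {
  prof <- cumsum(x - mean(x))
  vapply(sizesS, function(s) {
    n <- round(s * fs)
    ns <- length(prof) %/% n
    rms <- vapply(seq_len(ns), function(i) {
      seg <- prof[((i - 1) * n + 1):(i * n)]
      tt <- seq_len(n)
      sqrt(mean(stats::resid(stats::lm(seg ~ tt))^2))
    }, numeric(1))
    mean(rms)
  }, numeric(1))
}

# Higuchi curve lengths by direct double loop over k and offset m
naiveHiguchi <- function(x, kmax, ks = seq_len(kmax)) {
  n <- length(x)
  L <- vapply(ks, function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      nm <- (n - m) %/% k
      if (nm < 1) return(NA_real_)
      idx <- m + (0:nm) * k
      sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }, numeric(1))
    mean(Lm, na.rm = TRUE)
  }, numeric(1))
  lk <- log(1 / ks)
  ll <- log(L)
  ok <- is.finite(ll)
  stats::coef(stats::lm(ll[ok] ~ lk[ok]))[2]
}

# Benjamini-Hochberg step-up applied by hand
handBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Pillai's trace from the eigenvalues of W^-1 B
pillaiOracle <- function(Y, groups) {
  Y <- as.matrix(Y)
  groups <- factor(groups)
  gm <- colMeans(Y)
  p <- ncol(Y)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (g in levels(groups)) {
    Yg <- Y[groups == g, , drop = FALSE]
    mg <- colMeans(Yg)
    W <- W + crossprod(sweep(Yg, 2, mg))
    B <- B + nrow(Yg) * tcrossprod(mg - gm)
  }
  ev <- Re(eigen(solve(W) %*% B, only.values = TRUE)$values)
  sum(ev / (1 + ev))
}

# one-way sums of squares decomposition by direct summation
anovaOracle <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  list(F = (ssb / df1) / (ssw / df2), r2 = ssb / (ssb + ssw),
       df1 = df1, df2 = df2)
}
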