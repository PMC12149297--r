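test_that("Cohen's d matches hand computation and is antisymmetric", {
  # pooled SD of {0,1,2} vs {2,3,4} is exactly 1; signed difference -2
  expect_equal(cohensD(c(0, 1, 2), c(2, 3, 4)), -2)
  expect_equal(cohensD(c(2, 3, 4), c(0, 1, 2)), 2)
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohensD(c(1, 1), c(1, 1)), "zero pooled")
  expect_error(cohensD(1, c(1, 2)), "n >= 2")

  # t = d * sqrt(n1 n2 / (n1 + n2)) against t.test
  set.seed(5)
  for (i in 1:5) {
    g1 <- rnorm(7); g2 <- rnorm(11, 0.5)
    d <- cohensD(g1, g2)
    tt <- t.test(g1, g2, var.equal = TRUE)$statistic
    expect_equal(d * sqrt(7 * 11 / 18), unname(tt), tolerance = 1e-10)
  }
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  set.seed(6)
  v <- c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 2))
  g <- rep(c("a", "b", "c"), each = 10)
  res <- oneWayAnova(v, g)
  or <- anovaOracle(v, g)
  expect_equal(res$statistic, or$F, tolerance = 1e-10)
  expect_equal(res$effect, or$r2, tolerance = 1e-10)
  expect_equal(res$df1, or$df1)
  expect_equal(res$df2, or$df2)
  expect_true(res$effect >= 0 && res$effect <= 1)

  # two groups: F equals the square of the pooled t statistic
  t2 <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)$statistic^2
  expect_equal(oneWayAnova(v[g != "c"], g[g != "c"])$statistic,
               unname(t2), tolerance = 1e-10)

  same <- rep(c(1, 2, 3), 3)
  res0 <- oneWayAnova(same, rep(c("a", "b", "c"), each = 3))
  expect_equal(res0$statistic, 0)
  expect_lt(res0$effect, 1e-12)

  degen <- oneWayAnova(rep(1, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(degen$degenerate)
})

test_that("Tukey HSD reduces to the pooled t test for two groups", {
  set.seed(7)
  v <- c(rnorm(8), rnorm(9, 0.8))
  g <- rep(c("a", "b"), c(8, 9))
  tk <- tukeyHsd(v, g)
  tt <- t.test(v[g == "b"], v[g == "a"], var.equal = TRUE)
  expect_equal(tk$p_tukey, tt$p.value, tolerance = 1e-6)
  expect_equal(abs(tk$t), abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(tk$df, 15)

  v3 <- rep(c(1, 2, 3, 4), 3) + rep(c(0, 0, 0), each = 4)
  tk3 <- tukeyHsd(v3, rep(c("a", "b", "c"), each = 4))
  expect_true(all(tk3$p_tukey > 0.99))

  # widely separated groups: all adjusted p tiny
  set.seed(8)
  vs <- c(rnorm(10, 0), rnorm(10, 10), rnorm(10, 20))
  tks <- tukeyHsd(vs, rep(c("a", "b", "c"), each = 10))
  expect_true(all(tks$p_tukey < 1e-6))
})

test_that("Pillai's trace matches the eigen-decomposition oracle", {
  set.seed(9)
  Y <- matrix(rnorm(40 * 4), 40, 4)
  Y[1:14, 1] <- Y[1:14, 1] + 1.5
  Y[15:27, 2] <- Y[15:27, 2] - 1
  g <- rep(c("a", "b", "c"), c(14, 13, 13))
  res <- pillaiManova(Y, g)
  expect_equal(res$statistic, pillaiOracle(Y, g), tolerance = 1e-8)
  expect_true(res$p < 0.01)

  # identical group means: zero between-group matrix, V = 0
  base <- matrix(rnorm(10 * 3), 10, 3)
  Y0 <- rbind(base, base, base)
  g0 <- rep(c("a", "b", "c"), each = 10)
  expect_lt(pillaiManova(Y0, g0)$statistic, 1e-10)

  expect_error(pillaiManova(matrix(rnorm(10), 10, 1), rep(c("a", "b"), 5)),
               ">= 2 response")
  expect_error(pillaiManova(matrix(rnorm(12), 4, 3),
                            rep(c("a", "b"), 2)), "too few")
})

test_that("Mann-Whitney U follows the min convention with ties", {
  sep <- mannWhitneyU(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  tied <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$U, 4.5)
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$U,
               mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$U)
  swapped <- mannWhitneyU(c(10, 11, 12), c(1, 2, 3))
  expect_equal(swapped$U, sep$U)

  # exact enumeration oracle for small tie-free samples: P(U <= u) over
  # all choose(6,3) rank assignments
  g1 <- c(1.2, 3.4, 2.2); g2 <- c(5.1, 0.4, 6.3)
  res <- mannWhitneyU(g1, g2)
  combos <- combn(6, 3)
  r <- rank(c(g1, g2))
  uOf <- function(idx) {
    u1 <- sum(r[idx]) - 3 * 4 / 2
    min(u1, 9 - u1)
  }
  uObs <- uOf(1:3)
  pExact <- mean(apply(combos, 2, uOf) <= uObs)
  expect_equal(res$U, uObs)
  expect_equal(res$p, pExact, tolerance = 1e-10)
})

test_that("D'Agostino-Pearson flags skewed data and passes Gaussian data", {
  set.seed(10)
  # calibration under the null: rejection rate at alpha = 0.05 over
  # repeated Gaussian samples stays near 0.05
  rej <- vapply(1:200, function(i) dagostinoPearson(rnorm(100))$p < 0.05,
                logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.05)
  skewed <- dagostinoPearson(rexp(200))
  expect_lt(skewed$p, 1e-4)
  expect_error(dagostinoPearson(rnorm(5)), "n >= 8")
})

test_that("channelwise t maps apply BH correction per comparison family", {
  # hand-applied BH step-up oracle against the adjustment in use
  p <- c(0.001, 0.02, 0.03, 0.4)
  expect_equal(handBH(p), c(0.004, 0.04, 0.04, 0.4))
  expect_equal(p.adjust(p, method = "BH"), handBH(p))
  set.seed(11)
  prand <- runif(19)
  expect_equal(p.adjust(prand, method = "BH"), handBH(prand))
  # monotone, never decreases
  expect_true(all(handBH(prand) >= prand))
  expect_equal(order(handBH(prand)[order(prand)]), 1:19)

  # planted single-channel effect is detected
  set.seed(12)
  vals <- matrix(rnorm(60 * 19), 60, 19,
                 dimnames = list(NULL, montageChannels(standardMontage())))
  vals[31:60, "Pz"] <- vals[31:60, "Pz"] + 3
  tm <- channelwiseTMap(vals, rep(c("g1", "g2"), each = 30),
                        c("g2", "g1"))
  expect_true(tm$significant[tm$channel == "Pz"])
  expect_lte(sum(tm$significant), 2)   # BH admits occasional companions
  expect_equal(tm$p_fdr, handBH(tm$p))

  # null calibration: false-discovery proportion controlled at alpha
  set.seed(13)
  fdp <- vapply(1:200, function(i) {
    v <- matrix(rnorm(20 * 4), 20, 4,
                dimnames = list(NULL, paste0("c", 1:4)))
    any(channelwiseTMap(v, rep(c("a", "b"), each = 10),
                        c("a", "b"))$significant)
  }, logical(1))
  expect_lt(mean(fdp), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 200))
})

test_that("regional summary computes means and the asymmetry index", {
  m <- standardMontage()
  v <- setNames(rep(2.5, 19), montageChannels(m))
  rs <- regionalSummary(v, m)
  expect_equal(rs$global_mean, 2.5)
  expect_equal(rs$asymmetry, 0)

  v2 <- v
  v2[rostralChannels(m)] <- 1.6
  v2[caudalChannels(m)] <- 1.7
  v2[setdiff(names(v2), c(rostralChannels(m), caudalChannels(m)))] <- 1.65
  rs2 <- regionalSummary(v2, m)
  expect_equal(rs2$asymmetry, -0.1)     # caudal dominance
  expect_equal(rs2$rostral_mean, 1.6)
  expect_equal(rs2$caudal_mean, 1.7)

  expect_error(regionalSummary(v[-1], m), "Fp1")
})
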