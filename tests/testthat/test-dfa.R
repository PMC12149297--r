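test_that("exponent fitting is exact on pure power laws", {
  sizes <- dfaWindowSizes()
  fit <- dfaExponent(sizes, sizes^0.7)
  expect_equal(fit$alpha, 0.7, tolerance = 1e-9)
  expect_lt(fit$residual, 1e-12)

  expect_equal(dfaExponent(sizes, rep(2, length(sizes)))$alpha, 0)

  # scale-free: any sub-range of a power law gives the same slope
  sub <- dfaExponent(sizes, sizes^1.3, fitInterval = c(3, 10))$alpha
  full <- dfaExponent(sizes, sizes^1.3, fitInterval = c(2, 25))$alpha
  expect_equal(sub, full, tolerance = 1e-9)

  expect_error(dfaExponent(c(2, 3), c(1, 2)), "fewer than 3")
})

test_that("fluctuation function matches the naive oracle and scales linearly", {
  x <- genSignal("fgn", 250, 60, seed = 21, H = 0.7)
  sizes <- dfaWindowSizes(c(1, 20), 6)
  fl <- dfaFluctuation(x, 250, sizes, overlap = 0)
  oracle <- naiveDFA(x, 250, sizes)
  expect_equal(fl$F, oracle, tolerance = 1e-8)

  fl2 <- dfaFluctuation(2 * x, 250, sizes, overlap = 0)
  expect_equal(fl2$F, 2 * fl$F, tolerance = 1e-10)
  expect_equal(dfaExponent(fl2$sizes, fl2$F)$alpha,
               dfaExponent(fl$sizes, fl$F)$alpha, tolerance = 1e-10)

  expect_warning(dfaFluctuation(x, 250, c(0.005, 5)), "skipped")
  expect_error(suppressWarnings(dfaFluctuation(x, 250, c(0.001, 0.002))),
               "skipped|shorter")
  expect_error(dfaFluctuation(x, 250, overlap = 0.95), "overlap")
})

test_that("DFA recovers the classical exponents for white and pink noise", {
  white <- vapply(1:20, function(i) {
    x <- genSignal("white", 500, 300, seed = 8000 + i)
    fl <- dfaFluctuation(x, 500)
    dfaExponent(fl$sizes, fl$F)$alpha
  }, numeric(1))
  expect_lt(abs(mean(white) - 0.5), 0.05)

  pink <- vapply(1:20, function(i) {
    x <- genSignal("pink", 500, 300, seed = 8100 + i)
    fl <- dfaFluctuation(x, 500)
    dfaExponent(fl$sizes, fl$F)$alpha
  }, numeric(1))
  expect_lt(abs(mean(pink) - 1), 0.07)
})

test_that("DFA alpha equals H for fractional Gaussian noise", {
  a <- vapply(1:20, function(i) {
    x <- genSignal("fgn", 500, 300, seed = 8200 + i, H = 0.9)
    fl <- dfaFluctuation(x, 500)
    dfaExponent(fl$sizes, fl$F)$alpha
  }, numeric(1))
  expect_lt(abs(mean(a) - 0.9), 0.07)
})

test_that("overlap convention changes the exponent only marginally", {
  diffs <- vapply(1:8, function(i) {
    x <- genSignal("fgn", 250, 120, seed = 300 + i, H = 0.75)
    f0 <- dfaFluctuation(x, 250, overlap = 0)
    f5 <- dfaFluctuation(x, 250, overlap = 0.5)
    abs(dfaExponent(f0$sizes, f0$F)$alpha -
        dfaExponent(f5$sizes, f5$F)$alpha)
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})

test_that("the alpha-LRTC pipeline respects channel structure and length limits", {
  fs <- 250
  rec <- genSignalRecording("white", fs, 40, seed = 77,
                            channels = c("Pz", "O1", "Fz"))
  res <- alphaLrtcPipeline(rec, durationS = 40,
                           calcInterval = c(0.8, 8), fitInterval = c(1, 6))
  expect_s4_class(res, "DFAResult")
  expect_named(dfaExponents(res), c("Pz", "O1", "Fz"))
  expect_true(all(res@fluctuation > 0))
  expect_true(all(diff(res@windowSizes) > 0))

  perm <- c("O1", "Fz", "Pz")
  rec2 <- EEGRecording(signalData(rec)[, perm], fs = fs)
  res2 <- alphaLrtcPipeline(rec2, durationS = 40,
                            calcInterval = c(0.8, 8), fitInterval = c(1, 6))
  expect_equal(unname(dfaExponents(res2)),
               unname(dfaExponents(res)[perm]), tolerance = 1e-12)

  expect_error(alphaLrtcPipeline(rec, durationS = 300), "shorter")
})

test_that("a planted long-range-correlated envelope survives the whole pipeline", {
  a <- vapply(1:6, function(i) {
    rec <- EEGRecording(matrix(genAlphaLrtcChannel(0.85, 500, 300,
                                                   seed = 900 + i),
                               ncol = 1, dimnames = list(NULL, "Pz")),
                        fs = 500)
    mean(dfaExponents(alphaLrtcPipeline(rec)))
  }, numeric(1))
  expect_gt(mean(a), 0.75)
  expect_lt(mean(a), 0.95)
})
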