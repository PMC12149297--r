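test_that("smooth curves score fractal dimension 1", {
  line <- seq(-2, 7, length.out = 5000)
  expect_equal(higuchiFD(line, 64), 1, tolerance = 0.01)
  expect_equal(as.numeric(boxCountingFD(line)), 1, tolerance = 0.05)

  const <- rep(3, 1000)
  bc <- boxCountingFD(const)
  expect_equal(as.numeric(bc), 1)
  expect_true(attr(bc, "degenerate"))
  hc <- higuchiFD(const, 16)
  expect_equal(as.numeric(hc), 1)
})

test_that("Higuchi agrees with a direct-summation oracle and hits the white-noise limit", {
  fds <- vapply(1:10, function(i)
    higuchiFD(genSignal("white", 500, 15, seed = 40 + i), 126), numeric(1))
  expect_lt(abs(mean(fds) - 2), 0.05)

  x <- genSignal("white", 250, 4, seed = 99)
  expect_equal(higuchiFD(x, 20), unname(naiveHiguchi(x, 20)),
               tolerance = 1e-10)
  xf <- genSignal("fbm", 250, 4, seed = 98, H = 0.6)
  expect_equal(higuchiFD(xf, 50), unname(naiveHiguchi(xf, 50)),
               tolerance = 1e-10)

  expect_error(higuchiFD(x, 1), "kmax")
  expect_error(higuchiFD(rnorm(50), 30), "too short")
})

test_that("fractional Brownian motion recovers FD = 2 - H", {
  h05 <- vapply(1:20, function(i)
    higuchiFD(genSignal("fbm", 500, 15, seed = 500 + i, H = 0.5), 126),
    numeric(1))
  expect_lt(abs(mean(h05) - 1.5), 0.1)
  b05 <- vapply(1:20, function(i)
    as.numeric(boxCountingFD(genSignal("fbm", 500, 15, seed = 500 + i,
                                       H = 0.5))), numeric(1))
  expect_lt(abs(mean(b05) - 1.5), 0.1)
  h07 <- vapply(1:20, function(i)
    higuchiFD(genSignal("fbm", 500, 15, seed = 700 + i, H = 0.7), 126),
    numeric(1))
  expect_lt(abs(mean(h07) - 1.3), 0.1)
})

test_that("both estimators are amplitude invariant", {
  x <- genSignal("fbm", 250, 5, seed = 13, H = 0.4)
  expect_equal(higuchiFD(7 * x, 40), higuchiFD(x, 40), tolerance = 1e-12)
  expect_equal(as.numeric(boxCountingFD(-3 * x)),
               as.numeric(boxCountingFD(x)), tolerance = 1e-12)
})

test_that("complexity ordering: white noise > fBm(0.5) > sinusoid", {
  fs <- 250
  tt <- seq(0, 8 - 1 / fs, by = 1 / fs)
  wins <- vapply(1:10, function(i) {
    w <- higuchiFD(genSignal("white", fs, 8, seed = i), 64)
    f <- higuchiFD(genSignal("fbm", fs, 8, seed = i + 100, H = 0.5), 64)
    s <- higuchiFD(sin(2 * pi * 3 * tt + i), 64)
    w > f && f > s
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("Higuchi H-sweep recovers slope 1 against 2 - H", {
  hs <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  est <- vapply(hs, function(H) mean(vapply(1:8, function(i)
    higuchiFD(genSignal("fbm", 500, 15, seed = round(1e4 * H) + i, H = H),
              126), numeric(1))), numeric(1))
  slope <- coef(lm(est ~ I(2 - hs)))[2]
  expect_lt(abs(unname(slope) - 1), 0.2)
})

test_that("windowed HFD follows the truncation rule and matches whole-epoch values", {
  fs <- 500
  ep <- makeEpoch(matrix(genSignal("white", fs, 15.5, seed = 3), ncol = 1),
                  fs)
  tab <- windowedHFD(ep, kmax = 126, windowS = 1)
  expect_equal(tab$n_windows, 15)
  expect_equal(tab$method, "higuchi")

  ep15 <- makeEpoch(matrix(genSignal("white", fs, 15, seed = 4), ncol = 1),
                    fs)
  whole <- higuchiFD(signalData(ep15)[, 1], 126)
  expect_equal(windowedHFD(ep15, 126, 1)$fd, whole, tolerance = 0.05)

  expect_error(windowedHFD(ep15, kmax = 126, windowS = 0.4), "too short")
})

test_that("kmax scan selects by the median rule and reports group curves", {
  expect_equal(eegrc:::kmaxMedianRule(c(2L, 10L, 50L), c(1.9, 1.7, 1.3)),
               10L)
  expect_equal(eegrc:::kmaxMedianRule(c(2L, 6L, 10L, 20L, 80L),
                                      c(2.0, 1.9, 1.75, 1.6, 1.2)), 10L)
  expect_equal(eegrc:::kmaxMedianRule(7L, 1.5), 7L)

  eps <- lapply(1:4, function(i)
    makeEpoch(vapply(1:2, function(j)
      genSignal("fbm", 128, 4, seed = 10 * i + j, H = 0.5),
      numeric(512)), fs = 128, subjectID = paste0("s", i),
      group = c("control", "AD")[1 + i %% 2]))
  sc <- kmaxScan(eps, c(4L, 8L, 16L, 32L), windowS = 4)
  expect_s4_class(sc, "KmaxScan")
  expect_true(selectedKmax(sc) %in% c(4L, 8L, 16L, 32L))
  expect_setequal(unique(sc@groupCurves$group), c("control", "AD"))
  expect_equal(nrow(sc@groupCurves), 8)
  # selection consistent with the rule applied to the subject means
  expect_equal(selectedKmax(sc),
               eegrc:::kmaxMedianRule(sc@kmaxValues,
                                      colMeans(sc@subjectMeans)))
  expect_error(kmaxScan(eps, integer(0)), "empty")
  expect_error(kmaxScan(eps[1], c(4L, 8L)), "2 subjects")
})
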