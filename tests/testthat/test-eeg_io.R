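test_that("standard montage has the fixed regional structure", {
  m <- standardMontage()
  expect_length(rostralChannels(m), 7)
  expect_length(caudalChannels(m), 7)
  expect_setequal(rostralChannels(m),
                  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"))
  expect_setequal(caudalChannels(m),
                  c("T5", "P3", "Pz", "P4", "T6", "O1", "O2"))
  expect_length(intersect(rostralChannels(m), caudalChannels(m)), 0)
  expect_setequal(
    setdiff(montageChannels(m),
            c(rostralChannels(m), caudalChannels(m))),
    c("T3", "C3", "Cz", "C4", "T4"))
})

test_that("channel labels canonicalize across dialects", {
  expect_equal(canonicalChannelNames(c("FP1", "fz", "P7", "p8", "T7")),
               c("Fp1", "Fz", "T5", "T6", "T3"))
  expect_equal(canonicalChannelNames(c("EEG Fp1-REF", "ECG", "A1")),
               c("Fp1", NA, NA))
})

test_that("matrix_tsv round trip is exact and keeps metadata", {
  rec <- whiteRecording(fs = 250, durationS = 2, seed = 11,
                        group = "AD", subjectID = "sub-xyz")
  path <- file.path(withr::local_tempdir(), "rec.tsv")
  writeRecording(rec, path, "matrix_tsv")
  back <- readRecording(path)
  expect_identical(signalData(back), signalData(rec))
  expect_identical(samplingRate(back), 250)
  expect_identical(subjectID(back), "sub-xyz")
  expect_identical(groupLabel(back), "AD")
})

test_that("EDF round trip agrees within the 16-bit quantization step", {
  rec <- whiteRecording(fs = 128, durationS = 3, seed = 3,
                        group = "FTD", subjectID = "sub-e")
  path <- file.path(withr::local_tempdir(), "rec.edf")
  writeRecording(rec, path, "edf", physRange = 1000)
  back <- readRecording(path)
  step <- 2000 / (2^16 - 1)
  expect_lt(max(abs(signalData(back) - signalData(rec))), step)
  expect_identical(samplingRate(back), 128)
  expect_identical(subjectID(back), "sub-e")
  expect_identical(groupLabel(back), "FTD")

  zero <- EEGRecording(matrix(0, 256, 19,
                              dimnames = list(NULL, montageChannels(standardMontage()))),
                       fs = 128)
  zpath <- file.path(withr::local_tempdir(), "zero.edf")
  writeRecording(zero, zpath, "edf")
  expect_true(all(abs(signalData(readRecording(zpath))) < step))
})

test_that("reader drops extra channels with a warning, errors on missing", {
  dir <- withr::local_tempdir()
  rec <- whiteRecording(fs = 100, durationS = 1, seed = 5)
  tab <- as.data.frame(signalData(rec))
  tab$ECG <- rnorm(nrow(tab))
  path <- file.path(dir, "extra.tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = 100, subject_id = "s", group = "unknown"),
                       file.path(dir, "extra.json"), auto_unbox = TRUE)
  expect_warning(back <- readRecording(path), "ECG")
  expect_identical(channelNames(back), montageChannels(standardMontage()))

  tab$ECG <- NULL
  tab$O2 <- NULL
  path2 <- file.path(dir, "missing.tsv")
  write.table(tab, path2, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = 100, subject_id = "s", group = "unknown"),
                       file.path(dir, "missing.json"), auto_unbox = TRUE)
  expect_error(readRecording(path2), "O2")
})

test_that("writer rejects non-montage channel sets; reader rejects .set", {
  bad <- EEGRecording(matrix(rnorm(100), 50, 2,
                             dimnames = list(NULL, c("Fp1", "Fp2"))),
                      fs = 50)
  expect_error(writeRecording(bad, tempfile(fileext = ".tsv")),
               "19 canonical")
  f <- tempfile(fileext = ".set")
  writeLines("not a set file", f)
  expect_error(readRecording(f, "eeglab_set"), "not supported")
})

test_that("regional mean over rostral, caudal and midline equals 19-channel mean", {
  m <- standardMontage()
  set.seed(42)
  for (i in 1:5) {
    v <- setNames(rnorm(19), montageChannels(m))
    rs <- regionalSummary(v, m)
    mid <- setdiff(montageChannels(m),
                   c(rostralChannels(m), caudalChannels(m)))
    expect_equal((7 * rs$rostral_mean + 7 * rs$caudal_mean +
                    5 * mean(v[mid])) / 19,
                 rs$global_mean, tolerance = 1e-12)
  }
})

test_that("batch reader walks flat and BIDS-style layouts", {
  dir <- withr::local_tempdir()
  sub1 <- file.path(dir, "sub-001", "eeg")
  dir.create(sub1, recursive = TRUE)
  writeRecording(whiteRecording(100, 1, 1, subjectID = "sub-001"),
                 file.path(sub1, "sub-001_eeg.tsv"), "matrix_tsv")
  writeRecording(whiteRecording(100, 1, 2, subjectID = "sub-002"),
                 file.path(dir, "sub-002.tsv"), "matrix_tsv")
  recs <- readCohortDir(dir)
  expect_setequal(names(recs), c("sub-001", "sub-002"))
})
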