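# Canonical 19-channel 10-20 set, in conventional rostral-to-caudal order.
CANONICAL_19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                  "T3", "C3", "Cz", "C4", "T4",
                  "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

ROSTRAL_7 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")
CAUDAL_7 <- c("T5", "P3", "Pz", "P4", "T6", "O1", "O2")

# dataset-dialect aliases mapped onto the canonical labels
CHANNEL_ALIASES <- c(P7 = "T5", P8 = "T6", T7 = "T3", T8 = "T4")

#' The standard 19-channel 10-20 montage
#'
#' Returns the fixed montage used throughout the package: the 19-channel
#' 10-20 set with the rostral region \{Fp1, Fp2, F7, F3, Fz, F4, F8\} and
#' the caudal region \{T5, P3, Pz, P4, T6, O1, O2\}. The five mid-chain
#' channels T3, C3, Cz, C4, T4 belong to neither region.
#'
#' @return A [Montage-class].
#' @examples
#' m <- standardMontage()
#' rostralChannels(m)
#' @export
standardMontage <- function() {
  new("Montage", all19 = CANONICAL_19, rostral = ROSTRAL_7, caudal = CAUDAL_7)
}

#' Map raw channel labels onto canonical 10-20 names
#'
#' Case-insensitive; strips common "EEG " prefixes and reference suffixes;
#' unifies the T5/P7, T6/P8, T3/T7, T4/T8 naming dialects onto the T labels.
#' Labels that are not 10-20 montage channels map to `NA`.
#'
#' @param labels character vector of raw channel labels.
#' @return character vector of canonical labels (or `NA`), same length.
#' @export
canonicalChannelNames <- function(labels) {
  x <- trimws(labels)
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("-(REF|LE|AVG|A1|A2)$", "", x, ignore.case = TRUE)
  lut <- c(CANONICAL_19, names(CHANNEL_ALIASES))
  names(lut) <- toupper(c(CANONICAL_19, names(CHANNEL_ALIASES)))
  canon <- unname(lut[toupper(x)])
  canon <- ifelse(canon %in% names(CHANNEL_ALIASES),
                  CHANNEL_ALIASES[canon], canon)
  unname(canon)
}

# keep the 19 montage channels in canonical order; warn about extras,
# error about missing channels
conformToMontage <- function(data, labels, path = "<data>") {
  canon <- canonicalChannelNames(labels)
  keep <- !is.na(canon)
  if (any(!keep))
    warning(sprintf("dropping %d non-montage channel(s) in %s: %s",
                    sum(!keep), path,
                    paste(labels[!keep], collapse = ", ")),
            call. = FALSE)
  data <- data[, keep, drop = FALSE]
  canon <- canon[keep]
  if (anyDuplicated(canon))
    stop("duplicate montage channels after canonicalization: ",
         paste(canon[duplicated(canon)], collapse = ", "))
  missing <- setdiff(CANONICAL_19, canon)
  if (length(missing))
    stop(sprintf("montage error in %s: missing required channel(s): %s",
                 path, paste(missing, collapse = ", ")))
  data <- data[, match(CANONICAL_19, canon), drop = FALSE]
  colnames(data) <- CANONICAL_19
  data
}

guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tsv = "matrix_tsv", txt = "matrix_tsv",
         edf = "edf", set = "eeglab_set",
         stop("cannot guess format from extension: ", path))
}

#' Read a multichannel EEG recording
#'
#' Reads one recording and conforms it to the canonical 19-channel 10-20
#' montage: labels are canonicalized (case-insensitive; T5/P7 and T6/P8
#' dialects unified), non-montage channels (e.g. A1/A2, ECG) are dropped
#' with a warning, and a missing montage channel is an error.
#'
#' Supported formats: `matrix_tsv` (header row of channel labels, one
#' column per channel, JSON sidecar `<stem>.json` holding `fs`,
#' `subject_id`, `group`) and 16-bit `edf`. EEGLAB `.set` files are not
#' supported by this reader.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"matrix_tsv"`, `"edf"` or
#'   `"eeglab_set"`.
#' @return An [EEGRecording-class] with the 19 montage channels in
#'   canonical order.
#' @seealso [writeRecording()], [readCohortDir()]
#' @export
readRecording <- function(path, format = c("auto", "matrix_tsv", "edf",
                                           "eeglab_set")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guessFormat(path)
  switch(format,
         matrix_tsv = readMatrixTsv(path),
         edf = readEdf(path),
         eeglab_set = stop("EEGLAB .set reading is not supported; ",
                           "export to EDF or matrix_tsv instead"))
}

#' Write a multichannel EEG recording
#'
#' Writes an [EEGRecording-class] as `matrix_tsv` (plus a JSON sidecar with
#' sampling rate and subject metadata) or as a 16-bit EDF with a +/-1000 uV
#' physical range. The recording must carry exactly the 19 canonical
#' montage channels.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @param format `"matrix_tsv"` or `"edf"`.
#' @param physRange symmetric physical range for EDF quantization, uV.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("matrix_tsv", "edf"),
                           physRange = 1000) {
  format <- match.arg(format)
  stopifnot(is(rec, "EEGRecording"))
  validObject(rec)
  if (!identical(sort(channelNames(rec)), sort(CANONICAL_19)))
    stop("writeRecording requires exactly the 19 canonical montage channels")
  switch(format,
         matrix_tsv = writeMatrixTsv(rec, path),
         edf = writeEdf(rec, path, physRange = physRange))
  invisible(path)
}

sidecarPath <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

readMatrixTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  meta <- list(fs = NA, subject_id = NA_character_, group = "unknown")
  sc <- sidecarPath(path)
  if (file.exists(sc)) {
    got <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta[names(got)] <- got
  }
  if (!is.finite(as.numeric(meta$fs)))
    stop("matrix_tsv sidecar missing sampling rate 'fs': ", sc)
  data <- conformToMontage(as.matrix(tab), colnames(tab), path)
  EEGRecording(data, fs = as.numeric(meta$fs),
               subjectID = as.character(meta$subject_id),
               group = as.character(meta$group))
}

writeMatrixTsv <- function(rec, path) {
  x <- signalData(rec)
  # full double precision so that read(write(x)) is bit-exact
  chr <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(x), collapse = "\t"), con)
  writeLines(apply(chr, 1, paste, collapse = "\t"), con)
  jsonlite::write_json(list(fs = samplingRate(rec),
                            subject_id = subjectID(rec),
                            group = groupLabel(rec)),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
}

# --- EDF (European Data Format, 16-bit) ------------------------------------
# Fixed-layout ASCII header (256 + 256*ns bytes) followed by int16
# little-endian data records. One data record per second of signal; a
# trailing partial second is dropped on write.

padField <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

writeEdf <- function(rec, path, physRange = 1000) {
  data <- signalData(rec)
  fs <- samplingRate(rec)
  ns <- ncol(data)
  spr <- as.integer(round(fs))       # samples per 1 s record
  nrec <- nrow(data) %/% spr
  if (nrec < 1) stop("recording shorter than one EDF record (1 s)")
  data <- data[seq_len(nrec * spr), , drop = FALSE]
  physMin <- -abs(physRange); physMax <- abs(physRange)
  digMin <- -32768L; digMax <- 32767L
  scale <- (digMax - digMin) / (physMax - physMin)
  dig <- round((pmin(pmax(data, physMin), physMax) - physMin) * scale) + digMin
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),
    padField(paste(subjectID(rec), groupLabel(rec)), 80),
    padField("eegrc", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 + 256 * ns, 8),
    padField("", 44),
    padField(nrec, 8),
    padField(1, 8),
    padField(ns, 4),
    paste(padField(colnames(data), 16), collapse = ""),
    paste(rep(padField("", 80), ns), collapse = ""),
    paste(rep(padField("uV", 8), ns), collapse = ""),
    paste(rep(padField(physMin, 8), ns), collapse = ""),
    paste(rep(padField(physMax, 8), ns), collapse = ""),
    paste(rep(padField(digMin, 8), ns), collapse = ""),
    paste(rep(padField(digMax, 8), ns), collapse = ""),
    paste(rep(padField("", 80), ns), collapse = ""),
    paste(rep(padField(spr, 8), ns), collapse = ""),
    paste(rep(padField("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(dig[rows, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                    # version
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8)
  hdrBytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # phys dim
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)            # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  seek(con, hdrBytes)
  if (length(unique(spr)) != 1L)
    stop("EDF with per-signal sampling rates is not supported")
  fs <- spr[1] / recDur
  data <- matrix(NA_real_, nrow = nrec * spr[1], ncol = ns)
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     signed = TRUE, endian = "little")
    rows <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[rows, ] <- matrix(block, ncol = ns)
  }
  for (i in seq_len(ns))
    data[, i] <- physMin[i] +
      (data[, i] - digMin[i]) * (physMax[i] - physMin[i]) /
      (digMax[i] - digMin[i])
  parts <- strsplit(patient, "[ ]+")[[1]]
  grp <- if (length(parts) >= 2 && parts[length(parts)] %in% GROUP_LEVELS)
    parts[length(parts)] else "unknown"
  sid <- if (length(parts) >= 1) parts[1] else NA_character_
  data <- conformToMontage(data, labels, path)
  EEGRecording(data, fs = fs, subjectID = sid, group = grp)
}

#' Read every recording in a directory
#'
#' Accepts either a flat directory of `.tsv`/`.edf` files or a BIDS-style
#' layout (`sub-XXX/eeg/...`). Files that fail to read are skipped with a
#' warning.
#'
#' @param dir directory path.
#' @param format passed to [readRecording()].
#' @return named list of [EEGRecording-class] objects.
#' @export
readCohortDir <- function(dir, format = "auto") {
  files <- list.files(dir, pattern = "\\.(tsv|edf)$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no .tsv or .edf recordings under ", dir)
  recs <- list()
  for (f in files) {
    rec <- tryCatch(readRecording(f, format),
                    error = function(e) {
                      warning("skipping ", f, ": ", conditionMessage(e),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(rec)) {
      nm <- if (!is.na(subjectID(rec))) subjectID(rec)
            else tools::file_path_sans_ext(basename(f))
      recs[[nm]] <- rec
    }
  }
  recs
}
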