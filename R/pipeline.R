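#' Default pipeline configuration
#'
#' All defaults mirror the primary-dataset settings: 500 Hz recordings,
#' 1-45 Hz broadband filter, common average reference, 15 s epochs with a
#' 100 uV artifact guard, Higuchi kmax 126 with 1 s windows, and alpha-band
#' DFA over 300 s (10 log-spaced windows spanning 0.8-30 s, 50% overlap,
#' fit 2-25 s). The `dataset2_128hz` dialect switches kmax to 32 and
#' disables DFA (8 s recordings are far too short for it).
#'
#' @param dialect `"dataset1_500hz"`, `"dataset2_128hz"` or `"custom"`.
#' @return nested list of settings, suitable for [runPipeline()] or for
#'   serializing to YAML.
#' @export
defaultPipelineConfig <- function(dialect = c("dataset1_500hz",
                                              "dataset2_128hz", "custom")) {
  dialect <- match.arg(dialect)
  cfg <- list(
    dialect = dialect,
    input = list(dir = NULL, format = "auto"),
    filter = list(low_hz = 1, high_hz = 45),
    epoch = list(duration_s = 15, amp_limit_uv = 100),
    hfd = list(kmax = 126, window_s = 1),
    dfa = list(enabled = TRUE, duration_s = 300, low_hz = 8, high_hz = 13,
               calc_interval = c(0.8, 30), n_windows = 10, overlap = 0.5,
               fit_interval = c(2, 25), trim_s = 1),
    stats = list(alpha = 0.05),
    output_dir = NULL,
    seed = 1
  )
  if (dialect == "dataset2_128hz") {
    cfg$hfd$kmax <- 32
    cfg$dfa$enabled <- FALSE
  }
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [defaultPipelineConfig()] (the
#' file's `dialect` key picks the base defaults).
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- defaultPipelineConfig(
    if (is.null(user$dialect)) "dataset1_500hz" else user$dialect)
  mergeList <- function(a, b) {
    for (k in names(b)) {
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]]))
        mergeList(a[[k]], b[[k]]) else b[[k]]
    }
    a
  }
  validatePipelineConfig(mergeList(base, user))
}

#' Validate a pipeline configuration
#'
#' Checks structural invariants; in particular the `dataset2_128hz`
#' dialect forbids DFA (its recordings are too short).
#'
#' @param config configuration list.
#' @return the config, invisibly, or an error.
#' @export
validatePipelineConfig <- function(config) {
  if (identical(config$dialect, "dataset2_128hz") &&
      isTRUE(config$dfa$enabled))
    stop("config error: DFA cannot be enabled for the dataset2_128hz ",
         "dialect (recordings too short)")
  if (config$filter$low_hz >= config$filter$high_hz)
    stop("config error: filter.low_hz must be below filter.high_hz")
  invisible(config)
}

#' Filter a cohort by processability rules
#'
#' Drops subjects for which no artifact-free epoch of the required
#' duration exists, returning the retained recordings and an exclusion
#' log. Subjects that are merely too short for DFA are *not* dropped here;
#' stage-wise eligibility is handled inside [runPipeline()].
#'
#' @param recordings named list of [EEGRecording-class] objects.
#' @param rules list with `epoch_duration_s` and `amp_limit_uv`.
#' @return list with `kept` (recordings) and `log` (data.frame:
#'   `subject_id`, `excluded`, `reason`).
#' @export
excludeSubjects <- function(recordings,
                            rules = list(epoch_duration_s = 15,
                                         amp_limit_uv = 100)) {
  logRows <- list()
  kept <- list()
  for (nm in names(recordings)) {
    rec <- recordings[[nm]]
    err <- tryCatch({
      selectEpoch(rec, rules$epoch_duration_s, rules$amp_limit_uv)
      NULL
    }, error = function(e) conditionMessage(e))
    if (is.null(err)) {
      kept[[nm]] <- rec
      logRows[[nm]] <- data.frame(subject_id = nm, excluded = FALSE,
                                  reason = NA_character_)
    } else {
      logRows[[nm]] <- data.frame(subject_id = nm, excluded = TRUE,
                                  reason = err)
    }
  }
  if (!length(kept)) stop("all subjects excluded")
  list(kept = kept, log = do.call(rbind, c(logRows,
                                           make.row.names = FALSE)))
}

# regional summaries for one per-subject x channel metric table
summariseRegional <- function(tab, valueCol, metric, groupsOf) {
  out <- lapply(split(tab, tab$subject_id), function(d) {
    v <- stats::setNames(d[[valueCol]], d$channel)
    cbind(regionalSummary(v, metric = metric,
                          subjectId = d$subject_id[1]),
          group = groupsOf[[d$subject_id[1]]])
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

# ANOVA + Tukey + normality screen for one regional column of a summary
regionStats <- function(summ, metric, region) {
  v <- summ[[region]]
  g <- summ$group
  keep <- g %in% names(which(table(g) >= 2))
  v <- v[keep]; g <- g[keep]
  if (length(unique(g)) < 2) return(NULL)
  an <- oneWayAnova(v, g)
  tk <- tukeyHsd(v, g)
  cbind(metric = metric, region = region,
        data.frame(F = an$statistic, df1 = an$df1, df2 = an$df2,
                   p_anova = an$p, r2 = an$effect),
        tk[, c("group1", "group2", "t", "df", "d", "p_tukey")],
        row.names = NULL)
}

#' Run the full analysis pipeline
#'
#' Orchestrates, for every subject: broadband filtering, common average
#' re-referencing, epoch selection, relative band power, box-counting and
#' Higuchi fractal dimension, alpha-band DFA (when enabled and the
#' recording is long enough), regional summaries, and the between-group
#' statistics (ANOVA + Tukey per metric and region, MANOVA over the band
#' profile with one band dropped because relative powers sum to one, and
#' FDR-corrected channelwise t maps). Failures are logged per subject and
#' the pipeline continues over the remaining subjects.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or a
#'   YAML file path.
#' @param recordings named list of [EEGRecording-class] objects; when
#'   `NULL`, recordings are read from `config$input$dir`.
#' @return list with elements `bandPower`, `complexity`, `dfa`,
#'   `regional`, `anova`, `manova`, `tmaps`, `manifest`. When
#'   `config$output_dir` is set, the tables are also written as TSV with a
#'   JSON manifest (including per-file checksums).
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        recordings = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validatePipelineConfig(config)
  if (is.null(recordings)) {
    if (is.null(config$input$dir))
      stop("no recordings given and no input.dir configured")
    recordings <- readCohortDir(config$input$dir, config$input$format)
  }
  if (is.null(names(recordings)))
    names(recordings) <- vapply(recordings, subjectID, "")

  scr <- excludeSubjects(recordings,
                         list(epoch_duration_s = config$epoch$duration_s,
                              amp_limit_uv = config$epoch$amp_limit_uv))
  recordings <- scr$kept
  subjLog <- scr$log
  groupsOf <- lapply(recordings, groupLabel)

  bandRows <- list(); boxRows <- list(); hfdRows <- list()
  dfaRows <- list()
  procLog <- list()
  for (nm in names(recordings)) {
    rec <- recordings[[nm]]
    res <- tryCatch({
      filt <- bandpass(rec, config$filter$low_hz, config$filter$high_hz,
                       kind = "broadband")
      filt <- commonAverageReference(filt)
      ep <- selectEpoch(filt, config$epoch$duration_s,
                        config$epoch$amp_limit_uv)
      bandRows[[nm]] <- relativeBandPower(ep)
      boxRows[[nm]] <- boxCountingTable(ep)
      hfdRows[[nm]] <- windowedHFD(ep, kmax = config$hfd$kmax,
                                   windowS = config$hfd$window_s)
      dfaNote <- "dfa disabled"
      if (isTRUE(config$dfa$enabled)) {
        if (duration(filt) >= config$dfa$duration_s) {
          dr <- alphaLrtcPipeline(
            filt, durationS = config$dfa$duration_s,
            lowHz = config$dfa$low_hz, highHz = config$dfa$high_hz,
            calcInterval = config$dfa$calc_interval,
            nWindows = config$dfa$n_windows,
            overlap = config$dfa$overlap,
            fitInterval = config$dfa$fit_interval,
            trimS = config$dfa$trim_s)
          dfaRows[[nm]] <- data.frame(
            subject_id = nm, channel = names(dfaExponents(dr)),
            alpha = unname(dfaExponents(dr)),
            residual = unname(dr@residuals), row.names = NULL)
          dfaNote <- "ok"
        } else {
          dfaNote <- sprintf("excluded from DFA: %.1f s < %g s",
                             duration(filt), config$dfa$duration_s)
        }
      }
      data.frame(subject_id = nm, status = "ok",
                 epoch_offset_s = ep@sourceOffset, dfa = dfaNote)
    }, error = function(e)
      data.frame(subject_id = nm, status = "failed",
                 epoch_offset_s = NA_real_, dfa = conditionMessage(e)))
    procLog[[nm]] <- res
  }
  procLog <- do.call(rbind, c(procLog, make.row.names = FALSE))

  bandPower <- do.call(rbind, c(bandRows, make.row.names = FALSE))
  complexity <- rbind(do.call(rbind, c(boxRows, make.row.names = FALSE))[,
                        c("subject_id", "channel", "method", "fd")],
                      do.call(rbind, c(hfdRows, make.row.names = FALSE))[,
                        c("subject_id", "channel", "method", "fd")])
  dfaTab <- if (length(dfaRows))
    do.call(rbind, c(dfaRows, make.row.names = FALSE)) else NULL

  # regional summaries
  bandNames <- canonicalBands()$name
  regional <- list()
  for (b in bandNames) {
    tb <- bandPower[, c("subject_id", "channel", b)]
    regional[[paste0("rel_", b)]] <-
      summariseRegional(tb, b, paste0("rel_", b), groupsOf)
  }
  for (m in c("box_counting", "higuchi")) {
    tb <- complexity[complexity$method == m, ]
    regional[[paste0("fd_", m)]] <-
      summariseRegional(tb, "fd", paste0("fd_", m), groupsOf)
  }
  if (!is.null(dfaTab))
    regional$dfa_alpha <- summariseRegional(dfaTab, "alpha", "dfa_alpha",
                                            groupsOf)
  regionalTab <- do.call(rbind, c(regional, make.row.names = FALSE))

  # group statistics over regional summaries
  anovaRows <- list()
  for (m in names(regional)) {
    for (rg in c("global_mean", "rostral_mean", "caudal_mean",
                 "asymmetry")) {
      st <- regionStats(regional[[m]], m, rg)
      if (!is.null(st)) anovaRows[[paste(m, rg)]] <- st
    }
  }
  anovaTab <- if (length(anovaRows))
    do.call(rbind, c(anovaRows, make.row.names = FALSE)) else NULL

  # normality screen (reported diagnostic only; tests are not switched)
  normRows <- list()
  for (m in names(regional)) {
    summ <- regional[[m]]
    for (gr in unique(summ$group)) {
      x <- summ$global_mean[summ$group == gr]
      if (length(x) >= 8)
        normRows[[paste(m, gr)]] <-
          cbind(metric = m, group = gr, dagostinoPearson(x))
    }
  }
  normTab <- if (length(normRows))
    do.call(rbind, c(normRows, make.row.names = FALSE)) else NULL

  # MANOVA over the global band profile; one band dropped because the
  # five relative powers sum to one (singular otherwise)
  manovaTab <- NULL
  gm <- sapply(bandNames, function(b)
    regional[[paste0("rel_", b)]]$global_mean)
  gGroups <- regional[[paste0("rel_", bandNames[1])]]$group
  if (length(unique(gGroups)) >= 2 &&
      nrow(gm) > (length(bandNames) - 1) + length(unique(gGroups))) {
    manovaTab <- tryCatch(
      pillaiManova(gm[, setdiff(bandNames, "gamma")], gGroups),
      error = function(e) NULL)
  }

  # channelwise t maps, one FDR family per metric x comparison
  tmaps <- list()
  grpTab <- table(unlist(groupsOf))
  glevels <- names(grpTab[grpTab >= 2])
  if (length(glevels) >= 2) {
    pairsMat <- utils::combn(glevels, 2)
    metricMats <- list()
    for (b in bandNames)
      metricMats[[paste0("rel_", b)]] <-
        metricMatrix(bandPower, b, groupsOf)
    for (m in c("box_counting", "higuchi"))
      metricMats[[paste0("fd_", m)]] <-
        metricMatrix(complexity[complexity$method == m, ], "fd", groupsOf)
    if (!is.null(dfaTab))
      metricMats$dfa_alpha <- metricMatrix(dfaTab, "alpha", groupsOf)
    for (m in names(metricMats)) {
      mm <- metricMats[[m]]
      for (k in seq_len(ncol(pairsMat))) {
        cmp <- pairsMat[, k]
        tm <- channelwiseTMap(mm$values, mm$groups, cmp,
                              alphaLevel = config$stats$alpha)
        tm$metric <- m
        tmaps[[paste(m, cmp[1], cmp[2], sep = ":")]] <- tm
      }
    }
  }
  tmapTab <- if (length(tmaps))
    do.call(rbind, c(tmaps, make.row.names = FALSE)) else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("eegrc")),
    config = config,
    subjects = subjLog,
    processing = procLog,
    n_subjects = length(recordings)
  )
  result <- list(bandPower = bandPower, complexity = complexity,
                 dfa = dfaTab, regional = regionalTab, anova = anovaTab,
                 manova = manovaTab, tmaps = tmapTab, normality = normTab,
                 manifest = manifest)
  if (!is.null(config$output_dir))
    writePipelineOutputs(result, config$output_dir)
  result
}

# per-subject x channel metric table -> subjects x channels matrix
metricMatrix <- function(tab, valueCol, groupsOf) {
  wide <- stats::reshape(tab[, c("subject_id", "channel", valueCol)],
                         idvar = "subject_id", timevar = "channel",
                         direction = "wide")
  rn <- wide$subject_id
  m <- as.matrix(wide[, -1])
  colnames(m) <- sub(paste0("^", valueCol, "\\."), "", colnames(m))
  rownames(m) <- rn
  list(values = m, groups = unlist(groupsOf[rn]))
}

# write result tables as TSV plus a JSON manifest with checksums
writePipelineOutputs <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in c("bandPower", "complexity", "dfa", "regional", "anova",
               "manova", "tmaps", "normality")) {
    tab <- result[[nm]]
    if (is.null(tab)) next
    f <- file.path(outDir, paste0(nm, ".tsv"))
    utils::write.table(tab, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, f)
  }
  manifest <- result$manifest
  manifest$files <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(files)
}
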