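.TIME_FMT <- "%Y-%m-%dT%H:%M:%S"

.parseTime <- function(x) {
  as.POSIXct(x, format = .TIME_FMT, tz = "UTC")
}

.formatTime <- function(t) {
  ifelse(is.na(t), "", format(t, .TIME_FMT, tz = "UTC"))
}

#' Read and write epoch-count CSV files
#'
#' The epoch schema is `subject_id,timestamp,count` with ISO-8601
#' timestamps. On reading, each subject's series is validated: strictly
#' increasing, gap-free timestamps at a constant epoch length, and
#' non-negative counts; violations raise an error citing the offending data
#' line (empty count fields are read as device-off `NA` epochs).
#'
#' @param path CSV file path.
#' @return `readEpochs()`: named list of [EpochSeries-class], one per
#'   subject. `writeEpochs()`: the path, invisibly.
#' @export
readEpochs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "count")
  if (!all(need %in% names(df))) {
    stop("epoch CSV must have header: ", paste(need, collapse = ","))
  }
  ts <- .parseTime(df$timestamp)
  badTs <- which(is.na(ts) & !is.na(df$timestamp))
  if (length(badTs)) {
    stop("malformed timestamp at line ", badTs[1] + 1L, ": '",
         df$timestamp[badTs[1]], "'")
  }
  badCount <- which(!is.na(df$count) & df$count < 0)
  if (length(badCount)) {
    stop("negative count at line ", badCount[1] + 1L)
  }
  df$.line <- seq_len(nrow(df)) + 1L
  out <- lapply(split(df, df$subject_id), function(d) {
    tsub <- .parseTime(d$timestamp)
    if (is.unsorted(tsub, strictly = TRUE)) {
      i <- which(diff(as.numeric(tsub)) <= 0)[1]
      stop("non-monotone timestamps for subject ", d$subject_id[1],
           " at line ", d$.line[i + 1L])
    }
    steps <- diff(as.numeric(tsub))
    if (length(steps) && any(steps != steps[1])) {
      i <- which(steps != steps[1])[1]
      stop("gap in epoch series for subject ", d$subject_id[1],
           " at line ", d$.line[i + 1L])
    }
    epochSeries(d$subject_id[1], tsub[1],
                if (length(steps)) steps[1] else 15L, d$count)
  })
  out[order(names(out))]
}

#' @rdname readEpochs
#' @param epochs Named list of [EpochSeries-class].
#' @export
writeEpochs <- function(epochs, path) {
  rows <- lapply(epochs, function(es) {
    data.frame(subject_id = subjectID(es),
               timestamp = .formatTime(epochTimes(es)),
               count = counts(es))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write the sleep-diary CSV
#'
#' Schema: `subject_id,night,bed_time,wake_time,nap_start,nap_end,
#' device_off_start,device_off_end`; ISO-8601 timestamps, empty fields for
#' absent naps or device-off intervals.
#'
#' @param path CSV file path.
#' @param diary Diary `data.frame` ([simulateSubject()] layout).
#' @return `readDiary()` the diary `data.frame`; `writeDiary()` the path,
#'   invisibly.
#' @export
readDiary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("bed_time", "wake_time", "nap_start", "nap_end",
                "device_off_start", "device_off_end")) {
    df[[col]] <- .parseTime(df[[col]])
  }
  df
}

#' @rdname readDiary
#' @export
writeDiary <- function(diary, path) {
  out <- diary
  for (col in c("bed_time", "wake_time", "nap_start", "nap_end",
                "device_off_start", "device_off_end")) {
    out[[col]] <- .formatTime(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Score sleep and build the analysis frame for a whole cohort
#'
#' In-memory orchestration of the full pipeline downstream of the epoch
#' data: per subject, aggregate to 60-s epochs, detect nightly rest
#' intervals, score sleep/wake, compute nightly measures and weekly
#' summaries, score naps and RU SATED dimensions; convert raw cognitive
#' scores to T-scores and the two-stage global T-score; assemble the
#' analysis frame.
#'
#' @param epochs Named list of [EpochSeries-class].
#' @param diary Diary `data.frame` covering the same subjects.
#' @param phenotypes Phenotype `data.frame` (covariates, questionnaire
#'   items, `raw_<test>` columns).
#' @param normative Normative table ([defaultNormativeTable()] layout).
#' @param domainMap Test-to-domain map ([defaultDomainMap()]).
#' @param minNights Valid-night inclusion threshold.
#' @param scoring Named list of overrides passed to [scoreSubject()].
#' @return List: `nightly` (all subjects' nightly measures), `summaries`,
#'   `dimensions`, `cognition` (per-domain and global T-scores), `frame`
#'   (the [buildAnalysisFrame()] output), `rests`.
#' @export
processCohort <- function(epochs, diary, phenotypes,
                          normative = defaultNormativeTable(),
                          domainMap = defaultDomainMap(),
                          minNights = 5, scoring = list()) {
  ids <- names(epochs)
  nightlyAll <- list(); summaries <- list(); dims <- list(); rests <- list()
  for (id in ids) {
    dsub <- diary[diary$subject_id == id, , drop = FALSE]
    if (!nrow(dsub)) {
      summaries[[id]] <- cbind(data.frame(subject_id = id),
                               summarizeSubject(data.frame(valid = logical())))
      next
    }
    res <- do.call(scoreSubject, c(list(series = epochs[[id]], diary = dsub),
                                   scoring))
    nightlyAll[[id]] <- cbind(data.frame(subject_id = id), res$nightly)
    summaries[[id]] <- cbind(data.frame(subject_id = id),
                             summarizeSubject(res$nightly, minNights = minNights))
    if (!is.null(res$rests)) {
      rests[[id]] <- cbind(data.frame(subject_id = id), res$rests)
    }
    ph <- phenotypes[phenotypes$subject_id == id, , drop = FALSE]
    if (nrow(ph) && any(res$nightly$valid)) {
      dims[[id]] <- cbind(
        data.frame(subject_id = id),
        dimensionScores(res$nightly, res$naps,
                        ph$isi_satisfaction[1], ph$promis_satisfaction[1])
      )
    }
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  dims <- if (length(dims)) do.call(rbind, dims) else
    data.frame(subject_id = character())
  rownames(dims) <- NULL

  testT <- tScoreTable(phenotypes, normative)
  cognition <- globalT(testT, domainMap)
  frame <- buildAnalysisFrame(summaries, dims, cognition, phenotypes)
  list(
    nightly = do.call(rbind, nightlyAll),
    summaries = summaries, dimensions = dims, cognition = cognition,
    frame = frame,
    rests = if (length(rests)) do.call(rbind, rests) else NULL
  )
}

#' Run the five association analyses on an analysis frame
#'
#' Executes, per HIV stratum (when both strata have at least `minStratum`
#' subjects, otherwise on the pooled frame): rank regression of the
#' traditional measures (average duration, its 7-h-centered absolute
#' deviation, WASO, maintenance efficiency), PLS with VIP, random-forest
#' VIM, median-regression contrasts for the six sleep-health dimensions,
#' rank regression on the total sleep-health score, and the Gaussian-
#' mixture latent-class grouping; plus HIV-interaction tests for the
#' traditional measures on the pooled frame.
#'
#' @param frame Analysis frame ([buildAnalysisFrame()]).
#' @param nTrees,mTry,seed,maxGroups,nBoot Method settings (see [rfFit()],
#'   [lcaFit()]).
#' @param stratifyBy Stratification column (default `"hiv_status"`);
#'   `NULL` disables stratification.
#' @param minStratum Minimum subjects per stratum to stratify (default 30).
#' @return List: `tidy` (`data.frame` of all regression-type rows:
#'   method, stratum, term, estimate, ci_low, ci_high, p, n),
#'   `interactions`, and per-stratum `pls`, `rf`, `lca` objects.
#' @export
runAssociations <- function(frame, nTrees = 1000L, mTry = 15L, seed = 1L,
                            maxGroups = 5L, nBoot = 0L,
                            stratifyBy = "hiv_status", minStratum = 30L) {
  traditional <- c("avg_duration", "avg_waso", "avg_maintenance_efficiency")
  frame$centered_duration <- centeredDuration(frame$avg_duration)

  strata <- list(all = frame)
  if (!is.null(stratifyBy)) {
    sp <- split(frame, frame[[stratifyBy]])
    if (length(sp) == 2L && all(vapply(sp, nrow, integer(1)) >= minStratum)) {
      strata <- stats::setNames(sp, paste0(stratifyBy, "_", names(sp)))
    }
  }
  tidy <- list(); pls <- list(); rf <- list(); lca <- list()
  for (s in names(strata)) {
    fr <- strata[[s]]
    rows <- lapply(c(traditional, "centered_duration"), function(v) {
      rankRegression(fr, v)
    })
    rows <- c(rows, lapply(
      c("satisfaction", "alertness", "timing", "efficiency", "duration",
        "regularity"),
      function(d) {
        tryCatch(
          dimensionRegression(fr, d, nBoot = max(100L, nBoot), seed = seed),
          error = function(e) NULL   # e.g. reference category absent
        )
      }
    ))
    rows <- c(rows, list(totalScoreRegression(fr)))
    tr <- do.call(rbind, rows)
    tr$stratum <- s
    tidy[[s]] <- tr
    pls[[s]] <- plsFit(fr)
    rf[[s]] <- rfFit(fr, nTrees = nTrees, mTry = mTry, seed = seed)
    lca[[s]] <- lcaFit(fr, maxGroups = maxGroups, nBoot = nBoot, seed = seed)
  }
  interactions <- NULL
  if (!is.null(stratifyBy) && length(unique(frame[[stratifyBy]])) == 2L) {
    interactions <- data.frame(
      term = c(traditional, "centered_duration"),
      p = vapply(c(traditional, "centered_duration"),
                 function(v) interactionTest(frame, v, stratum = stratifyBy),
                 numeric(1))
    )
  }
  list(tidy = do.call(rbind, tidy), interactions = interactions,
       pls = pls, rf = rf, lca = lca,
       settings = list(nTrees = nTrees, mTry = mTry, seed = seed,
                       maxGroups = maxGroups, nBoot = nBoot))
}

#' Run the file-based pipeline end to end
#'
#' Chains simulate (optional) -> score-sleep -> measures -> sleep-health ->
#' associate, reading the epoch/diary/phenotype/normative CSVs and writing
#' each stage's output CSV into `outDir` before the next stage starts,
#' followed by a JSON run manifest (configuration snapshot, package
#' version, per-stage row counts, excluded subjects with reasons, seeds).
#' Re-running with the same configuration and inputs reproduces all
#' outputs identically (manifest timestamp aside).
#'
#' @param epochsFile,diaryFile,phenotypeFile,normativeFile Input CSV paths.
#' @param outDir Output directory (created if needed).
#' @param domainMap Test-to-domain map.
#' @param minNights Valid-night inclusion threshold.
#' @param scoring Scoring overrides ([scoreSubject()]).
#' @param nTrees,mTry,seed,maxGroups,nBoot Association settings.
#' @return The manifest, invisibly (a list).
#' @export
runPipeline <- function(epochsFile, diaryFile, phenotypeFile,
                        normativeFile = NULL, outDir,
                        domainMap = defaultDomainMap(), minNights = 5,
                        scoring = list(), nTrees = 1000L, mTry = 15L,
                        seed = 1L, maxGroups = 5L, nBoot = 0L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  epochs <- readEpochs(epochsFile)
  diary <- readDiary(diaryFile)
  phen <- utils::read.csv(phenotypeFile, stringsAsFactors = FALSE)
  norm <- if (is.null(normativeFile)) defaultNormativeTable() else
    utils::read.csv(normativeFile, stringsAsFactors = FALSE)

  missingDiary <- setdiff(names(epochs), unique(diary$subject_id))
  epochs <- epochs[setdiff(names(epochs), missingDiary)]

  res <- processCohort(epochs, diary, phen, norm, domainMap, minNights,
                       scoring)
  utils::write.csv(res$nightly, file.path(outDir, "nightly_measures.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summaries, file.path(outDir, "subject_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(res$dimensions, file.path(outDir, "sleep_dimensions.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cognition, file.path(outDir, "cognitive_tscores.csv"),
                   row.names = FALSE)

  assoc <- runAssociations(res$frame, nTrees = nTrees, mTry = mTry,
                           seed = seed, maxGroups = maxGroups, nBoot = nBoot)
  utils::write.csv(assoc$tidy, file.path(outDir, "association_results.csv"),
                   row.names = FALSE)
  vipRows <- do.call(rbind, lapply(names(assoc$pls), function(s) {
    data.frame(stratum = s, variable = names(assoc$pls[[s]]$vip),
               vip = unname(assoc$pls[[s]]$vip),
               relative_vim = unname(assoc$rf[[s]]$relativeVIM[names(assoc$pls[[s]]$vip)]))
  }))
  utils::write.csv(vipRows, file.path(outDir, "variable_importance.csv"),
                   row.names = FALSE)

  excluded <- attr(res$frame, "excluded")
  if (length(missingDiary)) {
    excluded <- rbind(data.frame(subject_id = missingDiary,
                                 reason = "no_diary_record"), excluded)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("actisleep")),
    created = format(Sys.time(), .TIME_FMT, tz = "UTC"),
    inputs = list(epochs = epochsFile, diary = diaryFile,
                  phenotypes = phenotypeFile,
                  normative = normativeFile %||% "default"),
    settings = list(minNights = minNights, nTrees = nTrees, mTry = mTry,
                    seed = seed, maxGroups = maxGroups, nBoot = nBoot,
                    scoring = scoring),
    rows = list(subjects = length(epochs), nights = nrow(res$nightly),
                included = nrow(res$frame),
                association_rows = nrow(assoc$tidy)),
    excluded = excluded
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated cohort to the pipeline's CSV schemas
#'
#' @param bundle A [CohortBundle-class].
#' @param dir Output directory.
#' @return Named list of the four file paths, invisibly.
#' @export
writeCohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    epochs = file.path(dir, "epochs.csv"),
    diary = file.path(dir, "diary.csv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    normative = file.path(dir, "normative.csv"),
    truth = file.path(dir, "ground_truth.csv")
  )
  writeEpochs(cohortEpochs(bundle), paths$epochs)
  writeDiary(cohortDiary(bundle), paths$diary)
  utils::write.csv(cohortPhenotypes(bundle), paths$phenotypes, row.names = FALSE)
  utils::write.csv(cohortNormative(bundle), paths$normative, row.names = FALSE)
  utils::write.csv(cohortTruth(bundle)$summaries, paths$truth, row.names = FALSE)
  invisible(paths)
}
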