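#' Convert a raw cognitive test score to a T-score
#'
#' `T = 50 + 10 * direction * (raw - mean) / sd` against the matching
#' normative entry; mean 50, SD 10, higher is better. `direction = -1`
#' flips tests where larger raw scores indicate worse performance (e.g.
#' completion times).
#'
#' @param raw Raw test score(s).
#' @param mean,sd Normative mean and SD (SD must be positive).
#' @param direction `+1` (higher raw is better, default) or `-1`.
#' @return Numeric T-score(s).
#' @examples
#' tScore(72, mean = 60, sd = 12)            # 60
#' tScore(72, mean = 60, sd = 12, direction = -1)  # 40
#' @export
tScore <- function(raw, mean, sd, direction = 1) {
  if (any(sd <= 0)) stop("normative sd must be positive")
  if (!all(direction %in% c(-1, 1))) stop("direction must be +1 or -1")
  50 + 10 * direction * (raw - mean) / sd
}

#' T-scores for a table of raw test scores against a normative table
#'
#' Looks up each test's normative entry (optionally within strata columns
#' shared by `raw` and `norm`) and applies [tScore()].
#'
#' @param raw `data.frame` with a `subject_id` column and one `raw_<test_id>`
#'   column per test.
#' @param norm Normative `data.frame`: `test_id`, `mean`, `sd`, `direction`,
#'   plus optional stratum columns (e.g. `age_band`, `gender`) which, when
#'   present, must also appear in `raw`.
#' @return `data.frame`: `subject_id` plus one T-score column per test
#'   (named by `test_id`).
#' @export
tScoreTable <- function(raw, norm) {
  strata <- setdiff(names(norm), c("test_id", "mean", "sd", "direction"))
  out <- data.frame(subject_id = raw$subject_id)
  for (tid in unique(norm$test_id)) {
    col <- paste0("raw_", tid)
    if (!col %in% names(raw)) stop("missing raw score column: ", col)
    entries <- norm[norm$test_id == tid, , drop = FALSE]
    if (!length(strata)) {
      e <- entries[1L, ]
      out[[tid]] <- tScore(raw[[col]], e$mean, e$sd, e$direction)
    } else {
      key <- do.call(paste, c(raw[strata], sep = "\r"))
      ekey <- do.call(paste, c(entries[strata], sep = "\r"))
      m <- match(key, ekey)
      if (anyNA(m)) {
        stop("no normative stratum for test ", tid, " matching: ",
             paste(unique(key[is.na(m)]), collapse = "; "))
      }
      out[[tid]] <- tScore(raw[[col]], entries$mean[m], entries$sd[m],
                           entries$direction[m])
    }
  }
  out
}

#' Two-stage global cognitive T-score
#'
#' Individual test T-scores are averaged (unweighted) within each of the
#' five cognitive domains, and the domain T-scores are averaged into the
#' global T-score, so a domain with many tests does not dominate.
#'
#' @param testT Named numeric vector of per-test T-scores, or a
#'   `data.frame` from [tScoreTable()] (one row per subject, `subject_id`
#'   column).
#' @param domainMap Named character vector mapping every test to exactly
#'   one domain (e.g. [defaultDomainMap()]).
#' @return For a vector: list with `test`, `domain` (named numeric) and
#'   `global`. For a data.frame: `data.frame` with `subject_id`, one column
#'   per domain, and `global_t`.
#' @examples
#' globalT(c(a = 40, b = 60, c = 50), c(a = "d1", b = "d1", c = "d2"))$global
#' @export
globalT <- function(testT, domainMap) {
  if (is.data.frame(testT)) {
    tests <- setdiff(names(testT), "subject_id")
    .checkDomainMap(tests, domainMap)
    doms <- unique(domainMap[tests])
    out <- data.frame(subject_id = testT$subject_id)
    for (d in doms) {
      cols <- tests[domainMap[tests] == d]
      out[[d]] <- rowMeans(testT[, cols, drop = FALSE])
    }
    out$global_t <- rowMeans(out[doms])
    return(out)
  }
  .checkDomainMap(names(testT), domainMap)
  domain <- tapply(testT, domainMap[names(testT)], mean)
  list(test = testT, domain = domain, global = mean(domain))
}

.checkDomainMap <- function(tests, domainMap) {
  unmapped <- setdiff(tests, names(domainMap))
  if (length(unmapped)) {
    stop("test(s) not mapped to a domain: ", paste(unmapped, collapse = ", "))
  }
  empty <- setdiff(unique(domainMap), domainMap[tests])
  if (length(empty)) {
    stop("empty domain(s): ", paste(empty, collapse = ", "))
  }
}
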