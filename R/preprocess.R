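TARGET_LEVELS <- c("face", "eyes", "arrows")
CONGRUENCY_LEVELS <- c("congruent", "incongruent")

#' Read a trial-level CSV/TSV of spatial-Stroop data
#'
#' Reads a delimited text file into the validated trial-record layout
#' used throughout the package.  Category labels for target type and
#' congruency are normalized case-insensitively against their closed
#' vocabularies; a `responded` column is derived from RT presence when
#' absent.
#'
#' @param path file path (`.csv` or `.tsv`; delimiter inferred from the
#'   extension, comma by default).
#' @param column_map optional named character vector mapping the roles
#'   `study_id`, `participant_id`, `target_type`, `congruency`, `rt_ms`,
#'   `accuracy`, `responded` to the file's column names.  Unmapped roles
#'   default to their own name.
#' @return data frame of validated trial records.
#' @export
read_trials <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  roles <- c("study_id", "participant_id", "target_type", "congruency",
             "rt_ms", "accuracy", "responded")
  map <- stats::setNames(roles, roles)
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  required <- setdiff(roles, "responded")
  missing <- required[!map[required] %in% names(raw)]
  if (length(missing))
    stop("input lacks required column(s): ",
         paste(sprintf("%s (role %s)", map[missing], missing), collapse = ", "),
         call. = FALSE)

  out <- data.frame(study_id = as.character(raw[[map["study_id"]]]),
                    participant_id = as.character(raw[[map["participant_id"]]]),
                    target_type = tolower(trimws(as.character(raw[[map["target_type"]]]))),
                    congruency = tolower(trimws(as.character(raw[[map["congruency"]]]))),
                    rt_ms = as.numeric(raw[[map["rt_ms"]]]),
                    accuracy = as_flag(raw[[map["accuracy"]]]),
                    stringsAsFactors = FALSE)
  out$responded <- if (map["responded"] %in% names(raw))
    as_flag(raw[[map["responded"]]]) else !is.na(out$rt_ms)

  validate_trials(out)
}

# coerce 0/1, "true"/"false", logicals to logical
as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

validate_trials <- function(trials) {
  bad <- which(!trials$target_type %in% TARGET_LEVELS)
  if (length(bad))
    stop(sprintf("unknown target_type label '%s' at row %d",
                 trials$target_type[bad[1]], bad[1]), call. = FALSE)
  bad <- which(!trials$congruency %in% CONGRUENCY_LEVELS)
  if (length(bad))
    stop(sprintf("unknown congruency label '%s' at row %d",
                 trials$congruency[bad[1]], bad[1]), call. = FALSE)
  bad <- which(trials$responded & (is.na(trials$rt_ms) | trials$rt_ms <= 0))
  if (length(bad))
    stop(sprintf("responded trial with missing/non-positive RT at row %d",
                 bad[1]), call. = FALSE)
  bad <- which(!trials$responded & !is.na(trials$rt_ms))
  if (length(bad))
    stop(sprintf("non-responded trial carries an RT at row %d", bad[1]),
         call. = FALSE)
  trials
}

#' Exclude participants with a high non-response rate
#'
#' Removes every trial of participants whose proportion of
#' non-responses meets or exceeds `threshold`.  Pooled multi-study data
#' occasionally contain a participant who stopped responding (rates
#' around 64% have been observed); the default cutoff of one half flags
#' such cases while leaving ordinary lapse rates untouched.
#'
#' @param trials trial data frame.
#' @param threshold proportion in (0, 1]; participants with
#'   non-response proportion `>= threshold` are dropped.
#' @return list with `trials` (filtered) and `excluded` (data frame of
#'   study/participant/non-response proportion for dropped participants).
#' @export
exclude_nonresponders <- function(trials, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  key <- interaction(trials$study_id, trials$participant_id, drop = TRUE)
  prop_nr <- tapply(!trials$responded, key, mean)
  drop_keys <- names(prop_nr)[prop_nr >= threshold]
  excluded <- do.call(rbind, lapply(drop_keys, function(k) {
    i <- which(key == k)[1]
    data.frame(study_id = trials$study_id[i],
               participant_id = trials$participant_id[i],
               nonresponse_prop = unname(prop_nr[k]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(excluded))
    excluded <- data.frame(study_id = character(), participant_id = character(),
                           nonresponse_prop = numeric(), stringsAsFactors = FALSE)
  list(trials = trials[!key %in% drop_keys, , drop = FALSE],
       excluded = excluded)
}

#' Trim reaction times to an analysis window
#'
#' In `"trimmed"` mode keeps responded trials whose RT lies in the
#' closed interval `[low, high]`; the canonical window excludes RTs
#' shorter than 200 ms and longer than 1300 ms, so boundary values are
#' retained.  In `"nontrimmed"` mode keeps all responded trials
#' regardless of RT, the robustness variant.
#'
#' @param trials trial data frame.
#' @param low,high window bounds in ms (`low < high`).
#' @param mode `"trimmed"` or `"nontrimmed"`.
#' @return filtered trial data frame.
#' @export
trim_rts <- function(trials, low = 200, high = 1300,
                     mode = c("trimmed", "nontrimmed")) {
  mode <- match.arg(mode)
  stopifnot(low < high)
  keep <- trials$responded
  if (mode == "trimmed")
    keep <- keep & !is.na(trials$rt_ms) &
      trials$rt_ms >= low & trials$rt_ms <= high
  trials[keep, , drop = FALSE]
}

#' Keep correct trials only
#'
#' @param trials trial data frame.
#' @return rows with `accuracy == TRUE`; warns if the result is empty.
#' @export
filter_correct <- function(trials) {
  out <- trials[trials$accuracy, , drop = FALSE]
  if (nrow(out) == 0L && nrow(trials) > 0L)
    warning("no correct trials remain after accuracy filtering",
            call. = FALSE)
  out
}

#' Account for trials removed at each preprocessing stage
#'
#' Tallies, per study x target type x congruency cell, the number and
#' proportion of input trials removed by each successive rule and the
#' retained count.  Counts are conserved: removed plus retained equals
#' the input count in every cell.
#'
#' @param before the input trial table.
#' @param after_stages named list of successively filtered tables, in
#'   application order (each a row-subset of its predecessor).
#' @return data frame with one row per cell x rule (rules named from
#'   `after_stages`, plus `"retained"`), columns `n` and `proportion`
#'   (of that cell's input trials).
#' @export
removal_report <- function(before, after_stages) {
  stopifnot(is.list(after_stages), length(after_stages) >= 1,
            !is.null(names(after_stages)))
  cell_counts <- function(d) {
    if (nrow(d) == 0L)
      return(stats::setNames(integer(0), character(0)))
    tab <- table(paste(d$study_id, d$target_type, d$congruency, sep = "\r"))
    stats::setNames(as.integer(tab), names(tab))
  }
  n0 <- cell_counts(before)
  counts <- lapply(after_stages, cell_counts)
  prev <- n0
  for (i in seq_along(counts)) {
    cur <- stats::setNames(integer(length(n0)), names(n0))
    cur[names(counts[[i]])] <- counts[[i]]
    extra <- setdiff(names(counts[[i]]), names(n0))
    if (length(extra) || any(cur > prev))
      stop("stage '", names(after_stages)[i],
           "' is not a subset of the preceding stage", call. = FALSE)
    counts[[i]] <- cur
    prev <- cur
  }

  cells <- names(n0)
  parts <- do.call(rbind, strsplit(cells, "\r", fixed = TRUE))
  rows <- list()
  prev <- n0
  for (i in seq_along(counts)) {
    removed <- prev - counts[[i]]
    rows[[length(rows) + 1L]] <-
      data.frame(study_id = parts[, 1], target_type = parts[, 2],
                 congruency = parts[, 3], rule = names(after_stages)[i],
                 n = as.integer(removed), proportion = removed / n0,
                 stringsAsFactors = FALSE)
    prev <- counts[[i]]
  }
  rows[[length(rows) + 1L]] <-
    data.frame(study_id = parts[, 1], target_type = parts[, 2],
               congruency = parts[, 3], rule = "retained",
               n = as.integer(prev), proportion = prev / n0,
               stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the full preprocessing pipeline
#'
#' Fixed order: exclude high-non-response participants, keep responded
#' trials, trim the RT window (or not, in the non-trimmed variant),
#' keep correct trials.  The pipeline is idempotent: re-applying it to
#' its own output changes nothing.
#'
#' @param trials trial data frame.
#' @param low,high,mode passed to [trim_rts()].
#' @param nonresponse_threshold passed to [exclude_nonresponders()].
#' @return list with `trials` (the analysis set), `report` (a
#'   [removal_report()]), and `excluded` (participant exclusions).
#' @export
preprocess_trials <- function(trials, low = 200, high = 1300,
                              mode = c("trimmed", "nontrimmed"),
                              nonresponse_threshold = 0.5) {
  mode <- match.arg(mode)
  excl <- exclude_nonresponders(trials, nonresponse_threshold)
  responded <- excl$trials[excl$trials$responded, , drop = FALSE]
  trimmed <- trim_rts(responded, low, high, mode)
  correct <- filter_correct(trimmed)
  report <- removal_report(trials, list(participant_exclusion = excl$trials,
                                        nonresponse = responded,
                                        rt_window = trimmed,
                                        incorrect = correct))
  list(trials = correct, report = report, excluded = excl$excluded)
}
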