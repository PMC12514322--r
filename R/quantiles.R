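#' Hyndman-Fan Type-8 sample quantile
#'
#' The median-unbiased interpolation estimator: with order statistics
#' `x_(1) <= ... <= x_(n)` and plotting position
#' `h = (n + 1/3) p + 1/3` (clamped to `[1, n]`), returns
#' `x_(floor(h)) + (h - floor(h)) (x_(floor(h)+1) - x_(floor(h)))`.
#' This matches `stats::quantile(type = 8)` and is the estimator
#' recommended for reaction-time distribution work.
#'
#' @param x numeric sample (need not be sorted; `NA`s are an error).
#' @param probs probabilities in (0, 1).
#' @return numeric vector of quantiles, one per probability.
#' @examples
#' hf_quantile8(c(1, 2, 3, 4), 0.5)        # 2.5
#' hf_quantile8(c(10, 20, 30, 40, 50), .3) # 19.33
#' @export
hf_quantile8 <- function(x, probs) {
  if (length(x) == 0L) stop("empty sample", call. = FALSE)
  if (anyNA(x)) stop("sample contains NA", call. = FALSE)
  if (any(probs <= 0 | probs >= 1))
    stop("'probs' must lie strictly in (0, 1)", call. = FALSE)
  xs <- sort(x)
  n <- length(xs)
  h <- pmin(pmax((n + 1 / 3) * probs + 1 / 3, 1), n)
  lo <- floor(h)
  hi <- pmin(lo + 1, n)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

#' Build the per-participant CDF dataset
#'
#' Computes Hyndman-Fan Type-8 RT quantiles at the supplied
#' probabilities for every participant x target type x congruency cell
#' of a preprocessed trial table.  The default five-point grid
#' (.1, .3, .5, .7, .9) centres on the median; quartile- and
#' decile-style variants are obtained by changing `probs`.  Cells with
#' fewer than `min_trials` retained trials are skipped with a warning:
#' extreme quantiles are unstable in tiny samples.
#'
#' @param trials preprocessed trial data frame.
#' @param probs strictly increasing probabilities in (0, 1).
#' @param min_trials minimum retained trials per cell.
#' @return data frame of quantile cells: `study_id`, `participant_id`,
#'   `target_type`, `congruency`, `prob`, `qq` (factor over `probs`),
#'   `q_rt` (ms).
#' @export
build_cdf_dataset <- function(trials, probs = c(.1, .3, .5, .7, .9),
                              min_trials = 10) {
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  if (any(diff(probs) <= 0) || any(probs <= 0 | probs >= 1))
    stop("'probs' must be strictly increasing within (0, 1)", call. = FALSE)
  key <- interaction(trials$study_id, trials$participant_id,
                     trials$target_type, trials$congruency,
                     drop = TRUE, sep = "\r")
  groups <- split(trials$rt_ms, key)
  small <- vapply(groups, length, integer(1)) < min_trials
  if (any(small))
    warning(sprintf("%d cell(s) below the %d-trial minimum were skipped",
                    sum(small), min_trials), call. = FALSE)
  groups <- groups[!small]
  if (!length(groups)) stop("no cell meets the minimum trial count",
                            call. = FALSE)
  ids <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  np <- length(probs)
  out <- data.frame(study_id = rep(ids[, 1], each = np),
                    participant_id = rep(ids[, 2], each = np),
                    target_type = rep(ids[, 3], each = np),
                    congruency = rep(ids[, 4], each = np),
                    prob = rep(probs, length(groups)),
                    q_rt = unlist(lapply(groups, hf_quantile8, probs = probs),
                                  use.names = FALSE),
                    stringsAsFactors = FALSE)
  out$qq <- factor(out$prob, levels = probs)
  rownames(out) <- NULL
  out[c("study_id", "participant_id", "target_type", "congruency",
        "prob", "qq", "q_rt")]
}

#' Build the delta dataset from a CDF dataset
#'
#' For every participant x target type x probability with both
#' congruency conditions present, computes the delta function value
#' `delta = q_rt(incongruent) - q_rt(congruent)` (so a reversed
#' congruency effect -- faster incongruent responses -- is negative)
#' and the delta-plot abscissa `mean_rt`, the mean of the two parent
#' quantiles.  Keys missing one congruency are dropped with a warning.
#'
#' @param cdf a [build_cdf_dataset()] result.
#' @return data frame of delta cells: `study_id`, `participant_id`,
#'   `target_type`, `prob`, `qq`, `delta`, `mean_rt`.
#' @export
build_delta_dataset <- function(cdf) {
  con <- cdf[cdf$congruency == "congruent", ]
  inc <- cdf[cdf$congruency == "incongruent", ]
  keys <- c("study_id", "participant_id", "target_type", "prob")
  m <- merge(con[c(keys, "q_rt")], inc[c(keys, "q_rt")],
             by = keys, suffixes = c("_con", "_inc"))
  n_drop <- (nrow(con) - nrow(m)) + (nrow(inc) - nrow(m))
  if (n_drop > 0)
    warning(sprintf("%d quantile cell(s) lacking the paired congruency were dropped",
                    n_drop), call. = FALSE)
  out <- data.frame(m[keys],
                    delta = m$q_rt_inc - m$q_rt_con,
                    mean_rt = (m$q_rt_inc + m$q_rt_con) / 2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$study_id, out$participant_id, out$target_type,
                   out$prob), ]
  out$qq <- factor(out$prob, levels = sort(unique(out$prob)))
  rownames(out) <- NULL
  out[c("study_id", "participant_id", "target_type", "prob", "qq",
        "delta", "mean_rt")]
}

#' Vincentize: average participant-level quantiles (or deltas)
#'
#' Group-level distribution summaries by quantile averaging: the
#' arithmetic mean of participant-level values at each probability,
#' within the grouping given by `by`.
#'
#' @param cells a CDF or delta dataset (must contain `prob` and either
#'   `q_rt` or `delta`; `q_rt` wins if both are present).
#' @param by character vector of grouping columns (e.g.
#'   `"target_type"`, or `c("target_type", "congruency")`).
#' @param value column to average; default picks `q_rt` else `delta`.
#' @return data frame of group x prob means in column `mean_value`,
#'   with the number of averaged cells in `n`.
#' @export
vincentize <- function(cells, by = "target_type", value = NULL) {
  if (is.null(value))
    value <- if ("q_rt" %in% names(cells)) "q_rt" else "delta"
  stopifnot(value %in% names(cells), all(by %in% names(cells)),
            "prob" %in% names(cells))
  f <- stats::as.formula(paste(value, "~",
                               paste(c(by, "prob"), collapse = " + ")))
  agg <- stats::aggregate(f, data = cells, FUN = mean)
  n <- stats::aggregate(f, data = cells, FUN = length)
  names(agg)[names(agg) == value] <- "mean_value"
  agg$n <- n[[value]]
  agg[order(interaction(agg[by], drop = TRUE), agg$prob), , drop = FALSE]
}
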