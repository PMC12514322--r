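#' Default ex-Gaussian baselines and shift profiles by target type
#'
#' The packaged defaults sketch a multi-study spatial-Stroop cohort:
#' arrow targets are faster overall than social targets (face/eyes) by
#' roughly 100 ms, arrows carry a flat positive congruency effect
#' (standard congruency effect, SCE), and social targets carry a
#' reversed effect (RCE) that is null at the fastest percentile and
#' grows, then saturates, toward the slow tail.
#'
#' @return named list of parameter lists / profiles.
#' @keywords internal
default_baselines <- function() {
  list(face   = list(mu = 460, sigma = 45, tau = 140),
       eyes   = list(mu = 460, sigma = 45, tau = 140),
       arrows = list(mu = 380, sigma = 40, tau = 110))
}

#' @rdname default_baselines
#' @keywords internal
default_profiles <- function(baseline = default_baselines()) {
  # social profiles solve delta(.1) = 0 with a negative, saturating shape
  list(face   = delta_profile(9.650, -100.0, 35.0, baseline$face),
       eyes   = delta_profile(7.225,  -75.0, 27.5, baseline$eyes),
       arrows = delta_profile(31.000,    0.0,  0.0, baseline$arrows))
}

#' Configuration for the synthetic multi-study cohort generator
#'
#' Bundles and validates every generator parameter: design sizes, target
#' types, per-target ex-Gaussian baselines and ground-truth
#' [delta_profile()]s, additive study- and participant-level offsets,
#' and the rates of the three trial-level nuisance processes (incorrect
#' responses, non-responses, out-of-range contaminant RTs).
#'
#' @param n_studies number of studies (>= 1).
#' @param participants_per_study participants in each study (>= 1).
#' @param trials_per_cell trials per target x congruency cell (>= 1).
#' @param target_types character subset of `c("face", "eyes", "arrows")`
#'   presented in every study.
#' @param baseline named list (one entry per target type) of ex-Gaussian
#'   parameter lists `list(mu, sigma, tau)` in ms.
#' @param profile named list (one entry per target type) of
#'   [delta_profile()] objects, or `list(a, b, c)` coefficient lists to
#'   be validated against that target's baseline.
#' @param study_sd SD (ms) of the study-level additive shift.
#' @param participant_sd SD (ms) of the participant-level additive shift.
#' @param error_rate probability a responded trial is incorrect.
#' @param nonresponse_rate probability a trial has no response.
#' @param contamination list `(rate, low, high)`: with probability
#'   `rate` a responded trial's RT is replaced by a uniform draw outside
#'   the canonical 200--1300 ms window, from `[low, 200)` or
#'   `(1300, high]` with equal odds.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_studies = 11,
                       participants_per_study = 64,
                       trials_per_cell = 80,
                       target_types = c("face", "eyes", "arrows"),
                       baseline = default_baselines(),
                       profile = NULL,
                       study_sd = 30,
                       participant_sd = 40,
                       error_rate = 0.06,
                       nonresponse_rate = 0.02,
                       contamination = list(rate = 0.01, low = 50, high = 2500),
                       seed = NULL) {
  target_types <- match.arg(target_types, c("face", "eyes", "arrows"),
                            several.ok = TRUE)
  counts <- c(n_studies = n_studies,
              participants_per_study = participants_per_study,
              trials_per_cell = trials_per_cell)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("design counts must be integers >= 1", call. = FALSE)
  if (study_sd < 0 || participant_sd < 0)
    stop("offset SDs must be >= 0", call. = FALSE)
  rates <- c(error_rate, nonresponse_rate, contamination$rate)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (contamination$rate > 0 &&
      (contamination$low >= 200 || contamination$high <= 1300))
    stop("contamination range must lie outside [200, 1300] ms", call. = FALSE)

  baseline <- lapply(baseline, as.list)
  missing_b <- setdiff(target_types, names(baseline))
  if (length(missing_b))
    stop("no baseline for target type(s): ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  for (tt in target_types) check_exg(baseline[[tt]]$mu, baseline[[tt]]$sigma,
                                     baseline[[tt]]$tau)

  if (is.null(profile)) profile <- default_profiles(baseline = baseline)
  missing_p <- setdiff(target_types, names(profile))
  if (length(missing_p))
    stop("no delta profile for target type(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  profile <- profile[names(profile)]
  for (tt in target_types) {
    if (!inherits(profile[[tt]], "delta_profile")) {
      pp <- as.list(profile[[tt]])
      profile[[tt]] <- delta_profile(pp$a, pp$b,
                                     if (is.null(pp$c)) 0 else pp$c,
                                     baseline = baseline[[tt]])
    }
  }
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(length(seed) == 1L, !is.na(seed))
  }

  structure(list(n_studies = as.integer(n_studies),
                 participants_per_study = as.integer(participants_per_study),
                 trials_per_cell = as.integer(trials_per_cell),
                 target_types = target_types,
                 baseline = baseline[target_types],
                 profile = profile[target_types],
                 study_sd = study_sd,
                 participant_sd = participant_sd,
                 error_rate = error_rate,
                 nonresponse_rate = nonresponse_rate,
                 contamination = contamination,
                 seed = seed),
            class = "sim_config")
}

#' @export
#' @method print sim_config
print.sim_config <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d studies x %d participants, %d trials/cell\n",
              x$n_studies, x$participants_per_study, x$trials_per_cell))
  cat("targets:", paste(x$target_types, collapse = ", "), "\n")
  cat(sprintf("offsets: study SD %g ms, participant SD %g ms; error %.1f%%, non-response %.1f%%, contamination %.1f%%\n",
              x$study_sd, x$participant_sd, 100 * x$error_rate,
              100 * x$nonresponse_rate, 100 * x$contamination$rate))
  if (!is.null(x$seed)) cat("seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate one participant's trials for a single target type
#'
#' Congruent RTs are drawn from the target's ex-Gaussian baseline plus
#' the supplied additive offset; incongruent RTs apply the profile's
#' percentile-indexed transform `g(x) = x + delta(F(x))` to a fresh
#' baseline draw before offsetting.  Because `g` is strictly increasing
#' (validated at profile construction) the population q-quantile of the
#' incongruent RTs equals `Q_cong(q) + delta(q)` exactly, and the
#' additive offset cancels from the quantile difference.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param baseline ex-Gaussian parameter list `list(mu, sigma, tau)`.
#' @param profile a [delta_profile()].
#' @param trials_per_cell trials per congruency condition.
#' @param offset additive shift (ms), e.g. study + participant effects.
#' @return data frame with columns `congruency`, `rt_ms`
#'   (`2 * trials_per_cell` rows).
#' @export
simulate_participant <- function(baseline, profile, trials_per_cell,
                                 offset = 0) {
  stopifnot(inherits(profile, "delta_profile"), trials_per_cell >= 1)
  baseline <- as.list(baseline)
  xc <- rexgauss(trials_per_cell, baseline$mu, baseline$sigma, baseline$tau)
  xi <- rexgauss(trials_per_cell, baseline$mu, baseline$sigma, baseline$tau)
  xi <- xi + delta_fun(profile)(pexgauss(xi, baseline$mu, baseline$sigma,
                                         baseline$tau))
  data.frame(congruency = rep(c("congruent", "incongruent"),
                              each = trials_per_cell),
             rt_ms = c(xc, xi) + offset,
             stringsAsFactors = FALSE)
}

#' Simulate a multi-study spatial-Stroop cohort
#'
#' Generates one trial-level row per trial for every study x participant
#' x target type x congruency cell of the design in `config`, then
#' overlays the nuisance processes: incorrect responses (flat rate),
#' non-responses (RT set to missing, `responded = FALSE`) and uniform
#' out-of-range contaminant RTs.  Study and participant additive offsets
#' are drawn once per unit.  Identical `config` (including `seed`)
#' yields an identical table.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `study_id`, `participant_id`,
#'   `target_type`, `congruency`, `rt_ms`, `accuracy`, `responded`.
#' @examples
#' cfg <- sim_config(n_studies = 2, participants_per_study = 3,
#'                   trials_per_cell = 10, target_types = c("face", "arrows"),
#'                   error_rate = 0, nonresponse_rate = 0,
#'                   contamination = list(rate = 0, low = 50, high = 2500),
#'                   seed = 1)
#' trials <- simulate_cohort(cfg)
#' nrow(trials)  # 2 * 3 * 2 * 2 * 10
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
  }

  pieces <- vector("list",
                   config$n_studies * config$participants_per_study *
                     length(config$target_types))
  k <- 0L
  for (s in seq_len(config$n_studies)) {
    study_off <- stats::rnorm(1, 0, config$study_sd)
    sid <- sprintf("study%02d", s)
    for (p in seq_len(config$participants_per_study)) {
      part_off <- stats::rnorm(1, 0, config$participant_sd)
      pid <- sprintf("p%03d", p)
      for (tt in config$target_types) {
        k <- k + 1L
        tr <- simulate_participant(config$baseline[[tt]],
                                   config$profile[[tt]],
                                   config$trials_per_cell,
                                   offset = study_off + part_off)
        tr$study_id <- sid
        tr$participant_id <- pid
        tr$target_type <- tt
        pieces[[k]] <- tr
      }
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[c("study_id", "participant_id", "target_type",
               "congruency", "rt_ms")]
  n <- nrow(out)

  # trial-level nuisance processes, one uniform stream each (fixed order)
  contam <- stats::runif(n) < config$contamination$rate
  if (any(contam)) {
    side_low <- stats::runif(n) < 0.5
    low_draw <- stats::runif(n, config$contamination$low, 200)
    high_draw <- stats::runif(n, 1300, config$contamination$high)
    out$rt_ms[contam] <- ifelse(side_low[contam], low_draw[contam],
                                high_draw[contam])
  }
  out$accuracy <- stats::runif(n) >= config$error_rate
  nonresp <- stats::runif(n) < config$nonresponse_rate
  out$responded <- !nonresp
  out$rt_ms[nonresp] <- NA_real_
  out$accuracy[nonresp] <- FALSE
  rownames(out) <- NULL
  out
}
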