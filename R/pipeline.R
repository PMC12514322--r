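#' Full distributional delta-plot analysis
#'
#' The package's front door: preprocesses a trial table, builds the
#' CDF and delta datasets by Hyndman-Fan Type-8 quantile estimation,
#' fits the three mixed models (RT, delta, polynomial trend) with the
#' study-nested random structure, and computes the contrast layer --
#' EMMs by target and congruency, Tukey pairwise contrasts,
#' Bonferroni-adjusted delta-vs-zero tests per quantile, and the
#' per-target trend coefficients with their pairwise differences.
#'
#' @param trials trial data frame (from [read_trials()] or
#'   [simulate_cohort()]).
#' @param probs quantile probability grid.
#' @param low,high,mode,nonresponse_threshold preprocessing settings;
#'   see [preprocess_trials()].
#' @param min_trials minimum retained trials per quantile cell.
#' @param df_method denominator-df method (`"satterthwaite"` or
#'   `"kenward-roger"`).
#' @param alpha significance level for the stepwise reduction.
#' @param stepwise if `TRUE`, the RT and delta models start from the
#'   full factorial fixed structure and are reduced by backward
#'   elimination; if `FALSE` (default) the canonical
#'   two-way-interaction structures are fitted directly.  The trend
#'   model is never reduced.
#' @return object of class `stroop_dist` with the datasets, fits,
#'   ANOVA tables, EMM grids, contrast tables and trend results.
#'   Methods: `print`, `summary`, `plot` (delta or CDF plot).
#' @examples
#' \donttest{
#' cfg <- sim_config(n_studies = 3, participants_per_study = 8,
#'                   trials_per_cell = 40,
#'                   target_types = c("face", "arrows"), seed = 7)
#' fit <- delta_analysis(simulate_cohort(cfg))
#' print(fit)
#' }
#' @export
delta_analysis <- function(trials, probs = c(.1, .3, .5, .7, .9),
                           low = 200, high = 1300,
                           mode = c("trimmed", "nontrimmed"),
                           nonresponse_threshold = 0.5, min_trials = 10,
                           df_method = c("satterthwaite", "kenward-roger"),
                           alpha = 0.05, stepwise = FALSE) {
  mode <- match.arg(mode)
  df_method <- match.arg(df_method)
  pre <- preprocess_trials(trials, low = low, high = high, mode = mode,
                           nonresponse_threshold = nonresponse_threshold)
  cdf <- build_cdf_dataset(pre$trials, probs = probs,
                           min_trials = min_trials)
  delta <- build_delta_dataset(cdf)

  multi_target <- length(unique(cdf$target_type)) > 1
  rt_fixed <- c("congruency", "qq", "congruency:qq")
  if (multi_target)
    rt_fixed <- c("target_type", rt_fixed, "target_type:congruency",
                  "target_type:qq")
  rt_random <- c("study_id:participant_id",
                 if (multi_target) "study_id:target_type",
                 "study_id:target_type:congruency:qq")
  rt_spec <- model_spec("q_rt", sort_terms(rt_fixed), rt_random)
  d_fixed <- c("qq", if (multi_target) c("target_type", "target_type:qq"))
  d_random <- c("study_id:participant_id",
                if (multi_target) "study_id:target_type",
                "study_id:target_type:qq")
  d_spec <- model_spec("delta", sort_terms(d_fixed), d_random)

  if (stepwise) {
    rt_step <- stepwise_reduce(cdf, full_factorial_spec(rt_spec),
                               alpha = alpha, df_method = df_method)
    rt_fit <- rt_step$fit; rt_spec <- rt_step$spec
    d_step <- stepwise_reduce(delta, full_factorial_spec(d_spec),
                              alpha = alpha, df_method = df_method)
    delta_fit <- d_step$fit; d_spec <- d_step$spec
    step_log <- list(rt = rt_step$log, delta = d_step$log)
  } else {
    rt_fit <- fit_lmm(cdf, rt_spec, df_method = df_method)
    delta_fit <- fit_lmm(delta, d_spec, df_method = df_method)
    step_log <- NULL
  }
  trend_fit <- fit_trend_model(delta, df_method = df_method)

  tc_factors <- if (multi_target) c("target_type", "congruency") else "congruency"
  emm_rt_tc <- emm(rt_fit, tc_factors)
  emm_rt_q <- emm(rt_fit, c(if (multi_target) "target_type", "qq"))
  emm_delta_t <- if (multi_target) emm(delta_fit, "target_type") else NULL
  emm_delta_q <- emm(delta_fit, c(if (multi_target) "target_type", "qq"))

  congr_by_target <- pairwise_tukey(emm_rt_tc, fit = rt_fit,
                                    by = if (multi_target) "target_type")
  target_by_congr <- if (multi_target)
    pairwise_tukey(emm_rt_tc, fit = rt_fit, by = "congruency")
  delta_vs_zero <- contrasts_vs_zero(emm_delta_q, fit = delta_fit,
                                     by = if (multi_target) "target_type")
  trends <- compare_trends(trend_fit)

  structure(list(call = match.call(),
                 probs = probs,
                 settings = list(low = low, high = high, mode = mode,
                                 nonresponse_threshold = nonresponse_threshold,
                                 min_trials = min_trials,
                                 df_method = df_method, alpha = alpha,
                                 stepwise = stepwise),
                 trials = pre$trials, removal_report = pre$report,
                 excluded = pre$excluded,
                 cdf = cdf, delta = delta,
                 rt_fit = rt_fit, delta_fit = delta_fit,
                 trend_fit = trend_fit,
                 rt_anova = anova_table(rt_fit),
                 delta_anova = anova_table(delta_fit),
                 emm_rt = as.data.frame(emm_rt_tc),
                 emm_rt_quantile = as.data.frame(emm_rt_q),
                 emm_delta = if (multi_target) as.data.frame(emm_delta_t),
                 emm_delta_quantile = as.data.frame(emm_delta_q),
                 congruency_contrasts = congr_by_target,
                 target_contrasts = target_by_congr,
                 delta_vs_zero = delta_vs_zero,
                 trends = trends,
                 step_log = step_log),
            class = "stroop_dist")
}

# expand a spec to the full factorial of its factors (stepwise start)
full_factorial_spec <- function(spec) {
  mains <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  ff <- unlist(lapply(seq_along(mains), function(k)
    utils::combn(mains, k, paste, collapse = ":", simplify = FALSE)))
  model_spec(spec$response, ff, spec$random)
}

sort_terms <- function(terms) {
  ord <- vapply(strsplit(terms, ":", fixed = TRUE), length, integer(1))
  terms[order(ord, seq_along(terms))]
}

#' @export
#' @method print stroop_dist
print.stroop_dist <- function(x, ...) {
  cat("Distributional delta-plot analysis\n")
  cat(sprintf("  %d trials retained, %d participants, %d studies; probs: %s\n",
              nrow(x$trials),
              nlevels(interaction(x$trials$study_id,
                                  x$trials$participant_id, drop = TRUE)),
              length(unique(x$trials$study_id)),
              paste(x$probs, collapse = ", ")))
  cat(sprintf("  df method: %s; window: [%g, %g] ms (%s)\n",
              x$settings$df_method, x$settings$low, x$settings$high,
              x$settings$mode))
  cat("\nDelta-model ANOVA:\n")
  print(x$delta_anova, digits = 4)
  if (!is.null(x$emm_delta)) {
    cat("\nEMM-delta by target type (ms):\n")
    print(x$emm_delta, digits = 3)
  }
  cat("\nTrend coefficients:\n")
  print(x$trends$coefficients, digits = 4)
  invisible(x)
}

#' @export
#' @method summary stroop_dist
summary.stroop_dist <- function(object, ...) {
  cat("RT-model ANOVA:\n"); print(object$rt_anova, digits = 4)
  cat("\nDelta-model ANOVA:\n"); print(object$delta_anova, digits = 4)
  cat("\nDelta vs zero by quantile:\n")
  print(object$delta_vs_zero, digits = 3)
  cat("\nTrends:\n"); print(object$trends)
  invisible(object)
}

#' @export
plot.stroop_dist <- function(x, type = c("delta", "cdf"), file = NULL, ...) {
  type <- match.arg(type)
  if (type == "delta") plot_delta(x, file = file, ...)
  else plot_cdf(x, file = file, ...)
}

open_device <- function(file) {
  if (grepl("\\.svg$", file, ignore.case = TRUE))
    grDevices::svg(file, width = 7, height = 5)
  else grDevices::png(file, width = 1400, height = 1000, res = 200)
}

target_palette <- function(levels) {
  pal <- c(face = "#D55E00", eyes = "#0072B2", arrows = "#009E73")
  out <- pal[levels]
  out[is.na(out)] <- grDevices::palette()[seq_len(sum(is.na(out)))]
  stats::setNames(out, levels)
}

#' Delta plot of estimated marginal means
#'
#' One polyline per target type: EMM-delta (ordinate) against EMM-RT
#' (abscissa, averaged over congruency) by quantile, with 95% CI bars
#' on the deltas.  Writes PNG or SVG when `file` is given (format from
#' the extension).
#'
#' @param x a [delta_analysis()] result.
#' @param file optional output path.
#' @return (invisibly) the plotted data frame plus the axis limits
#'   used.
#' @export
plot_delta <- function(x, file = NULL) {
  stopifnot(inherits(x, "stroop_dist"))
  d <- x$emm_delta_quantile
  r <- x$emm_rt_quantile
  if (is.null(d) || nrow(d) == 0L) stop("no delta EMMs to plot",
                                        call. = FALSE)
  if (!"target_type" %in% names(d)) d$target_type <- "all"
  if (!"target_type" %in% names(r)) r$target_type <- "all"
  key <- c("target_type", "qq")
  m <- merge(d, r[c(key, "emmean")], by = key, suffixes = c("", "_rt"))
  m <- m[order(m$target_type, as.numeric(as.character(m$qq))), ]
  xlim <- range(m$emmean_rt)
  ylim <- range(c(m$lower.CL, m$upper.CL, 0))
  draw <- function() {
    graphics::plot(NA, xlim = xlim, ylim = ylim,
                   xlab = "EMM-RT (ms)", ylab = "EMM-delta (ms)",
                   main = "Delta plot by target type")
    graphics::abline(h = 0, lty = 3, col = "grey50")
    tg <- unique(m$target_type)
    cols <- target_palette(tg)
    for (t in tg) {
      mi <- m[m$target_type == t, ]
      graphics::lines(mi$emmean_rt, mi$emmean, col = cols[t], lwd = 2)
      graphics::points(mi$emmean_rt, mi$emmean, col = cols[t], pch = 16)
      graphics::arrows(mi$emmean_rt, mi$lower.CL, mi$emmean_rt,
                       mi$upper.CL, angle = 90, code = 3, length = 0.03,
                       col = cols[t])
    }
    graphics::legend("bottomleft", legend = tg, col = cols[tg], lwd = 2,
                     bty = "n")
  }
  if (!is.null(file)) {
    open_device(file); on.exit(grDevices::dev.off()); draw()
  } else draw()
  invisible(list(data = m, xlim = xlim, ylim = ylim))
}

#' CDF plot of estimated marginal means
#'
#' One polyline per target type x congruency: EMM-RT by quantile, with
#' 95% CI bars.  Quantile estimates are non-decreasing in probability,
#' so every polyline rises.
#'
#' @inheritParams plot_delta
#' @return (invisibly) the plotted data frame plus the axis limits.
#' @export
plot_cdf <- function(x, file = NULL) {
  stopifnot(inherits(x, "stroop_dist"))
  g <- emm(x$rt_fit,
           c(if ("target_type" %in% x$rt_fit$spec$fixed) "target_type",
             "congruency", "qq"))
  m <- as.data.frame(g)
  if (nrow(m) == 0L) stop("no RT EMMs to plot", call. = FALSE)
  if (!"target_type" %in% names(m)) m$target_type <- "all"
  m$prob <- as.numeric(as.character(m$qq))
  m <- m[order(m$target_type, m$congruency, m$prob), ]
  xlim <- range(m$prob)
  ylim <- range(c(m$lower.CL, m$upper.CL))
  draw <- function() {
    graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "probability",
                   ylab = "EMM-RT (ms)", main = "CDF by target and congruency")
    tg <- unique(m$target_type)
    cols <- target_palette(tg)
    for (t in tg) for (cg in unique(m$congruency)) {
      mi <- m[m$target_type == t & m$congruency == cg, ]
      lty <- if (cg == "incongruent") 2 else 1
      graphics::lines(mi$prob, mi$emmean, col = cols[t], lwd = 2, lty = lty)
      graphics::arrows(mi$prob, mi$lower.CL, mi$prob, mi$upper.CL,
                       angle = 90, code = 3, length = 0.03, col = cols[t])
    }
    graphics::legend("topleft",
                     legend = c(tg, "congruent", "incongruent"),
                     col = c(cols[tg], "black", "black"),
                     lty = c(rep(1, length(tg)), 1, 2), lwd = 2, bty = "n")
  }
  if (!is.null(file)) {
    open_device(file); on.exit(grDevices::dev.off()); draw()
  } else draw()
  invisible(list(data = m, xlim = xlim, ylim = ylim))
}
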