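#' Orthogonal polynomial basis
#'
#' Columns of degree 1..`degree`, each orthogonal to the constant and
#' to all lower degrees, and of unit norm (Gram-Schmidt on the powers
#' of `x`, as in `stats::poly`).  On equally spaced `x` these reduce to
#' the classical orthogonal polynomial contrast coefficients.
#'
#' @param x numeric predictor with at least `degree + 1` distinct
#'   values.
#' @param degree polynomial degree.
#' @return a `poly` matrix with the recurrence coefficients attached
#'   (usable for prediction at new `x`).
#' @examples
#' b <- orthopoly_basis(1:5, 2)
#' round(b[, 1], 4)  # proportional to (-2, -1, 0, 1, 2)
#' @export
orthopoly_basis <- function(x, degree) {
  stopifnot(is.numeric(x), degree >= 1)
  if (length(unique(x)) < degree + 1)
    stop("need at least degree + 1 distinct x values", call. = FALSE)
  stats::poly(x, degree = degree)
}

#' Raw-scale polynomial coefficients of an orthogonal-basis fit
#'
#' Converts an intercept plus coefficients on an [orthopoly_basis()]
#' into the coefficients of the equivalent raw polynomial
#' `c0 + c1 x + ... + cd x^d`.  The two parameterizations span the same
#' column space, so fitted values are reproduced exactly.
#'
#' @param x the predictor values the basis was built on.
#' @param intercept intercept of the orthogonal-basis fit.
#' @param beta coefficients on the basis columns (degree 1..d).
#' @return numeric vector `c(c0, c1, ..., cd)`.
#' @export
orthopoly_raw_coefs <- function(x, intercept, beta) {
  degree <- length(beta)
  b <- orthopoly_basis(x, degree)
  yhat <- intercept + as.vector(b %*% beta)
  xm <- stats::model.matrix(~ stats::poly(x, degree, raw = TRUE))
  stats::setNames(qr.coef(qr(xm), yhat), paste0("c", 0:degree))
}

trend_model_spec <- function() {
  structure(list(response = "delta",
                 fixed = c("target_type", "poly(mean_rt, 2)",
                           "target_type:poly(mean_rt, 2)"),
                 random = c("study_id:participant_id",
                            "study_id:target_type",
                            "study_id:target_type:qq")),
            class = "stroop_model_spec")
}

#' Fit the polynomial trend model of the delta plot
#'
#' Mixed model of the delta values on target type crossed with an
#' orthogonal quadratic in the delta-plot abscissa `mean_rt`, with the
#' study-nested random intercepts; the distributional random term
#' groups by study x target x quantile point.  The trend model is
#' fitted as specified -- no stepwise reduction.
#'
#' @param delta_data a [build_delta_dataset()] result (needs `delta`,
#'   `mean_rt`, `qq`, `study_id`, `participant_id`, `target_type`).
#' @inheritParams fit_lmm
#' @return a `stroop_lmm` (see [fit_lmm()]).
#' @export
fit_trend_model <- function(delta_data,
                            df_method = c("satterthwaite", "kenward-roger"),
                            control = NULL) {
  df_method <- match.arg(df_method)
  need <- c("delta", "mean_rt", "qq", "study_id", "participant_id",
            "target_type")
  miss <- setdiff(need, names(delta_data))
  if (length(miss))
    stop("delta dataset lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(delta_data$mean_rt)) < 3)
    stop("need at least 3 distinct mean_rt values for a quadratic trend",
         call. = FALSE)
  spec <- trend_model_spec()
  for (cl in c("study_id", "participant_id", "target_type", "qq"))
    delta_data[[cl]] <- factor(delta_data[[cl]])
  if (is.null(control))
    control <- lme4::lmerControl(check.conv.singular = "ignore",
                                 calc.derivs = FALSE)
  single_target <- nlevels(delta_data$target_type) < 2
  f <- if (single_target) {
    stats::as.formula(paste(
      "delta ~ poly(mean_rt, 2)",
      "+ (1 | study_id:participant_id) + (1 | study_id:qq)"),
      env = globalenv())
  } else {
    stats::as.formula(paste(
      "delta ~ target_type * poly(mean_rt, 2)",
      "+ (1 | study_id:participant_id) + (1 | study_id:target_type)",
      "+ (1 | study_id:target_type:qq)"), env = globalenv())
  }
  notes <- character()
  fit <- withCallingHandlers(
    lmerTest::lmer(f, data = delta_data, control = control),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  check_lmer_convergence(fit, notes)
  structure(list(fit = fit, spec = spec, data = delta_data,
                 df_method = df_method,
                 varcomp = varcomp_lmer(fit),
                 singular = lme4::isSingular(fit), notes = notes,
                 reml = TRUE, single_target = single_target),
            class = "stroop_lmm")
}

#' Per-target polynomial trend coefficients and their comparisons
#'
#' Raw-scale linear (ms of delta per ms of mean RT) and quadratic
#' (per ms^2) trend coefficients of the delta plot for each target
#' type, with confidence intervals, plus all pairwise between-target
#' coefficient differences with Bonferroni-adjusted p-values
#' (`emmeans::emtrends` under the hood).
#'
#' @param trend_fit a [fit_trend_model()] result.
#' @param adjust multiplicity adjustment for the pairwise comparisons.
#' @return object of class `stroop_trends`: list with `coefficients`
#'   and `comparisons` data frames.
#' @export
compare_trends <- function(trend_fit, adjust = "bonferroni") {
  stopifnot(inherits(trend_fit, "stroop_lmm"))
  single <- isTRUE(trend_fit$single_target)
  specs <- if (single) ~degree else ~ target_type | degree
  emt <- emmeans::emtrends(trend_fit$fit, specs,
                           var = "mean_rt", max.degree = 2,
                           data = trend_fit$data,
                           lmer.df = emm_df_mode(trend_fit$df_method))
  co <- norm_ci_cols(as.data.frame(summary(emt, infer = c(TRUE, TRUE),
                                           adjust = "none")))
  coefs <- data.frame(target_type = if (single)
                        as.character(unique(trend_fit$data$target_type))
                      else as.character(co$target_type),
                      degree = as.character(co$degree),
                      coef = co$mean_rt.trend, SE = co$SE, df = co$df,
                      lower_cl = co$lower.CL, upper_cl = co$upper.CL,
                      t = co$t.ratio, p = co$p.value,
                      stringsAsFactors = FALSE)
  if (single) {
    comps <- data.frame(contrast = character(), degree = character(),
                        estimate = numeric(), SE = numeric(),
                        df = numeric(), lower_cl = numeric(),
                        upper_cl = numeric(), t = numeric(),
                        p_adj = numeric(), adjust = character(),
                        stringsAsFactors = FALSE)
  } else {
    ctr <- emmeans::contrast(emt, method = "pairwise", by = "degree",
                             adjust = adjust)
    cs <- norm_ci_cols(as.data.frame(summary(ctr, infer = c(TRUE, TRUE))))
    comps <- data.frame(contrast = as.character(cs$contrast),
                        degree = as.character(cs$degree),
                        estimate = cs$estimate, SE = cs$SE, df = cs$df,
                        lower_cl = cs$lower.CL, upper_cl = cs$upper.CL,
                        t = cs$t.ratio, p_adj = cs$p.value, adjust = adjust,
                        stringsAsFactors = FALSE)
  }
  structure(list(coefficients = coefs, comparisons = comps),
            class = "stroop_trends")
}

#' @export
#' @method print stroop_trends
print.stroop_trends <- function(x, ...) {
  cat("delta-plot polynomial trends (raw scale):\n")
  print(x$coefficients, digits = 4)
  cat("\npairwise coefficient differences:\n")
  print(x$comparisons, digits = 4)
  invisible(x)
}
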