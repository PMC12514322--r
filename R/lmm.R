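#' Mixed-model specification for the distributional analyses
#'
#' A model spec names the response, the fixed terms and the random
#' intercept groupings (each a `:`-separated categorical key of the
#' dataset).  The two canonical specs encode the study-nested random
#' structure used for pooled multi-study spatial-Stroop data:
#' participants nested in studies, target type as a study-specific
#' feature, and a study x condition x quantile distributional term.
#'
#' @param response response column name (`"q_rt"` or `"delta"`).
#' @param fixed character vector of fixed-effect term labels (e.g.
#'   `"target_type"`, `"target_type:qq"`); interactions must be
#'   accompanied by their constituent main effects.
#' @param random character vector of grouping keys, e.g.
#'   `"study_id:participant_id"`.
#' @return an object of class `stroop_model_spec`.
#' @export
model_spec <- function(response, fixed, random) {
  stopifnot(is.character(response), length(response) == 1L,
            is.character(fixed), length(fixed) >= 1L,
            is.character(random), length(random) >= 1L)
  for (tm in fixed) {
    comp <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(comp) > 1L && !all(comp %in% fixed))
      stop("interaction '", tm, "' lacks a constituent main effect ",
           "(marginality)", call. = FALSE)
  }
  structure(list(response = response, fixed = fixed, random = random),
            class = "stroop_model_spec")
}

#' @rdname model_spec
#' @export
rt_model_spec <- function() {
  model_spec("q_rt",
             fixed = c("target_type", "congruency", "qq",
                       "target_type:congruency", "target_type:qq",
                       "congruency:qq"),
             random = c("study_id:participant_id",
                        "study_id:target_type",
                        "study_id:target_type:congruency:qq"))
}

#' @rdname model_spec
#' @export
delta_model_spec <- function() {
  model_spec("delta",
             fixed = c("target_type", "qq", "target_type:qq"),
             random = c("study_id:participant_id",
                        "study_id:target_type",
                        "study_id:target_type:qq"))
}

#' @export
#' @method print stroop_model_spec
print.stroop_model_spec <- function(x, ...) {
  cat(deparse(spec_formula(x)), sep = "\n")
  invisible(x)
}

spec_formula <- function(spec) {
  stats::as.formula(paste(spec$response, "~",
                          paste(spec$fixed, collapse = " + "), "+",
                          paste(sprintf("(1 | %s)", spec$random),
                                collapse = " + ")),
                    env = globalenv())
}

prep_model_data <- function(data, spec) {
  need <- unique(c(spec$response,
                   unlist(strsplit(c(spec$fixed, spec$random), ":",
                                   fixed = TRUE))))
  need <- setdiff(need, c("1", grep("(", need, fixed = TRUE, value = TRUE)))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  grp_cols <- setdiff(need, spec$response)
  for (cl in grp_cols)
    if (!is.numeric(data[[cl]]) || cl == "qq")
      data[[cl]] <- factor(data[[cl]])
  for (g in spec$random) {
    comp <- strsplit(g, ":", fixed = TRUE)[[1]]
    comp <- intersect(comp, names(data))
    lev <- nlevels(interaction(data[comp], drop = TRUE))
    if (lev < 2L)
      stop("random grouping '", g, "' has fewer than 2 levels",
           call. = FALSE)
  }
  data
}

#' Fit a linear mixed model with nested random intercepts
#'
#' REML fit of a [model_spec()] via `lmerTest::lmer`, with singular
#' (zero-variance) fits flagged rather than fatal -- they are expected
#' under degenerate inputs such as data generated with no study or
#' participant variance.  Hard non-convergence is an error carrying the
#' optimizer diagnostics.
#'
#' @param data dataset (CDF or delta dataset, typically).
#' @param spec a [model_spec()].
#' @param df_method denominator degrees-of-freedom method for all
#'   downstream tests: `"satterthwaite"` (default) or
#'   `"kenward-roger"`.
#' @param reml fit by REML (default) or ML.
#' @param control an optional [lme4::lmerControl()]; the default
#'   silences the singular-fit alarm, which is recorded on the result
#'   instead.
#' @return an object of class `stroop_lmm`: the `lmerTest` fit plus the
#'   spec, the df method, the variance components and convergence
#'   flags.  Methods: `print`, `summary`, `anova` (the F-table with
#'   partial eta squared), `coef` (fixed effects), `predict`,
#'   `residuals`.
#' @export
fit_lmm <- function(data, spec,
                    df_method = c("satterthwaite", "kenward-roger"),
                    reml = TRUE, control = NULL) {
  df_method <- match.arg(df_method)
  stopifnot(inherits(spec, "stroop_model_spec"))
  data <- prep_model_data(data, spec)
  if (is.null(control))
    control <- lme4::lmerControl(check.conv.singular = "ignore",
                                 calc.derivs = FALSE)
  notes <- character()
  fit <- withCallingHandlers(
    lmerTest::lmer(spec_formula(spec), data = data, REML = reml,
                   control = control),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  check_lmer_convergence(fit, notes)
  structure(list(fit = fit,
                 spec = spec,
                 data = data,
                 df_method = df_method,
                 varcomp = varcomp_lmer(fit),
                 singular = lme4::isSingular(fit),
                 notes = notes,
                 reml = reml),
            class = "stroop_lmm")
}

# hard optimizer failure is fatal; boundary/singular fits are recorded only
check_lmer_convergence <- function(fit, notes) {
  opt <- fit@optinfo$conv$opt
  if (!is.null(opt) && opt != 0)
    stop("mixed-model fit failed to converge (optimizer code ", opt,
         "): ", paste(notes, collapse = "; "), call. = FALSE)
  invisible(TRUE)
}

varcomp_lmer <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  stats::setNames(vc$vcov, vc$grp)
}

#' Extract variance components of a fitted mixed model
#'
#' Named vector of variance components (ms^2), one per random grouping
#' plus `"Residual"`.
#'
#' @param fit a [fit_lmm()] result.
#' @return named numeric vector.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "stroop_lmm"))
  fit$varcomp
}

#' @export
#' @method print stroop_lmm
print.stroop_lmm <- function(x, ...) {
  cat("mixed model:", deparse(spec_formula(x$spec)), "\n")
  cat(sprintf("REML: %s; df method: %s; singular: %s\n",
              x$reml, x$df_method, x$singular))
  cat("variance components (ms^2):\n")
  print(round(x$varcomp, 2))
  invisible(x)
}

#' @export
#' @method summary stroop_lmm
summary.stroop_lmm <- function(object, ...) summary(object$fit, ...)

#' @export
coef.stroop_lmm <- function(object, ...) lme4::fixef(object$fit)

#' @export
predict.stroop_lmm <- function(object, ...) stats::predict(object$fit, ...)

#' @export
residuals.stroop_lmm <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
anova.stroop_lmm <- function(object, ...) anova_table(object, ...)

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F df1 / (F df1 + df2)`, the proportion of residual-plus-
#' effect variability attributable to the term; `df2` may be fractional
#' (Satterthwaite/Kenward-Roger denominators).
#'
#' @param f F statistic(s), `>= 0`.
#' @param df1 numerator degrees of freedom, `>= 1`.
#' @param df2 denominator degrees of freedom, `> 0`.
#' @return numeric in `[0, 1)`.
#' @examples
#' partial_eta_sq(31.92, 2, 20.59)  # 0.756
#' @export
partial_eta_sq <- function(f, df1, df2) {
  if (any(f < 0)) stop("'f' must be >= 0", call. = FALSE)
  if (any(df1 < 1)) stop("'df1' must be >= 1", call. = FALSE)
  if (any(df2 <= 0)) stop("'df2' must be > 0", call. = FALSE)
  f * df1 / (f * df1 + df2)
}

#' Type-III ANOVA table with approximate denominator df
#'
#' Per-term F tests of the fixed effects with Satterthwaite (default)
#' or Kenward-Roger denominator degrees of freedom, plus partial eta
#' squared for each term.
#'
#' @param fit a [fit_lmm()] result.
#' @param df_method overrides the fit's df method if given.
#' @return data frame with columns `term`, `F`, `df1`, `df2`, `p`,
#'   `eta_p`, `df_method`.
#' @export
anova_table <- function(fit, df_method = NULL) {
  stopifnot(inherits(fit, "stroop_lmm"))
  if (is.null(df_method)) df_method <- fit$df_method
  ddf <- switch(df_method,
                satterthwaite = "Satterthwaite",
                `kenward-roger` = "Kenward-Roger",
                stop("unknown df method: ", df_method, call. = FALSE))
  a <- stats::anova(fit$fit, type = 3, ddf = ddf)
  out <- data.frame(term = rownames(a),
                    F = a[["F value"]],
                    df1 = a[["NumDF"]],
                    df2 = a[["DenDF"]],
                    p = a[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  out$eta_p <- partial_eta_sq(out$F, out$df1, out$df2)
  out$df_method <- df_method
  rownames(out) <- NULL
  out
}

# is term 'tm' contained in a higher-order retained term?
contained_in_higher <- function(tm, terms) {
  comp <- strsplit(tm, ":", fixed = TRUE)[[1]]
  for (other in setdiff(terms, tm)) {
    oc <- strsplit(other, ":", fixed = TRUE)[[1]]
    if (length(oc) > length(comp) && all(comp %in% oc)) return(TRUE)
  }
  FALSE
}

#' Backward elimination of non-significant fixed effects
#'
#' Iteratively refits the model, removing at each step the
#' least-significant removable fixed term whose p-value is `>= alpha`.
#' A term is removable only when no retained interaction contains it
#' (marginality); the random structure is never touched.
#'
#' @param data dataset.
#' @param spec starting [model_spec()].
#' @param alpha term-retention significance level.
#' @inheritParams fit_lmm
#' @return list with `spec` (the reduced spec), `fit` (its fit), and
#'   `log` (data frame of eliminated terms with their p-values).
#' @export
stepwise_reduce <- function(data, spec, alpha = 0.05,
                            df_method = c("satterthwaite", "kenward-roger"),
                            control = NULL) {
  df_method <- match.arg(df_method)
  stopifnot(alpha > 0, alpha < 1)
  log <- data.frame(term = character(), p = numeric(),
                    stringsAsFactors = FALSE)
  repeat {
    fit <- fit_lmm(data, spec, df_method = df_method, control = control)
    a <- anova_table(fit)
    removable <- !vapply(a$term, contained_in_higher, logical(1),
                         terms = a$term)
    cand <- which(removable & a$p >= alpha)
    if (!length(cand) || length(spec$fixed) == 1L) break
    worst <- cand[which.max(a$p[cand])]
    log <- rbind(log, data.frame(term = a$term[worst], p = a$p[worst]))
    spec <- model_spec(spec$response, setdiff(spec$fixed, a$term[worst]),
                       spec$random)
  }
  list(spec = spec, fit = fit, log = log)
}

emm_df_mode <- function(df_method) {
  switch(df_method, satterthwaite = "satterthwaite",
         `kenward-roger` = "kenward-roger", "satterthwaite")
}

#' Estimated marginal means over the reference grid
#'
#' Model-based means over the equally weighted full factorial grid of
#' the requested factors (so unbalanced cell counts do not tilt the
#' means), with standard errors from the fixed-effect covariance and
#' the fit's denominator-df method.
#'
#' @param fit a [fit_lmm()] result.
#' @param specs factors to average over, as a character vector (e.g.
#'   `c("target_type", "congruency")`) or an `emmeans` formula.
#' @param ... passed to [emmeans::emmeans()].
#' @return an `emmGrid`.
#' @export
emm <- function(fit, specs, ...) {
  stopifnot(inherits(fit, "stroop_lmm"))
  if (is.character(specs))
    specs <- stats::as.formula(paste("~", paste(specs, collapse = " * ")))
  emmeans::emmeans(fit$fit, specs = specs, data = fit$data,
                   lmer.df = emm_df_mode(fit$df_method), ...)
}

# map asymptotic (z) summary columns onto the t-scale names
norm_ci_cols <- function(s) {
  if (!"lower.CL" %in% names(s) && "asymp.LCL" %in% names(s)) {
    s$lower.CL <- s$asymp.LCL; s$upper.CL <- s$asymp.UCL
  }
  if (!"t.ratio" %in% names(s) && "z.ratio" %in% names(s))
    s$t.ratio <- s$z.ratio
  s
}

contrast_frame <- function(s, adjust, fit) {
  stat_cols <- c("emmean", "estimate", "SE", "df", "lower.CL", "upper.CL",
                 "asymp.LCL", "asymp.UCL", "t.ratio", "z.ratio", "p.value")
  lbl <- if ("contrast" %in% names(s)) as.character(s$contrast)
         else apply(s[, !(names(s) %in% stat_cols), drop = FALSE],
                    1, paste, collapse = " ")
  est <- if ("estimate" %in% names(s)) s$estimate else s$emmean
  # very large fits drop to the asymptotic (z) scale; normalize the columns
  tstat <- if ("t.ratio" %in% names(s)) s$t.ratio else s$z.ratio
  lo <- if ("lower.CL" %in% names(s)) s$lower.CL else s$asymp.LCL
  hi <- if ("upper.CL" %in% names(s)) s$upper.CL else s$asymp.UCL
  out <- data.frame(contrast = lbl, estimate = est, SE = s$SE, df = s$df,
                    t = tstat, p_adj = s$p.value, adjust = adjust,
                    lower_cl = lo, upper_cl = hi,
                    stringsAsFactors = FALSE)
  extra <- intersect(c("target_type", "congruency", "qq", "prob"), names(s))
  if (length(extra)) out <- cbind(s[extra], out)
  if (!is.null(fit)) {
    vc <- variance_components(fit)
    out$d <- vapply(est, cohens_d_westfall, numeric(1), varcomps = vc)
  }
  rownames(out) <- NULL
  out
}

#' All pairwise EMM contrasts with Tukey HSD adjustment
#'
#' Pairwise differences of estimated marginal means with
#' studentized-range (Tukey) adjusted p-values and confidence
#' intervals; optionally Westfall standardized effect sizes when the
#' parent fit is supplied.
#'
#' @param emm_grid an [emm()] grid.
#' @param fit optional parent [fit_lmm()], enabling the `d` column.
#' @param by optional conditioning factor(s) passed to
#'   [emmeans::contrast()].
#' @return data frame of contrast results.
#' @export
pairwise_tukey <- function(emm_grid, fit = NULL, by = NULL) {
  ctr <- emmeans::contrast(emm_grid, method = "pairwise", by = by,
                           adjust = "tukey")
  s <- as.data.frame(summary(ctr, infer = c(TRUE, TRUE)))
  contrast_frame(s, "tukey", fit)
}

#' One-sample EMM contrasts against zero
#'
#' Tests every estimated marginal mean against zero (is a congruency
#' effect present at this quantile?) with Bonferroni-adjusted p-values
#' by default.
#'
#' @param emm_grid an [emm()] grid (typically of delta EMMs).
#' @param adjust multiplicity adjustment (default `"bonferroni"`).
#' @param fit optional parent [fit_lmm()], enabling the `d` column.
#' @param by optional conditioning factor(s): the adjustment is applied
#'   within each `by` group.
#' @return data frame of contrast results.
#' @export
contrasts_vs_zero <- function(emm_grid, adjust = "bonferroni", fit = NULL,
                              by = NULL) {
  s <- as.data.frame(summary(emm_grid, infer = c(TRUE, TRUE), null = 0,
                             adjust = adjust, by = by))
  contrast_frame(s, adjust, fit)
}

#' Westfall standardized effect size for mixed-model contrasts
#'
#' Standardizes an EMM contrast by the square root of the summed
#' variance components (all random groupings plus residual), the
#' design-agnostic denominator recommended for mixed-model pairwise
#' comparisons.
#'
#' @param estimate contrast estimate (ms).
#' @param varcomps variance components (ms^2), including the residual;
#'   see [variance_components()].
#' @return standardized d.
#' @examples
#' cohens_d_westfall(12, c(4, 5, 7))  # 3
#' @export
cohens_d_westfall <- function(estimate, varcomps) {
  if (any(varcomps < 0)) stop("variance components must be >= 0",
                              call. = FALSE)
  if (all(varcomps == 0)) stop("all variance components are zero",
                               call. = FALSE)
  estimate / sqrt(sum(varcomps))
}
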