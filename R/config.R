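#' Pipeline configuration
#'
#' A single object that fully determines a pipeline run: either a path
#' to a trial-level CSV/TSV or a [sim_config()] to generate one, the
#' preprocessing window, the probability grid, model options and the
#' seed.  Round-trips losslessly through YAML.
#'
#' @param input path to a trial table, or `NULL` to simulate.
#' @param sim a [sim_config()] (used when `input` is `NULL`).
#' @param probs quantile probability grid.
#' @param low,high,mode,nonresponse_threshold,min_trials preprocessing
#'   settings.
#' @param df_method,alpha,stepwise model options (see
#'   [delta_analysis()]).
#' @param fig_format `"png"` or `"svg"`.
#' @param seed integer seed governing all randomness of the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(),
                            probs = c(.1, .3, .5, .7, .9),
                            low = 200, high = 1300,
                            mode = "trimmed",
                            nonresponse_threshold = 0.5, min_trials = 10,
                            df_method = "satterthwaite", alpha = 0.05,
                            stepwise = FALSE, fig_format = "png",
                            seed = 1L) {
  stopifnot(is.null(input) || (is.character(input) && length(input) == 1L))
  if (is.null(input)) stopifnot(inherits(sim, "sim_config"))
  fig_format <- match.arg(fig_format, c("png", "svg"))
  structure(list(input = input, sim = if (is.null(input)) sim,
                 probs = probs, low = low, high = high, mode = mode,
                 nonresponse_threshold = nonresponse_threshold,
                 min_trials = min_trials, df_method = df_method,
                 alpha = alpha, stepwise = stepwise,
                 fig_format = fig_format, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @name pipeline_config_io
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (!is.null(x$sim)) {
    s <- unclass(x$sim)
    s$profile <- lapply(s$profile, function(p)
      list(a = p$a, b = p$b, c = p$c))
    x$sim <- s
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config_io
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- NULL
  if (is.null(x$input) && !is.null(x$sim)) {
    s <- x$sim
    sim <- sim_config(n_studies = s$n_studies,
                      participants_per_study = s$participants_per_study,
                      trials_per_cell = s$trials_per_cell,
                      target_types = unlist(s$target_types),
                      baseline = s$baseline, profile = s$profile,
                      study_sd = s$study_sd,
                      participant_sd = s$participant_sd,
                      error_rate = s$error_rate,
                      nonresponse_rate = s$nonresponse_rate,
                      contamination = s$contamination, seed = s$seed)
  }
  pipeline_config(input = x$input, sim = if (is.null(x$input)) sim else sim_config(),
                  probs = unlist(x$probs), low = x$low, high = x$high,
                  mode = x$mode,
                  nonresponse_threshold = x$nonresponse_threshold,
                  min_trials = x$min_trials, df_method = x$df_method,
                  alpha = x$alpha, stepwise = x$stepwise,
                  fig_format = x$fig_format, seed = x$seed)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline and persist every output
#'
#' Executes simulate/read, preprocess, quantile construction, the three
#' mixed models and the contrast layer, writing each product to
#' `out_dir`: the (simulated) trial table, removal report, CDF and
#' delta datasets, per-model coefficient / variance-component / ANOVA /
#' EMM / contrast tables, trend tables, the delta and CDF figures, and
#' a machine-readable `manifest.json` (configuration, seed, package and
#' R versions).  A stage failure aborts with the stage name; outputs of
#' completed stages remain on disk.
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @param out_dir output directory (created if needed).
#' @return the [delta_analysis()] object, invisibly; side effect is the
#'   populated run directory.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  trials <- stage("input", {
    if (!is.null(config$input)) read_trials(config$input)
    else {
      sim <- config$sim
      sim$seed <- config$seed
      tr <- simulate_cohort(sim)
      utils::write.csv(tr, file.path(out_dir, "trials.csv"),
                       row.names = FALSE, na = "")
      tr
    }
  })

  res <- stage("analysis",
    delta_analysis(trials, probs = config$probs, low = config$low,
                   high = config$high, mode = config$mode,
                   nonresponse_threshold = config$nonresponse_threshold,
                   min_trials = config$min_trials,
                   df_method = config$df_method, alpha = config$alpha,
                   stepwise = config$stepwise))

  stage("outputs", {
    write_tsv(res$removal_report, file.path(out_dir, "removal_report.tsv"))
    write_tsv(res$cdf, file.path(out_dir, "cdf.tsv"))
    write_tsv(res$delta, file.path(out_dir, "delta.tsv"))
    write_tsv(res$rt_anova, file.path(out_dir, "rt_anova.tsv"))
    write_tsv(res$delta_anova, file.path(out_dir, "delta_anova.tsv"))
    vc <- function(f) data.frame(group = names(variance_components(f)),
                                 variance = unname(variance_components(f)))
    write_tsv(vc(res$rt_fit), file.path(out_dir, "rt_varcomp.tsv"))
    write_tsv(vc(res$delta_fit), file.path(out_dir, "delta_varcomp.tsv"))
    write_tsv(data.frame(term = names(coef(res$rt_fit)),
                         estimate = unname(coef(res$rt_fit))),
              file.path(out_dir, "rt_coefficients.tsv"))
    write_tsv(res$emm_rt, file.path(out_dir, "rt_emm.tsv"))
    if (!is.null(res$emm_delta))
      write_tsv(res$emm_delta, file.path(out_dir, "delta_emm.tsv"))
    write_tsv(res$emm_delta_quantile,
              file.path(out_dir, "delta_emm_quantile.tsv"))
    write_tsv(res$congruency_contrasts,
              file.path(out_dir, "congruency_contrasts.tsv"))
    write_tsv(res$delta_vs_zero, file.path(out_dir, "delta_vs_zero.tsv"))
    write_tsv(res$trends$coefficients,
              file.path(out_dir, "trend_coefficients.tsv"))
    write_tsv(res$trends$comparisons,
              file.path(out_dir, "trend_comparisons.tsv"))
  })

  stage("figures", {
    plot_delta(res, file.path(out_dir,
                              paste0("delta_plot.", config$fig_format)))
    plot_cdf(res, file.path(out_dir,
                            paste0("cdf_plot.", config$fig_format)))
  })

  stage("manifest", {
    cfg_path <- file.path(out_dir, "config.yaml")
    write_pipeline_config(config, cfg_path)
    manifest <- list(seed = config$seed,
                     config = "config.yaml",
                     package_version = as.character(utils::packageVersion("stroopdelta")),
                     r_version = R.version.string,
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(res)
}
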