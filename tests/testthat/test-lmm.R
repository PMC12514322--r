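test_that("partial eta squared follows its definition and validates inputs", {
  expect_equal(partial_eta_sq(0, 2, 30), 0)
  f <- c(3.2, 12.8); d1 <- c(2, 4); d2 <- c(28, 114.3)
  expect_equal(partial_eta_sq(f, d1, d2), f * d1 / (f * d1 + d2))
  expect_error(partial_eta_sq(-1, 1, 10), ">= 0")
  expect_error(partial_eta_sq(1, 0.5, 10), "df1")
  expect_error(partial_eta_sq(1, 1, 0), "df2")
})

test_that("zero-variance data give vanishing variance components and OLS fixed effects", {
  set.seed(41)
  d <- expand.grid(study_id = c("s1", "s2"),
                   participant_id = sprintf("p%02d", 1:10),
                   g = c("a", "b"), rep = 1:4)
  d$y <- c(a = 100, b = 130)[d$g] + rnorm(nrow(d), 0, 5)
  fit <- fit_lmm(d, model_spec("y", "g", c("study_id:participant_id")))
  vc <- variance_components(fit)
  expect_lt(vc[["study_id:participant_id"]], 1e-4 * vc[["Residual"]])
  expect_true(fit$singular)
  ols <- coef(lm(y ~ g, d))
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-6)
})

test_that("balanced one-way layouts reproduce the classical nested ANOVA F and cell means", {
  d <- balanced_oneway(c(a = 100, b = 115, c = 90), units_per_group = 12,
                       reps = 2, seed = 5)
  d$study_id <- "s0"  # single stratum; grouping key is the unit
  fit <- fit_lmm(d, model_spec("y", "g", "unit"))
  a <- anova_table(fit)

  # classical oracle: between-units F from the aov error decomposition
  cl <- summary(aov(y ~ g + Error(unit), d))
  f_cl <- cl[["Error: unit"]][[1]]["g", "F value"]
  df2_cl <- cl[["Error: unit"]][[1]]["Residuals", "Df"]
  expect_equal(a$F, f_cl, tolerance = 1e-6)
  expect_equal(a$df2, df2_cl, tolerance = 1e-6)
  expect_equal(a$eta_p, partial_eta_sq(a$F, a$df1, a$df2))

  cell_means <- tapply(d$y, d$g, mean)
  e <- as.data.frame(emm(fit, "g"))
  expect_equal(e$emmean, as.numeric(cell_means[as.character(e$g)]),
               tolerance = 1e-8)
})

test_that("EMMs weight the reference grid equally under imbalance", {
  # 5 vs 45 units of 2 observations; group means exactly 10 and 20
  units <- c(5, 45)
  g <- factor(rep(c("a", "b"), times = units * 2))
  unit <- factor(rep(seq_len(sum(units)), each = 2))
  set.seed(6)
  noise <- rnorm(length(g), 0, 1)
  noise <- noise - ave(noise, g)           # exact cell means
  d <- data.frame(g = g, unit = unit, y = c(10, 20)[as.integer(g)] + noise)
  fit <- fit_lmm(d, model_spec("y", "g", "unit"))
  e <- as.data.frame(emm(fit, "g"))
  expect_equal(e$emmean, c(10, 20), tolerance = 1e-6)
  grand <- as.data.frame(emm(fit, "1"))
  expect_equal(grand$emmean, 15, tolerance = 1e-6)  # not the pooled 19
})

test_that("Tukey adjustment collapses to the plain t-test for two groups and is monotone", {
  d <- balanced_oneway(c(a = 100, b = 106), seed = 7)
  fit <- fit_lmm(d, model_spec("y", "g", "unit"))
  grid <- emm(fit, "g")
  tk <- pairwise_tukey(grid, fit = fit)
  raw <- as.data.frame(summary(emmeans::contrast(grid, "pairwise",
                                                 adjust = "none")))
  expect_equal(tk$p_adj, raw$p.value, tolerance = 1e-9)
  expect_true(tk$lower_cl <= tk$estimate & tk$estimate <= tk$upper_cl)
  expect_equal(sign(tk$d), sign(tk$estimate))

  d3 <- balanced_oneway(c(a = 100, b = 100, c = 100), seed = 8)
  fit3 <- fit_lmm(d3, model_spec("y", "g", "unit"))
  tk3 <- pairwise_tukey(emm(fit3, "g"), fit = fit3)
  expect_true(all(tk3$p_adj > 0.5))
  raw3 <- as.data.frame(summary(emmeans::contrast(emm(fit3, "g"), "pairwise",
                                                  adjust = "none")))
  expect_true(all(tk3$p_adj >= raw3$p.value - 1e-12))
})

test_that("one-sample contrasts against zero apply the Bonferroni rule", {
  d <- balanced_oneway(c(a = 0, b = 4, c = 8, d = 12, e = 2), seed = 9)
  d$y <- d$y - mean(d$y[d$g == "a"])  # group a exactly zero
  fit <- fit_lmm(d, model_spec("y", "g", "unit"))
  grid <- emm(fit, "g")
  vz <- contrasts_vs_zero(grid, fit = fit)
  raw <- as.data.frame(summary(grid, infer = TRUE, null = 0,
                               adjust = "none"))
  expect_equal(vz$p_adj, pmin(1, 5 * raw$p.value), tolerance = 1e-9)
  a_row <- which(raw$g == "a")
  expect_equal(vz$estimate[a_row], 0, tolerance = 1e-8)
  expect_equal(vz$p_adj[a_row], 1)
})

test_that("Westfall d standardizes by the summed variance components", {
  expect_equal(cohens_d_westfall(12, c(4, 5, 7)), 3)
  expect_equal(cohens_d_westfall(0, c(4, 5, 7)), 0)
  expect_error(cohens_d_westfall(1, c(0, 0)), "zero")
  expect_error(cohens_d_westfall(1, c(-1, 2)), ">= 0")
  set.seed(10)
  est <- rnorm(20); v <- rexp(3)
  expect_equal(sign(vapply(est, cohens_d_westfall, numeric(1), varcomps = v)),
               sign(est))
})

test_that("backward elimination respects marginality and removes genuinely null terms first", {
  set.seed(12)
  d <- expand.grid(study_id = sprintf("s%d", 1:3),
                   participant_id = sprintf("p%02d", 1:8),
                   g1 = c("x", "y"), g2 = c("u", "v"), rep = 1:3)
  # strong mains, exactly null interaction
  d$y <- 10 * (d$g1 == "y") + 6 * (d$g2 == "v") + rnorm(nrow(d), 0, 3)
  spec <- model_spec("y", c("g1", "g2", "g1:g2"), "study_id:participant_id")
  red <- stepwise_reduce(d, spec, alpha = 0.05)
  expect_false("g1:g2" %in% red$spec$fixed)
  expect_true(all(c("g1", "g2") %in% red$spec$fixed))
  expect_equal(red$log$term[1], "g1:g2")
  expect_gte(red$log$p[1], 0.05)

  # pure interaction pattern: null mains are kept because the interaction stays
  d2 <- d
  d2$y <- 8 * xor(d2$g1 == "y", d2$g2 == "v") + rnorm(nrow(d2), 0, 3)
  red2 <- stepwise_reduce(d2, spec, alpha = 0.05)
  expect_setequal(red2$spec$fixed, c("g1", "g2", "g1:g2"))
  # and the log shows nothing was eliminated
  expect_equal(nrow(red2$log), 0)

  # all terms significant: spec unchanged
  red3 <- stepwise_reduce(d2, model_spec("y", c("g1", "g2", "g1:g2"),
                                         "study_id:participant_id"),
                          alpha = 0.05)
  expect_setequal(red3$spec$fixed, spec$fixed)
})

test_that("model specs enforce marginality and data requirements", {
  expect_error(model_spec("y", c("a:b"), "g"), "marginality")
  spec <- model_spec("y", "g", "unit")
  expect_error(fit_lmm(data.frame(y = 1:4, g = c("a", "b", "a", "b")), spec),
               "unit")
  d <- data.frame(y = rnorm(8), g = rep(c("a", "b"), 4), unit = "u1")
  expect_error(fit_lmm(d, spec), "fewer than 2 levels")
})

test_that("the RT model recovers injected congruency effects without bias", {
  base <- default_baselines()
  profiles <- list(face = delta_profile(-25, 0, 0, base$face),
                   arrows = delta_profile(30, 0, 0, base$arrows))
  truth <- c(face = -25, arrows = 30)
  n_rep <- 50
  est <- matrix(NA_real_, n_rep, 2, dimnames = list(NULL, names(truth)))
  for (r in seq_len(n_rep)) {
    cfg <- clean_config(n_studies = 3, participants_per_study = 8,
                        trials_per_cell = 40,
                        target_types = c("face", "arrows"),
                        baseline = base, profile = profiles,
                        seed = 1000 + r)
    tr <- simulate_cohort(cfg)
    cdf <- build_cdf_dataset(tr, min_trials = 10)
    fit <- fit_lmm(cdf, rt_model_spec())
    grid <- quiet(emm(fit, c("target_type", "congruency")))
    ctr <- pairwise_tukey(grid, fit = fit, by = "target_type")
    # contrast is congruent - incongruent = -delta
    for (tt in names(truth))
      est[r, tt] <- -ctr$estimate[ctr$target_type == tt]
  }
  for (tt in names(truth)) {
    mc_se <- sd(est[, tt]) / sqrt(n_rep)
    expect_lt(abs(mean(est[, tt]) - truth[[tt]]), 3 * mc_se)
    # every replicate pins the direction of the effect
    expect_true(all(sign(est[, tt]) == sign(truth[[tt]])))
  }
})
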