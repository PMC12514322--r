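test_that("the Type-8 estimator matches its defining formula on worked cases", {
  expect_equal(hf_quantile8(c(1, 2, 3, 4), 0.5), 2.5)
  expect_equal(hf_quantile8(c(5, 5, 5), c(.1, .5, .9)), c(5, 5, 5))
  # h = (5 + 1/3) * .3 + 1/3 = 1.9333..., interpolates x_(1), x_(2)
  expect_equal(hf_quantile8(c(10, 20, 30, 40, 50), 0.3), 19 + 1 / 3,
               tolerance = 1e-12)
  # h = 5.1333 clamps to n: the sample maximum
  expect_equal(hf_quantile8(c(10, 20, 30, 40, 50), 0.9), 50)
  expect_error(hf_quantile8(numeric(0), 0.5), "empty")
  expect_error(hf_quantile8(c(1, NA), 0.5), "NA")
  expect_error(hf_quantile8(1:4, 0), "strictly")
})

test_that("the Type-8 estimator agrees with the reference implementation and is monotone", {
  set.seed(100)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    x <- switch(sample(3, 1),
                rnorm(n, 500, 80),
                rexp(n, 1 / 200) + 250,
                sample(300:600, n, replace = TRUE))  # ties
    p <- runif(3, 0.01, 0.99)
    expect_equal(hf_quantile8(x, p),
                 unname(quantile(x, p, type = 8)), tolerance = 1e-9)
  }
  # non-decreasing in p and bounded by the sample range
  x <- rexp(40, 1 / 150) + 300
  p <- seq(.02, .98, by = .02)
  q <- hf_quantile8(x, p)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q >= min(x) & q <= max(x)))
})

test_that("the CDF dataset has one row per cell x probability, monotone within cell", {
  cfg <- clean_config(n_studies = 1, participants_per_study = 1,
                      trials_per_cell = 30, target_types = "eyes", seed = 3)
  tr <- simulate_cohort(cfg)
  cdf <- build_cdf_dataset(tr, min_trials = 10)
  expect_equal(nrow(cdf), 2 * 5)  # both congruencies x 5 probs

  # quartile-style grid: 3 inner points
  cdf3 <- build_cdf_dataset(tr, probs = c(.25, .5, .75), min_trials = 10)
  expect_equal(nrow(cdf3), 2 * 3)
  expect_equal(sort(unique(cdf3$prob)), c(.25, .5, .75))

  cfg2 <- clean_config(n_studies = 2, participants_per_study = 6,
                       trials_per_cell = 25,
                       target_types = c("face", "arrows"), seed = 13)
  cdf2 <- build_cdf_dataset(simulate_cohort(cfg2), min_trials = 10)
  mono <- tapply(seq_len(nrow(cdf2)),
                 interaction(cdf2$study_id, cdf2$participant_id,
                             cdf2$target_type, cdf2$congruency, drop = TRUE),
                 function(i) all(diff(cdf2$q_rt[i][order(cdf2$prob[i])]) >= 0))
  expect_true(all(mono))

  # small cells are dropped with a warning
  tiny <- tr[tr$congruency == "congruent", ][1:5, ]
  expect_warning(expect_error(build_cdf_dataset(tiny, min_trials = 10),
                              "minimum"), "skipped")
  expect_error(build_cdf_dataset(tr[0, ]), "empty")
  expect_error(build_cdf_dataset(tr, probs = c(.5, .3)), "increasing")
})

test_that("delta cells are exact quantile differences with the field's sign convention", {
  cdf <- data.frame(study_id = "s1", participant_id = "p1",
                    target_type = "face",
                    congruency = rep(c("congruent", "incongruent"), each = 3),
                    prob = rep(c(.25, .5, .75), 2),
                    q_rt = c(400, 450, 500, 430, 470, 510))
  d <- build_delta_dataset(cdf)
  expect_equal(d$delta, c(30, 20, 10))
  expect_equal(d$mean_rt, c(415, 460, 505))

  # identical conditions: zero deltas
  cdf0 <- cdf; cdf0$q_rt <- rep(c(400, 450, 500), 2)
  expect_equal(build_delta_dataset(cdf0)$delta, c(0, 0, 0))

  # faster incongruent responses give negative delta
  cdf_r <- cdf[cdf$prob == .5, ]; cdf_r$q_rt <- c(620, 590)
  expect_equal(build_delta_dataset(cdf_r)$delta, -30)

  # reconstruction: Q_incong = Q_cong + delta
  set.seed(7)
  cdf$q_rt <- runif(6, 300, 900)
  d2 <- build_delta_dataset(cdf)
  q_con <- cdf$q_rt[cdf$congruency == "congruent"]
  q_inc <- cdf$q_rt[cdf$congruency == "incongruent"]
  expect_equal(q_con + d2$delta, q_inc, tolerance = 1e-12)
  expect_true(all(d2$mean_rt >= pmin(q_con, q_inc) &
                    d2$mean_rt <= pmax(q_con, q_inc)))

  # unpaired cells dropped with a warning
  expect_warning(d3 <- build_delta_dataset(cdf[-2, ]), "dropped")
  expect_equal(nrow(d3), 2)
})

test_that("vincentizing equals the brute-force participant average", {
  one <- data.frame(participant_id = "p1", target_type = "face",
                    prob = c(.3, .5), q_rt = c(400, 450))
  v1 <- vincentize(one)
  expect_equal(v1$mean_value, c(400, 450))

  two <- rbind(one, within(one, q_rt <- q_rt + 100))
  two$participant_id <- rep(c("p1", "p2"), each = 2)
  v2 <- vincentize(two)
  expect_equal(v2$mean_value[v2$prob == .5], 500)

  cfg <- clean_config(n_studies = 2, participants_per_study = 8,
                      trials_per_cell = 20,
                      target_types = c("face", "arrows"), seed = 17)
  cdf <- build_cdf_dataset(simulate_cohort(cfg), min_trials = 10)
  v <- vincentize(cdf, by = c("target_type", "congruency"))
  brute <- aggregate(q_rt ~ target_type + congruency + prob, cdf, mean)
  m <- merge(v, brute)
  expect_equal(m$mean_value, m$q_rt, tolerance = 1e-12)
})
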