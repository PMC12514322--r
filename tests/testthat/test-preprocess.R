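test_that("read_trials validates schema and normalizes vocabulary", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- trial_rows(c(300, 400, 500, 600, NA, 700),
                  accuracy = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
                  responded = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
                  congruency = c("Congruent", "INCONGRUENT", "congruent",
                                 "incongruent", "congruent", "congruent"))
  write.csv(d, path, row.names = FALSE, na = "")
  tr <- read_trials(path)
  expect_equal(nrow(tr), 6)
  expect_setequal(unique(tr$congruency), c("congruent", "incongruent"))
  expect_false(tr$responded[5])
  expect_true(is.na(tr$rt_ms[5]))

  # missing required column
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d[setdiff(names(d), "congruency")], path2, row.names = FALSE)
  expect_error(read_trials(path2), "congruency")

  # unknown category label, reported with its row
  d2 <- d; d2$target_type[3] <- "hands"
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d2, path3, row.names = FALSE, na = "")
  expect_error(read_trials(path3), "hands.*row 3")

  # column renaming via the role map
  d3 <- d; names(d3)[names(d3) == "rt_ms"] <- "RT"
  path4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d3, path4, row.names = FALSE, na = "")
  expect_equal(read_trials(path4, column_map = c(rt_ms = "RT"))$rt_ms,
               tr$rt_ms)
})

test_that("non-responder exclusion applies its threshold inclusively", {
  mostly_missing <- trial_rows(c(rep(NA, 64), runif(36, 300, 800)),
                               responded = c(rep(FALSE, 64), rep(TRUE, 36)),
                               participant = "p64")
  fine <- trial_rows(runif(100, 300, 800), participant = "p_ok")
  tr <- rbind(mostly_missing, fine)

  res <- exclude_nonresponders(tr, threshold = 0.5)
  expect_equal(res$excluded$participant_id, "p64")
  expect_equal(res$excluded$nonresponse_prop, 0.64)
  expect_equal(sort(unique(res$trials$participant_id)), "p_ok")

  # no non-responses: untouched
  res2 <- exclude_nonresponders(fine, threshold = 0.5)
  expect_identical(res2$trials, fine)
  expect_equal(nrow(res2$excluded), 0)

  # threshold 1.0 removes only total non-responders
  res3 <- exclude_nonresponders(tr, threshold = 1.0)
  expect_equal(nrow(res3$excluded), 0)
  all_missing <- trial_rows(rep(NA_real_, 10), responded = FALSE,
                            participant = "p_gone")
  res4 <- exclude_nonresponders(rbind(tr, all_missing), threshold = 1.0)
  expect_equal(res4$excluded$participant_id, "p_gone")
})

test_that("RT trimming keeps the closed window and the non-trimmed variant keeps all responded", {
  tr <- trial_rows(c(150, 250, 1400, 200, 1300, NA),
                   responded = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(trim_rts(tr, 200, 1300, "trimmed")$rt_ms, c(250, 200, 1300))
  expect_equal(trim_rts(tr, 200, 1300, "nontrimmed")$rt_ms,
               c(150, 250, 1400, 200, 1300))
  expect_error(trim_rts(tr, 1300, 200), "low < high")
})

test_that("accuracy filtering keeps correct trials and warns when nothing remains", {
  tr <- trial_rows(c(300, 400, 500), accuracy = c(TRUE, FALSE, TRUE))
  expect_equal(filter_correct(tr)$rt_ms, c(300, 500))
  all_good <- trial_rows(c(300, 400))
  expect_identical(filter_correct(all_good), all_good)
  all_bad <- trial_rows(c(300, 400), accuracy = FALSE)
  expect_warning(out <- filter_correct(all_bad), "no correct")
  expect_equal(nrow(out), 0)
})

test_that("removal report conserves counts and rejects non-subset stages", {
  rt <- runif(100, 300, 800)
  tr <- trial_rows(rt)
  tr$responded[1:5] <- FALSE; tr$rt_ms[1:5] <- NA
  tr$accuracy[6:15] <- FALSE
  tr$rt_ms[16:18] <- 1500
  s1 <- tr[tr$responded, ]
  s2 <- s1[s1$rt_ms <= 1300, ]
  s3 <- s2[s2$accuracy, ]
  rep_ <- removal_report(tr, list(nonresponse = s1, window = s2,
                                  incorrect = s3))
  get <- function(rule) rep_$n[rep_$rule == rule]
  expect_equal(get("nonresponse"), 5)
  expect_equal(get("window"), 3)
  expect_equal(get("incorrect"), 10)
  expect_equal(get("retained"), 82)
  expect_equal(rep_$proportion[rep_$rule == "nonresponse"], 0.05)
  expect_equal(sum(rep_$n), 100)

  # no removals: all-zero removal rows
  rep0 <- removal_report(tr, list(noop = tr))
  expect_equal(rep0$n[rep0$rule == "noop"], 0)
  expect_equal(rep0$n[rep0$rule == "retained"], 100)

  expect_error(removal_report(s2, list(bigger = tr)), "not a subset")
})

test_that("removal report conservation holds on simulated cohorts", {
  cfg <- sim_config(n_studies = 2, participants_per_study = 5,
                    trials_per_cell = 30, target_types = c("eyes", "arrows"),
                    error_rate = .08, nonresponse_rate = .04,
                    contamination = list(rate = .05, low = 50, high = 2500),
                    seed = 21)
  tr <- simulate_cohort(cfg)
  pre <- preprocess_trials(tr)
  rp <- pre$report
  # per cell: removals + retained reconstruct the cell's input count
  tot <- aggregate(n ~ study_id + target_type + congruency, rp, sum)
  input <- as.data.frame(table(tr$study_id, tr$target_type, tr$congruency),
                         stringsAsFactors = FALSE)
  names(input) <- c("study_id", "target_type", "congruency", "n_in")
  m <- merge(tot, input)
  expect_equal(m$n, m$n_in)
})

test_that("the preprocessing pipeline is idempotent and leaves RTs unmodified", {
  cfg <- sim_config(n_studies = 2, participants_per_study = 4,
                    trials_per_cell = 40, target_types = "face",
                    error_rate = .05, nonresponse_rate = .03, seed = 31)
  tr <- simulate_cohort(cfg)
  p1 <- preprocess_trials(tr)
  p2 <- preprocess_trials(p1$trials)
  expect_equal(p2$trials, p1$trials, ignore_attr = TRUE)
  expect_true(all(p1$trials$rt_ms %in% tr$rt_ms))
})
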