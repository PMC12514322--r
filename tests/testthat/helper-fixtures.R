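# Fixtures are generated in code; nothing is read from disk.

# a clean cohort: no errors, no non-responses, no contamination
clean_config <- function(..., seed = 1) {
  sim_config(...,
             error_rate = 0, nonresponse_rate = 0,
             contamination = list(rate = 0, low = 50, high = 2500),
             seed = seed)
}

# balanced nested layout for mixed-model oracles:
# g groups x units_per_group units x reps observations per unit
balanced_oneway <- function(means, units_per_group = 12, reps = 2,
                            unit_sd = 15, resid_sd = 10, seed = 1) {
  set.seed(seed)
  g <- factor(rep(names(means), each = units_per_group * reps))
  unit <- factor(rep(seq_len(length(means) * units_per_group), each = reps))
  u <- rnorm(nlevels(unit), 0, unit_sd)
  data.frame(g = g, unit = unit,
             y = unlist(means)[as.character(g)] + u[unit] +
               rnorm(length(g), 0, resid_sd))
}

# trial table built directly (bypasses the simulator) for preprocess tests
trial_rows <- function(rt, accuracy = TRUE, responded = !is.na(rt),
                       study = "s1", participant = "p1",
                       target = "arrows", congruency = "congruent") {
  n <- length(rt)
  data.frame(study_id = rep_len(study, n),
             participant_id = rep_len(participant, n),
             target_type = rep_len(target, n),
             congruency = rep_len(congruency, n),
             rt_ms = rt,
             accuracy = rep_len(accuracy, n),
             responded = rep_len(responded, n),
             stringsAsFactors = FALSE)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
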