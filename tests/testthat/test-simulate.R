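test_that("trial events respect the task rules and configured timing", {
  cfg <- simulation_config(seed = 1)
  cfg$event_timing$jitter[] <- 0

  set.seed(1)
  go <- simulate_trial_events(cfg, "execution", "go", "ring")
  ev <- as.numeric(go[, c("cue_onset", "object_presentation", "go_nogo_signal",
                          "movement_onset", "pulling_onset")])
  expect_equal(ev, unname(cfg$event_timing$means))
  expect_true(all(diff(ev) > 0))

  nogo <- simulate_trial_events(cfg, "observation", "nogo", "big_cone")
  expect_true(is.na(nogo$movement_onset))
  expect_true(is.na(nogo$pulling_onset))
  expect_false(is.na(nogo$go_nogo_signal))

  expect_error(simulate_trial_events(cfg, "imagination", "go", "ring"),
               "invalid task")
  expect_error(simulate_trial_events(cfg, "execution", "maybe", "ring"),
               "invalid condition")
  expect_error(simulate_trial_events(cfg, "execution", "go", "banana"),
               "invalid object")
})

test_that("jittered event order is always preserved and means are unbiased", {
  cfg <- simulation_config(seed = 1)
  set.seed(99)
  mov <- replicate(1000, {
    tr <- simulate_trial_events(cfg, "execution", "go", "ring")
    ev <- as.numeric(tr[, c("cue_onset", "object_presentation",
                            "go_nogo_signal", "movement_onset",
                            "pulling_onset")])
    expect_true(all(diff(ev) > 0))
    tr$movement_onset
  })
  # Monte-Carlo mean against the configured mean (jitter accumulates over
  # the four inter-event intervals)
  sem <- stats::sd(mov) / sqrt(length(mov))
  expect_lt(abs(mean(mov) - cfg$event_timing$means[["movement_onset"]]),
            3 * sem + 1e-12)
})

test_that("rate profile obeys the category and gain rules", {
  cfg <- simulation_config(seed = 1)
  cfg$event_timing$jitter[] <- 0
  set.seed(2)
  trial_of <- function(task, condition = "go")
    simulate_trial_events(cfg, task, condition, "ring")
  grid <- seq(0, 5, by = 0.01)

  unit <- list(category = "SOT_object", baseline = 10, preferred_object = "ring",
               suppressed = FALSE)

  # identity gains: rate identically baseline
  cfg1 <- cfg; cfg1$modulation_gain <- 1; cfg1$object_tuning <- c(1, 1, 1)
  cfg1$go_gain <- 1
  expect_equal(unit_rate_profile(unit, trial_of("execution"), grid, cfg1),
               rep(10, length(grid)))

  # ST object unit reverts to baseline out of the execution task
  st <- unit; st$category <- "ST_object"
  expect_equal(unit_rate_profile(st, trial_of("observation"), grid, cfg),
               rep(10, length(grid)))
  # all object categories are flat in the extrapersonal task
  expect_equal(unit_rate_profile(unit, trial_of("extrapersonal"), grid, cfg),
               rep(10, length(grid)))
  # but an SOT object unit modulates in observation
  expect_gt(max(unit_rate_profile(unit, trial_of("observation"), grid, cfg)), 10)

  # self_bias = 1: execution and observation profiles identical
  cfg_sym <- cfg; cfg_sym$self_bias <- 1
  expect_equal(unit_rate_profile(unit, trial_of("execution"), grid, cfg_sym),
               unit_rate_profile(unit, trial_of("observation"), grid, cfg_sym))

  # suppressed units modulate downward and never below zero
  sup <- unit; sup$suppressed <- TRUE
  r <- unit_rate_profile(sup, trial_of("execution"), grid, cfg)
  expect_true(all(r >= 0))
  expect_lt(min(r), 10)
  expect_true(all(r <= 10 + 1e-12))

  # action units are silent in No-Go trials (no movement window)
  act <- unit; act$category <- "SOT_action"
  expect_equal(unit_rate_profile(act, trial_of("execution", "nogo"), grid, cfg),
               rep(10, length(grid)))

  expect_error(unit_rate_profile(list(category = "both", baseline = -1,
                                      preferred_object = "ring",
                                      suppressed = FALSE),
                                 trial_of("execution"), grid, cfg),
               "negative baseline")
})

test_that("generated datasets are seeded-deterministic with the full design", {
  cfg <- simulation_config(n_units_per_category = c(
    ST_action = 1L, OT_action = 0L, SOT_action = 1L, ST_object = 0L,
    OT_object = 1L, SOT_object = 0L, both = 0L, unresponsive = 1L),
    seed = 7L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$ground_truth, b$ground_truth)

  # 3 tasks x 2 conditions x 3 objects x 12 trials
  expect_equal(nrow(a$trials), 216)
  cells <- table(a$trials$task, a$trials$condition, a$trials$object)
  expect_true(all(cells == 12))
  # No-Go trials never carry movement events; spikes stay in the trial span
  nogo <- a$trials[a$trials$condition == "nogo", ]
  expect_true(all(is.na(nogo$movement_onset)) && all(is.na(nogo$pulling_onset)))
  expect_true(all(a$spikes$spike_time >= 0))
})

test_that("constant-rate units are Poisson-consistent", {
  cfg <- simulation_config(seed = 3)
  unit <- list(unit_id = "x", category = "unresponsive", baseline = 10,
               preferred_object = "ring", suppressed = FALSE)
  trial <- data.frame(task = "execution", condition = "go", object = "ring",
                      cue_onset = 0.8, object_presentation = 1.8,
                      go_nogo_signal = 3.0, movement_onset = 3.5,
                      pulling_onset = 4.2)
  span <- 4.8
  set.seed(11)
  counts <- replicate(500, length(mirrorpop:::sample_spikes(unit, trial, span, cfg)))
  # total count within 4 SD of the Poisson expectation (10 Hz x 2400 s)
  expected <- 10 * span * 500
  expect_lt(abs(sum(counts) - expected), 4 * sqrt(expected))
  # Fano factor of per-trial counts near 1
  fano <- stats::var(counts) / mean(counts)
  expect_gt(fano, 0.8); expect_lt(fano, 1.2)
})

test_that("ground-truth expected rates match empirical rates", {
  cfg <- simulation_config(seed = 5)
  cfg$event_timing$jitter[] <- 0
  ds_units <- data.frame(unit_id = c("a", "b"),
                         category = c("SOT_object", "ST_action"),
                         preferred_object = "ring",
                         suppressed = c(FALSE, TRUE),
                         baseline = c(8, 12), stringsAsFactors = FALSE)
  expected <- mirrorpop:::expected_epoch_rates(ds_units, cfg)
  set.seed(21)
  trial <- simulate_trial_events(cfg, "execution", "go", "ring")
  for (u in 1:2) {
    unit <- ds_units[u, ]
    # 500 replicate Go/ring trials in execution
    rates <- replicate(500, {
      st <- mirrorpop:::sample_spikes(unit, trial, 5.2, cfg)
      vapply(epoch_windows(trial), function(w) epoch_rate(st, w), numeric(1))
    })
    for (ep in rownames(rates)) {
      # expected table averages the three objects; recompute for ring only
      grid <- seq(epoch_windows(trial)[[ep]][1],
                  epoch_windows(trial)[[ep]][2] - 5e-4, by = 0.001)
      exp_ring <- mean(unit_rate_profile(unit, trial, grid, cfg))
      sem <- stats::sd(rates[ep, ]) / sqrt(ncol(rates))
      expect_lt(abs(mean(rates[ep, ]) - exp_ring), 3 * sem + 0.15)
    }
  }
  # bookkeeping covers every unit/task/epoch exactly once
  expect_equal(nrow(expected), 2 * 3 * 5)
  expect_true(all(expected$expected_rate >= 0))
})
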