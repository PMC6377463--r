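# Synthetic spike-train generator: Poisson units with epoch-locked,
# agent-specific and object-selective rate modulation over the three task
# contexts (execution, observation, extrapersonal), Go/No-Go conditions and
# three graspable objects.

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic dataset generator.
#' Units fall into eight ground-truth categories crossing the response domain
#' (action-related, object-related, both, unresponsive) with the agent type:
#' self-type (ST, responds only when the monkey acts), other-type (OT, only
#' when the experimenter acts) and self-and-other-type (SOT, both).
#'
#' @param n_units_per_category named integer vector giving the number of units
#'   for each of `ST_action`, `OT_action`, `SOT_action`, `ST_object`,
#'   `OT_object`, `SOT_object`, `both`, `unresponsive`.
#' @param baseline_rate_range baseline firing-rate interval (spikes/s); each
#'   unit draws its baseline uniformly from it.
#' @param modulation_gain multiplicative rate factor applied in a unit's
#'   response window for its preferred object.
#' @param object_tuning length-3 positive vector of relative gains for the
#'   preferred object and the two non-preferred objects.
#' @param go_gain multiplicative Go-vs-No-Go factor applied to object-related
#'   responses during object presentation.
#' @param suppressed_fraction proportion of responsive units whose modulation
#'   is a rate decrease (gain inverted, floored at zero by construction).
#' @param trials_per_condition correct trials per (task, condition, object)
#'   cell; 12 by default.
#' @param event_timing list with `means` and `jitter` (seconds) for
#'   `cue_onset`, `object_presentation`, `go_nogo_signal`, `movement_onset`,
#'   `pulling_onset`, plus `min_gap`, the smallest admissible inter-event
#'   interval. Jitter is applied to inter-event intervals as a truncated
#'   normal so the event order is preserved by construction.
#' @param self_bias execution-vs-observation modulation-amplitude ratio for
#'   SOT (and `both`) units; 1 means agent-invariant responses.
#' @param object_window_duration duration (s) of the object-presentation
#'   response window.
#' @param ramp duration (s) of the linear ramps at response-window edges.
#' @param post_event_padding recording time (s) kept after the last trial
#'   event; defines the trial span.
#' @param tasks task contexts to simulate; all three by default.
#' @param seed integer RNG seed; mandatory for reproducible pipelines.
#' @return an object of class `mirrorpop_simconfig`.
#' @export
simulation_config <- function(n_units_per_category = c(
                                ST_action = 6L, OT_action = 6L, SOT_action = 6L,
                                ST_object = 6L, OT_object = 6L, SOT_object = 6L,
                                both = 4L, unresponsive = 8L),
                              baseline_rate_range = c(5, 15),
                              modulation_gain = 3,
                              object_tuning = c(1, 0.4, 0.4),
                              go_gain = 1.5,
                              suppressed_fraction = 0.2,
                              trials_per_condition = 12L,
                              event_timing = list(
                                means = c(cue_onset = 0.8,
                                          object_presentation = 1.8,
                                          go_nogo_signal = 3.0,
                                          movement_onset = 3.5,
                                          pulling_onset = 4.2),
                                jitter = c(cue_onset = 0.05,
                                           object_presentation = 0.05,
                                           go_nogo_signal = 0.05,
                                           movement_onset = 0.08,
                                           pulling_onset = 0.08),
                                min_gap = 0.05),
                              self_bias = 1.3,
                              object_window_duration = 0.8,
                              ramp = 0.1,
                              post_event_padding = 1.0,
                              tasks = TASKS,
                              seed = 1L) {
  cfg <- list(n_units_per_category = n_units_per_category,
              baseline_rate_range = baseline_rate_range,
              modulation_gain = modulation_gain,
              object_tuning = object_tuning,
              go_gain = go_gain,
              suppressed_fraction = suppressed_fraction,
              trials_per_condition = as.integer(trials_per_condition),
              event_timing = event_timing,
              self_bias = self_bias,
              object_window_duration = object_window_duration,
              ramp = ramp,
              post_event_padding = post_event_padding,
              tasks = match.arg(tasks, TASKS, several.ok = TRUE),
              seed = as.integer(seed))
  class(cfg) <- "mirrorpop_simconfig"
  validate_simconfig(cfg)
}

#' @keywords internal
validate_simconfig <- function(cfg) {
  stopifnot(inherits(cfg, "mirrorpop_simconfig"))
  miss <- setdiff(UNIT_CATEGORIES, names(cfg$n_units_per_category))
  if (length(miss) > 0)
    stop("n_units_per_category missing categories: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (cfg$trials_per_condition < 2L)
    stop("trials_per_condition must be >= 2", call. = FALSE)
  if (any(cfg$baseline_rate_range < 0) || diff(cfg$baseline_rate_range) < 0)
    stop("baseline_rate_range must be a non-negative increasing interval",
         call. = FALSE)
  if (any(cfg$object_tuning <= 0)) stop("object_tuning gains must be positive",
                                        call. = FALSE)
  if (cfg$go_gain <= 0) stop("go_gain must be positive", call. = FALSE)
  if (any(cfg$event_timing$jitter < 0)) stop("jitters must be >= 0", call. = FALSE)
  ev <- cfg$event_timing$means
  need <- c("cue_onset", "object_presentation", "go_nogo_signal",
            "movement_onset", "pulling_onset")
  if (!all(need %in% names(ev)))
    stop("event_timing$means must name all five events", call. = FALSE)
  if (any(diff(ev[need]) <= 0))
    stop("event timing means must be strictly increasing in task order",
         call. = FALSE)
  if (cfg$suppressed_fraction < 0 || cfg$suppressed_fraction > 1)
    stop("suppressed_fraction must be in [0, 1]", call. = FALSE)
  cfg
}

# Truncated-normal draw (lower bound only), by rejection; sd may be 0.
#' @keywords internal
rtnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

#' Simulate the event timestamps of one trial
#'
#' Draws a jittered but strictly ordered event sequence: cue onset, object
#' presentation (light on), Go/No-Go signal (sound stops), then, for Go trials
#' only, movement onset and pulling onset. In the execution task the monkey
#' acts; in the observation and extrapersonal tasks the experimenter does, so
#' Go-trial movement events exist in all three tasks. No-Go trials have no
#' movement events (encoded as `NA`, never as zero).
#'
#' @param config a [simulation_config()].
#' @param task one of `execution`, `observation`, `extrapersonal`.
#' @param condition `go` or `nogo`.
#' @param object one of `ring`, `small_cone`, `big_cone`.
#' @return one-row data frame with the trial labels and timestamps (seconds,
#'   relative to trial start).
#' @export
simulate_trial_events <- function(config, task, condition, object) {
  assert_label(task, TASKS, "task")
  assert_label(condition, CONDITIONS, "condition")
  assert_label(object, OBJECTS, "object")
  ev <- config$event_timing
  order_names <- c("cue_onset", "object_presentation", "go_nogo_signal",
                   "movement_onset", "pulling_onset")
  means <- ev$means[order_names]
  jit <- ev$jitter[order_names]
  # jitter inter-event intervals (truncated below at min_gap) so that the
  # event order cannot be violated by sampling
  times <- rtnorm_lower(1, means[1], jit[1], ev$min_gap)
  for (i in 2:5) {
    gap <- rtnorm_lower(1, means[i] - means[i - 1], jit[i], ev$min_gap)
    times <- c(times, times[i - 1] + gap)
  }
  names(times) <- order_names
  if (condition == "nogo") times[c("movement_onset", "pulling_onset")] <- NA_real_
  data.frame(task = task, condition = condition, object = object,
             cue_onset = times[["cue_onset"]],
             object_presentation = times[["object_presentation"]],
             go_nogo_signal = times[["go_nogo_signal"]],
             movement_onset = times[["movement_onset"]],
             pulling_onset = times[["pulling_onset"]],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Trapezoidal activation profile: 0 outside [start, end], linear 100-ms ramps
# inside the window edges, 1 on the plateau.
#' @keywords internal
trapezoid <- function(t, start, end, ramp) {
  if (is.na(start) || is.na(end) || end <= start) return(numeric(length(t)))
  r <- min(ramp, (end - start) / 2)
  up <- pmin(pmax((t - start) / max(r, 1e-9), 0), 1)
  down <- pmin(pmax((end - t) / max(r, 1e-9), 0), 1)
  pmin(up, down)
}

# Which tasks a category responds in, per domain.
#' @keywords internal
responds_in_task <- function(category, domain, task) {
  if (domain == "action") {
    switch(category,
           ST_action = task == "execution",
           OT_action = task %in% c("observation", "extrapersonal"),
           SOT_action = TRUE,
           both = TRUE,
           FALSE)
  } else {
    # object-related responses are confined to the monkey's peripersonal
    # space: every object category is flat in the extrapersonal task
    if (task == "extrapersonal") return(FALSE)
    switch(category,
           ST_object = task == "execution",
           OT_object = task == "observation",
           SOT_object = TRUE,
           both = TRUE,
           FALSE)
  }
}

#' Firing-rate profile of one unit on one trial
#'
#' Piecewise rate model: baseline multiplied by the category/epoch/task gain,
#' the object-tuning gain and (for object responses in Go trials) the Go gain,
#' with linear ramps at the response-window edges. SOT units scale their
#' modulation amplitude by `self_bias` in the execution task. Suppressed
#' units modulate downward (inverted gain), which keeps rates non-negative.
#'
#' @param unit one-row list or data frame with `category`, `baseline`,
#'   `preferred_object`, `suppressed`.
#' @param trial one-row trial record as from [simulate_trial_events()].
#' @param time_grid numeric vector of times (s, trial-relative).
#' @param config the [simulation_config()] the unit was drawn under.
#' @return numeric vector of rates (spikes/s), one per grid point.
#' @export
unit_rate_profile <- function(unit, trial, time_grid, config) {
  if (unit$baseline < 0) stop("negative baseline rate", call. = FALSE)
  gain_total <- rep(1, length(time_grid))
  obj_gain <- object_gain_for(unit, trial$object, config)
  amp <- function(a) {
    # execution-vs-observation amplitude ratio for agent-invariant categories
    if (unit$category %in% c("SOT_action", "SOT_object", "both") &&
        trial$task == "execution") 1 + (a - 1) * config$self_bias else a
  }
  if (responds_in_task(unit$category, "object", trial$task) &&
      unit$category %in% c("ST_object", "OT_object", "SOT_object", "both")) {
    a <- config$modulation_gain * obj_gain *
      (if (trial$condition == "go") config$go_gain else 1)
    m <- trapezoid(time_grid, trial$object_presentation,
                   trial$object_presentation + config$object_window_duration,
                   config$ramp)
    gain_total <- gain_total * (1 + (amp(a) - 1) * m)
  }
  if (responds_in_task(unit$category, "action", trial$task) &&
      unit$category %in% c("ST_action", "OT_action", "SOT_action", "both") &&
      !is.na(trial$movement_onset)) {
    a <- config$modulation_gain * obj_gain
    m <- trapezoid(time_grid, trial$movement_onset - 0.5,
                   trial$pulling_onset + 0.5, config$ramp)
    gain_total <- gain_total * (1 + (amp(a) - 1) * m)
  }
  rate <- if (isTRUE(unit$suppressed)) unit$baseline / gain_total
          else unit$baseline * gain_total
  pmax(rate, 0)
}

#' @keywords internal
object_gain_for <- function(unit, object, config) {
  if (unit$category == "unresponsive") return(1)
  others <- setdiff(OBJECTS, unit$preferred_object)
  gains <- c(config$object_tuning[1],
             config$object_tuning[2], config$object_tuning[3])
  names(gains) <- c(unit$preferred_object, others)
  unname(gains[object])
}

#' @keywords internal
trial_span <- function(trial, padding) {
  last_ev <- max(trial$cue_onset, trial$object_presentation,
                 trial$go_nogo_signal, trial$movement_onset,
                 trial$pulling_onset, na.rm = TRUE)
  last_ev + padding
}

# Inhomogeneous Poisson sampling by thinning against an upper rate bound.
# Suppressed and unresponsive units never exceed baseline, so their bound is
# tight and thinning wastes no draws on them.
#' @keywords internal
sample_spikes <- function(unit, trial, span, config) {
  if (unit$category == "unresponsive" || isTRUE(unit$suppressed)) {
    bound <- unit$baseline + 1e-9
  } else {
    g <- config$modulation_gain * max(config$object_tuning) * config$go_gain
    bound <- unit$baseline * (1 + (g - 1) * max(1, config$self_bias)) + 1e-9
  }
  n <- stats::rpois(1, bound * span)
  if (n == 0) return(numeric(0))
  t <- stats::runif(n, 0, span)
  keep <- stats::runif(n) < unit_rate_profile(unit, trial, t, config) / bound
  sort(t[keep])
}

#' Generate a full synthetic dataset
#'
#' Builds the unit population from the category counts, simulates
#' `trials_per_condition` correct trials for every (task, condition, object)
#' cell, and samples spikes from each unit's inhomogeneous Poisson rate
#' profile. Output is byte-identical under a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return an object of class `mirrorpop_dataset`: list with `trials`,
#'   `spikes`, `units` data frames, a `ground_truth` list (`units` with
#'   category/preferred object/suppression labels and `expected_rates` per
#'   unit, task and epoch on Go trials) and the generating `config`.
#' @export
generate_dataset <- function(config) {
  validate_simconfig(config)
  set.seed(config$seed)
  units_gt <- build_unit_population(config)

  tasks <- if (is.null(config$tasks)) TASKS else config$tasks
  design <- expand.grid(rep = seq_len(config$trials_per_condition),
                        object = OBJECTS, condition = CONDITIONS, task = tasks,
                        stringsAsFactors = FALSE)
  trials <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    tr <- simulate_trial_events(config, design$task[i], design$condition[i],
                                design$object[i])
    tr$trial_id <- i
    tr
  }))
  trials <- trials[, c("trial_id", "task", "condition", "object", "cue_onset",
                       "object_presentation", "go_nogo_signal",
                       "movement_onset", "pulling_onset")]

  spans <- vapply(seq_len(nrow(trials)), function(i)
    trial_span(trials[i, ], config$post_event_padding), numeric(1))

  trial_rows <- split(trials, seq_len(nrow(trials)))
  unit_rows <- split(units_gt, seq_len(nrow(units_gt)))
  n_cells <- nrow(units_gt) * nrow(trials)
  st_list <- vector("list", n_cells)
  uid <- character(n_cells); tid <- integer(n_cells)
  k <- 0L
  for (u in seq_along(unit_rows)) {
    unit <- unit_rows[[u]]
    for (i in seq_along(trial_rows)) {
      k <- k + 1L
      st_list[[k]] <- sample_spikes(unit, trial_rows[[i]], spans[i], config)
      uid[k] <- unit$unit_id
      tid[k] <- trials$trial_id[i]
    }
  }
  n_per_cell <- lengths(st_list)
  spikes <- data.frame(unit_id = rep(uid, n_per_cell),
                       trial_id = rep(tid, n_per_cell),
                       spike_time = unlist(st_list, use.names = FALSE),
                       stringsAsFactors = FALSE)

  units <- data.frame(unit_id = units_gt$unit_id, subject = "M1",
                      session = 1L, channel = seq_len(nrow(units_gt)),
                      stringsAsFactors = FALSE)
  gt <- list(units = units_gt[, c("unit_id", "category", "preferred_object",
                                  "suppressed", "baseline")],
             expected_rates = expected_epoch_rates(units_gt, config))
  out <- list(trials = trials, spikes = spikes, units = units,
              ground_truth = gt, config = config)
  class(out) <- "mirrorpop_dataset"
  out
}

#' @keywords internal
build_unit_population <- function(config) {
  rows <- list()
  idx <- 0L
  for (cat in UNIT_CATEGORIES) {
    n <- config$n_units_per_category[[cat]]
    if (n == 0) next
    n_sup <- if (cat == "unresponsive") 0L else round(config$suppressed_fraction * n)
    for (j in seq_len(n)) {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        unit_id = sprintf("u%03d", idx),
        category = cat,
        preferred_object = OBJECTS[(j - 1L) %% 3L + 1L],
        suppressed = j <= n_sup,
        baseline = stats::runif(1, config$baseline_rate_range[1],
                                config$baseline_rate_range[2]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Expected Go-trial firing rate per (unit, task, epoch), evaluated on the
# jitter-free rate profile so it is exact for the generator's own model.
#' @keywords internal
expected_epoch_rates <- function(units_gt, config) {
  means <- config$event_timing$means
  proto <- data.frame(task = NA_character_, condition = "go",
                      object = NA_character_,
                      cue_onset = means[["cue_onset"]],
                      object_presentation = means[["object_presentation"]],
                      go_nogo_signal = means[["go_nogo_signal"]],
                      movement_onset = means[["movement_onset"]],
                      pulling_onset = means[["pulling_onset"]],
                      stringsAsFactors = FALSE)
  tasks <- if (is.null(config$tasks)) TASKS else config$tasks
  grid_step <- 0.001
  rows <- list(); k <- 0L
  for (u in seq_len(nrow(units_gt))) {
    unit <- units_gt[u, ]
    if (unit$category == "unresponsive") {
      for (task in tasks) for (ep in c(EPOCHS_ACTION, "object_presentation")) {
        k <- k + 1L
        rows[[k]] <- data.frame(unit_id = unit$unit_id, task = task,
                                epoch = ep, expected_rate = unit$baseline,
                                stringsAsFactors = FALSE)
      }
      next
    }
    for (task in tasks) {
      tr <- proto; tr$task <- task
      # average the three objects, as the epoch analyses do
      win <- epoch_windows(tr)
      for (ep in names(win)) {
        vals <- vapply(OBJECTS, function(obj) {
          tr$object <- obj
          g <- seq(win[[ep]][1], win[[ep]][2] - grid_step / 2, by = grid_step)
          mean(unit_rate_profile(unit, tr, g, config))
        }, numeric(1))
        k <- k + 1L
        rows[[k]] <- data.frame(unit_id = unit$unit_id, task = task,
                                epoch = ep, expected_rate = mean(vals),
                                stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.mirrorpop_dataset <- function(x, ...) {
  cat("mirrorpop synthetic dataset\n")
  cat(sprintf("  units:  %d (%s)\n", nrow(x$units),
              paste(sprintf("%s=%d", names(table(x$ground_truth$units$category)),
                            table(x$ground_truth$units$category)), collapse = ", ")))
  cat(sprintf("  trials: %d (%d tasks x %d conditions x %d objects x %d reps)\n",
              nrow(x$trials), length(unique(x$trials$task)),
              length(unique(x$trials$condition)),
              length(unique(x$trials$object)), x$config$trials_per_condition))
  cat(sprintf("  spikes: %d\n", nrow(x$spikes)))
  invisible(x)
}
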