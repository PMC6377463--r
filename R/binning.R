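# Epoch-of-interest extraction and sliding-window binning. All window
# arithmetic is in seconds with half-open intervals [start, end): a spike on
# a right edge belongs to the next bin, so non-overlapping partitions
# conserve spikes.

#' Epochs of interest for one trial
#'
#' Named analysis windows, each `[start, end)` in trial-relative seconds:
#' `baseline` (0.5 s before object presentation), `object_presentation`
#' (0 to 0.5 s after the light goes on), `premovement` (0.5 s before
#' reaching onset), `reaching_grasping` (reaching onset to pulling onset,
#' variable duration, trial by trial) and `holding` (0.5 s after pulling
#' onset). Movement-anchored windows exist only when the trial has a
#' movement onset (Go trials).
#'
#' @param trial one-row trial record.
#' @return named list of length-2 numeric vectors (start, end).
#' @export
epoch_windows <- function(trial) {
  op <- trial$object_presentation
  win <- list(baseline = c(op - 0.5, op),
              object_presentation = c(op, op + 0.5))
  if (!is.na(trial$movement_onset)) {
    win$premovement <- c(trial$movement_onset - 0.5, trial$movement_onset)
    win$reaching_grasping <- c(trial$movement_onset, trial$pulling_onset)
    win$holding <- c(trial$pulling_onset, trial$pulling_onset + 0.5)
  }
  win
}

#' Firing rate in one window
#'
#' Spike count in the half-open window `[start, end)` divided by the window
#' duration.
#'
#' @param spike_times numeric vector of spike times (s) for one unit on one
#'   trial.
#' @param window length-2 numeric (start, end), end > start.
#' @return rate in spikes/s.
#' @export
epoch_rate <- function(spike_times, window) {
  dur <- window[2] - window[1]
  if (!is.finite(dur) || dur <= 0)
    stop("epoch window must have positive duration", call. = FALSE)
  count_in_window(spike_times, window[1], window[2]) / dur
}

#' Per-trial epoch rates for a set of units
#'
#' Long table of firing rates per (unit, trial, epoch), the input format of
#' the single-unit ANOVAs.
#'
#' @param dataset a `mirrorpop_dataset` (or any list with `trials` and
#'   `spikes` in the package's tabular schema).
#' @param unit_ids units to include; default all units present in `spikes`.
#' @param trial_ids trials to include; default all.
#' @return data frame with unit_id, trial_id, task, condition, object,
#'   epoch, rate.
#' @export
epoch_rate_table <- function(dataset, unit_ids = NULL, trial_ids = NULL) {
  trials <- dataset$trials
  if (!is.null(trial_ids)) trials <- trials[trials$trial_id %in% trial_ids, ]
  if (is.null(unit_ids)) unit_ids <- unique(dataset$spikes$unit_id)
  sp <- dataset$spikes[dataset$spikes$unit_id %in% unit_ids &
                         dataset$spikes$trial_id %in% trials$trial_id, ]
  key <- paste(sp$unit_id, sp$trial_id, sep = "\r")
  spl <- split(sp$spike_time, key)
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    win <- epoch_windows(tr)
    ep_names <- names(win)
    starts <- vapply(win, `[`, numeric(1), 1)
    ends <- vapply(win, `[`, numeric(1), 2)
    durs <- ends - starts
    block <- vector("list", length(unit_ids))
    for (u in seq_along(unit_ids)) {
      st <- spl[[paste(unit_ids[u], tr$trial_id, sep = "\r")]]
      if (is.null(st)) st <- numeric(0)
      st <- sort(st)
      rates <- bin_counts(st, starts, ends) / durs
      block[[u]] <- data.frame(unit_id = unit_ids[u], trial_id = tr$trial_id,
                               task = tr$task, condition = tr$condition,
                               object = tr$object, epoch = ep_names,
                               rate = rates, stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, block)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sliding-window binned firing rates
#'
#' Rates on a grid of (possibly overlapping) bins aligned to a named trial
#' event. Each bin is `[center - width/2, center + width/2)`. Trials lacking
#' the alignment event are excluded with a warning.
#'
#' @param dataset a `mirrorpop_dataset`-like list with `trials` and `spikes`.
#' @param align_event column name of the alignment event (e.g.
#'   `"object_presentation"`, `"movement_onset"`).
#' @param range length-2 numeric: first and last bin center (s) relative to
#'   the alignment event.
#' @param bin_width bin width (s); must satisfy `bin_width >= step > 0`.
#' @param step distance between consecutive bin centers (s).
#' @param unit_ids,trial_ids optional subsets.
#' @return object of class `mirrorpop_binned`: list with `rates`
#'   (unit x trial x bin array, spikes/s), `bin_centers`, `bin_width`,
#'   `step`, `align_event`, `unit_ids`, `trial_ids`, and `segments`
#'   bookkeeping (one segment here; see [dual_align()]).
#' @export
sliding_binned_rates <- function(dataset, align_event, range,
                                 bin_width, step,
                                 unit_ids = NULL, trial_ids = NULL) {
  if (!(bin_width >= step && step > 0))
    stop("need bin_width >= step > 0", call. = FALSE)
  trials <- dataset$trials
  if (!is.null(trial_ids)) trials <- trials[trials$trial_id %in% trial_ids, ]
  if (!align_event %in% names(trials))
    stop("unknown alignment event: ", align_event, call. = FALSE)
  missing_ev <- is.na(trials[[align_event]])
  if (any(missing_ev)) {
    warning(sprintf("%d trial(s) lack event '%s' and were excluded",
                    sum(missing_ev), align_event), call. = FALSE)
    trials <- trials[!missing_ev, ]
  }
  if (is.null(unit_ids)) unit_ids <- unique(dataset$spikes$unit_id)
  centers <- seq(range[1], range[2] + 1e-12, by = step)
  n_bin <- length(centers)
  rates <- array(0, dim = c(length(unit_ids), nrow(trials), n_bin),
                 dimnames = list(unit_ids, trials$trial_id, NULL))
  sp <- dataset$spikes[dataset$spikes$unit_id %in% unit_ids &
                         dataset$spikes$trial_id %in% trials$trial_id, ]
  key <- paste(sp$unit_id, sp$trial_id, sep = "\r")
  spl <- split(sp$spike_time, key)
  for (i in seq_len(nrow(trials))) {
    t0 <- trials[[align_event]][i]
    starts <- t0 + centers - bin_width / 2
    ends <- t0 + centers + bin_width / 2
    for (u in seq_along(unit_ids)) {
      st <- spl[[paste(unit_ids[u], trials$trial_id[i], sep = "\r")]]
      if (is.null(st) || length(st) == 0) next
      rates[u, i, ] <- bin_counts(sort(st), starts, ends) / bin_width
    }
  }
  structure(list(rates = rates, bin_centers = centers, bin_width = bin_width,
                 step = step, align_event = align_event, unit_ids = unit_ids,
                 trial_ids = trials$trial_id,
                 trial_info = trials[, c("trial_id", "task", "condition", "object")],
                 segments = data.frame(segment = 1L, align_event = align_event,
                                       n_bins = n_bin,
                                       stringsAsFactors = FALSE)),
            class = "mirrorpop_binned")
}

#' Concatenate two alignments of the same trials with an explicit gap
#'
#' Joins two binned segments (e.g. aligned to object presentation, then to
#' movement onset or the Go/No-Go signal) along the bin axis. The junction is
#' recorded so downstream statistics are never computed across the gap.
#'
#' @param binned_a,binned_b `mirrorpop_binned` objects over identical unit and
#'   trial sets.
#' @return `mirrorpop_binned` with concatenated bins, a `segments` table and
#'   `gap_after`, the bin index after which the gap sits.
#' @export
dual_align <- function(binned_a, binned_b) {
  if (!identical(binned_a$unit_ids, binned_b$unit_ids))
    stop("dual_align: unit sets differ", call. = FALSE)
  if (!identical(sort(binned_a$trial_ids), sort(binned_b$trial_ids)))
    stop("dual_align: trial sets differ", call. = FALSE)
  # reorder B's trials to match A
  idx <- match(binned_a$trial_ids, binned_b$trial_ids)
  rb <- binned_b$rates[, idx, , drop = FALSE]
  out <- binned_a
  out$rates <- array(c(binned_a$rates, rb),
                     dim = c(dim(binned_a$rates)[1], dim(binned_a$rates)[2],
                             dim(binned_a$rates)[3] + dim(rb)[3]),
                     dimnames = list(binned_a$unit_ids, binned_a$trial_ids, NULL))
  out$bin_centers <- c(binned_a$bin_centers, binned_b$bin_centers)
  out$align_event <- c(binned_a$align_event, binned_b$align_event)
  out$gap_after <- dim(binned_a$rates)[3]
  seg_b <- binned_b$segments
  seg_b$segment <- seg_b$segment + max(binned_a$segments$segment)
  out$segments <- rbind(binned_a$segments, seg_b)
  out
}

#' @export
print.mirrorpop_binned <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("mirrorpop binned activity: %d units x %d trials x %d bins\n",
              d[1], d[2], d[3]))
  cat(sprintf("  bin width %.0f ms, step %.0f ms, aligned to %s%s\n",
              1000 * x$bin_width, 1000 * x$step,
              paste(x$align_event, collapse = " + "),
              if (!is.null(x$gap_after)) sprintf(" (gap after bin %d)", x$gap_after)
              else ""))
  invisible(x)
}
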