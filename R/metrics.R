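# Per-unit response parameters on Go trials: peak rate and timing of the
# trial-averaged 20-ms-binned response, burst duration by the 66%-of-peak
# rule, and the object preference index with its label-shuffle null.
#
# Reference windows: action-related units use [-0.5, +0.8] s around movement
# onset; object-related units use [0, +0.8] s after object presentation.

METRIC_WINDOWS <- list(action = list(event = "movement_onset", range = c(-0.5, 0.8)),
                       object = list(event = "object_presentation", range = c(0, 0.8)))

# Trial-averaged rate in contiguous 20-ms bins over the domain's reference
# window, averaging the 36 Go trials (12 per object).
#' @keywords internal
metric_binned_average <- function(dataset, unit_id, task, domain,
                                  bin_width = 0.02) {
  w <- METRIC_WINDOWS[[domain]]
  go <- dataset$trials$trial_id[dataset$trials$task == task &
                                  dataset$trials$condition == "go"]
  centers <- seq(w$range[1] + bin_width / 2, w$range[2] - bin_width / 2 + 1e-9,
                 by = bin_width)
  b <- sliding_binned_rates(dataset, w$event,
                            range = c(centers[1], centers[length(centers)]),
                            bin_width = bin_width, step = bin_width,
                            unit_ids = unit_id, trial_ids = go)
  list(avg = apply(b$rates[1, , , drop = FALSE], 3, mean),
       centers = b$bin_centers, binned = b)
}

#' Peak of activity and its timing
#'
#' The highest value (spikes/s) of the trial-averaged 20-ms-binned rate
#' within the domain's reference window, and the time of that bin relative
#' to the reference event. Ties go to the earliest bin.
#'
#' @param dataset a `mirrorpop_dataset`.
#' @param unit_id,task unit and task (Go trials only).
#' @param domain `"action"` (window around movement onset) or `"object"`
#'   (window after object presentation).
#' @return list with `peak_rate`, `peak_time`, and `flagged` (TRUE when the
#'   unit fired no spikes in the window, in which case the peak is 0 at the
#'   earliest bin).
#' @export
peak_activity <- function(dataset, unit_id, task, domain = c("action", "object")) {
  domain <- match.arg(domain)
  ba <- metric_binned_average(dataset, unit_id, task, domain)
  peak_from_average(ba$avg, ba$centers)
}

#' @keywords internal
peak_from_average <- function(avg, centers) {
  idx <- which.max(avg)  # earliest bin on ties
  list(peak_rate = avg[idx], peak_time = centers[idx], peak_index = idx,
       flagged = avg[idx] == 0)
}

#' Burst duration around the peak
#'
#' Scanning outward from the peak bin, finds the first bin before and after
#' the peak whose value falls below 66% of the peak; the burst duration is
#' the time lag between those two bins. If no sub-threshold bin exists
#' before a window edge, the edge bin is used and the result is flagged as
#' censored.
#'
#' @param avg trial-averaged binned rates (20-ms bins).
#' @param centers bin centers (s, relative to the reference event).
#' @param peak result of [peak_from_average()] on the same average.
#' @param threshold fraction of the peak defining the burst bounds
#'   (default 0.66).
#' @return list with `duration` (s; `NA` if the peak is 0), `start`, `end`,
#'   and `censored` (either edge used).
#' @export
burst_duration <- function(avg, centers, peak, threshold = 0.66) {
  if (peak$peak_rate <= 0)
    return(list(duration = NA_real_, start = NA_real_, end = NA_real_,
                censored = NA, flagged = TRUE))
  cut <- threshold * peak$peak_rate
  below <- avg < cut
  i <- peak$peak_index
  before <- which(below[seq_len(i - 1)])
  after <- which(below[seq(i + 1, length(avg))]) + i
  cens_lo <- length(before) == 0
  cens_hi <- length(after) == 0 || i == length(avg)
  start <- if (cens_lo) centers[1] else centers[max(before)]
  end <- if (cens_hi) centers[length(centers)] else centers[min(after)]
  list(duration = end - start, start = start, end = end,
       censored = cens_lo || cens_hi, flagged = FALSE)
}

#' Object preference index
#'
#' PI = (n - sum_i r_i / r_pref) / (n - 1) with n objects, per-object mean
#' activities r_i and preferred-object activity r_pref = max(r_i). Ranges
#' from 0 (no selectivity) to 1 (response to only one object).
#'
#' @param rates non-negative per-object mean activities (length n >= 2), at
#'   least one positive.
#' @return PI in [0, 1].
#' @export
preference_index <- function(rates) {
  if (any(is.na(rates)) || any(rates < 0))
    stop("preference_index: rates must be non-negative", call. = FALSE)
  if (all(rates == 0))
    stop("preference_index: undefined when all rates are 0", call. = FALSE)
  n <- length(rates)
  (n - sum(rates / max(rates))) / (n - 1)
}

# Per-trial net activity (mean rate in the metric window minus the unit's
# mean baseline rate, floored at 0) for the 36 Go trials, with object labels.
#' @keywords internal
trial_net_rates <- function(dataset, unit_id, task, domain) {
  w <- METRIC_WINDOWS[[domain]]
  trials <- dataset$trials[dataset$trials$task == task &
                             dataset$trials$condition == "go", ]
  sp <- dataset$spikes[dataset$spikes$unit_id == unit_id &
                         dataset$spikes$trial_id %in% trials$trial_id, ]
  spl <- split(sp$spike_time, sp$trial_id)
  vals <- numeric(nrow(trials)); base <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    ev <- tr[[w$event]]
    st <- spl[[as.character(tr$trial_id)]]
    if (is.null(st)) st <- numeric(0)
    vals[i] <- epoch_rate(st, ev + w$range)
    base[i] <- epoch_rate(st, c(tr$object_presentation - 0.5,
                                tr$object_presentation))
  }
  data.frame(trial_id = trials$trial_id, object = trials$object,
             net = pmax(vals - mean(base), 0), stringsAsFactors = FALSE)
}

#' Shuffle null for the preference index
#'
#' Pools the 36 Go trials, permutes the object labels, re-splits them into
#' three sets of 12 and recomputes the PI, `n_shuffles` times.
#'
#' @param net data frame from the per-trial net activity of one unit
#'   (columns `object`, `net`); must be balanced across objects.
#' @param n_shuffles number of label permutations (default 1000).
#' @param permute permutation function over indices; replace to force a
#'   specific permutation (identity gives back the real PI).
#' @return list with `real_pi`, `null` (vector of shuffled PIs, NA where a
#'   shuffle had all-zero rates) and `percentile` of the real PI in the
#'   null.
#' @export
pi_shuffle_null <- function(net, n_shuffles = 1000, permute = sample) {
  counts <- table(net$object)
  if (length(unique(counts)) != 1)
    stop("pi_shuffle_null: unbalanced trial counts across objects", call. = FALSE)
  mean_by_obj <- function(lab) tapply(net$net, lab, mean)
  real <- preference_index(as.numeric(mean_by_obj(net$object)))
  null <- rep(NA_real_, n_shuffles)
  for (s in seq_len(n_shuffles)) {
    lab <- net$object[permute(nrow(net))]
    m <- as.numeric(mean_by_obj(lab))
    if (any(m > 0)) null[s] <- preference_index(m)
  }
  list(real_pi = real, null = null,
       percentile = mean(null[!is.na(null)] < real) +
         0.5 * mean(null[!is.na(null)] == real))
}

#' Tuning metrics for a set of units in one task
#'
#' Computes peak rate, peak timing, burst duration (with censoring flag) and
#' the preference index for each unit, on the domain's reference window.
#'
#' @param dataset a `mirrorpop_dataset`.
#' @param unit_ids units to process.
#' @param task task context (Go trials used).
#' @param domain `"action"` or `"object"`: selects the reference window.
#' @param n_shuffles PI shuffle-null size; 0 skips the null (no percentile).
#' @return data frame, one row per unit: peak_rate, peak_time,
#'   burst_duration, censored, pi, pi_percentile.
#' @export
tuning_metrics <- function(dataset, unit_ids, task, domain = c("action", "object"),
                           n_shuffles = 0) {
  domain <- match.arg(domain)
  rows <- lapply(unit_ids, function(uid) {
    ba <- metric_binned_average(dataset, uid, task, domain)
    pk <- peak_from_average(ba$avg, ba$centers)
    bd <- burst_duration(ba$avg, ba$centers, pk)
    net <- trial_net_rates(dataset, uid, task, domain)
    m <- tapply(net$net, net$object, mean)
    pi_val <- if (any(m > 0)) preference_index(as.numeric(m)) else NA_real_
    pi_pct <- NA_real_
    if (n_shuffles > 0 && !is.na(pi_val))
      pi_pct <- pi_shuffle_null(net, n_shuffles)$percentile
    data.frame(unit_id = uid, task = task, window = domain,
               peak_rate = pk$peak_rate, peak_time = pk$peak_time,
               burst_duration = bd$duration,
               censored = isTRUE(bd$censored),
               pi = pi_val, pi_percentile = pi_pct,
               flagged = pk$flagged || isTRUE(bd$flagged) || is.na(pi_val),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Execution-vs-observation comparison of tuning metrics
#'
#' For SOT units measured in both tasks: two-tailed Pearson correlation and
#' paired-samples t test for each parameter (peak rate, peak timing, burst
#' duration, PI). Pairs with a censored burst duration are excluded from the
#' burst-duration comparison.
#'
#' @param metrics_exe,metrics_obs outputs of [tuning_metrics()] for the same
#'   units in execution and observation.
#' @return data frame: parameter, n, pearson_r, p_correlation, p_paired_t.
#' @export
cross_task_comparison <- function(metrics_exe, metrics_obs) {
  m <- merge(metrics_exe, metrics_obs, by = "unit_id",
             suffixes = c("_exe", "_obs"))
  if (nrow(m) < 3)
    stop("cross_task_comparison: need >= 3 paired observations", call. = FALSE)
  params <- c("peak_rate", "peak_time", "burst_duration", "pi")
  rows <- lapply(params, function(p) {
    a <- m[[paste0(p, "_exe")]]; b <- m[[paste0(p, "_obs")]]
    keep <- stats::complete.cases(a, b)
    if (p == "burst_duration") keep <- keep & !m$censored_exe & !m$censored_obs
    a <- a[keep]; b <- b[keep]
    if (length(a) < 3)
      return(data.frame(parameter = p, n = length(a), pearson_r = NA_real_,
                        p_correlation = NA_real_, p_paired_t = NA_real_,
                        stringsAsFactors = FALSE))
    zero_var <- stats::sd(a) == 0 || stats::sd(b) == 0
    ct <- if (zero_var) NULL
          else stats::cor.test(a, b, alternative = "two.sided", method = "pearson")
    tt <- if (stats::sd(a - b) == 0) NULL else stats::t.test(a, b, paired = TRUE)
    data.frame(parameter = p, n = length(a),
               pearson_r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
               p_correlation = if (is.null(ct)) NA_real_ else ct$p.value,
               p_paired_t = if (is.null(tt)) 1 else tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
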