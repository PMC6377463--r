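# Shared vocabulary and small helpers used across the pipeline.

TASKS <- c("execution", "observation", "extrapersonal")
CONDITIONS <- c("go", "nogo")
OBJECTS <- c("ring", "small_cone", "big_cone")
UNIT_CATEGORIES <- c("ST_action", "OT_action", "SOT_action",
                     "ST_object", "OT_object", "SOT_object",
                     "both", "unresponsive")
EPOCHS_ACTION <- c("baseline", "premovement", "reaching_grasping", "holding")
EPOCHS_OBJECT <- c("baseline", "object_presentation")

#' @keywords internal
assert_label <- function(value, allowed, what) {
  if (length(value) != 1L || is.na(value) || !value %in% allowed) {
    stop(sprintf("invalid %s: '%s' (allowed: %s)", what,
                 paste(value, collapse = ","), paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  value
}

# Count spikes in the half-open window [start, end); `times` need not be sorted.
#' @keywords internal
count_in_window <- function(times, start, end) {
  sum(times >= start & times < end)
}

# Vectorised half-open bin counts for many [starts, ends) windows over one
# sorted spike vector; right edges are exclusive by construction.
#' @keywords internal
bin_counts <- function(sorted_times, starts, ends) {
  n_lt <- function(x) findInterval(x, sorted_times, left.open = TRUE)
  n_lt(ends) - n_lt(starts)
}

# Deterministic sub-seed for a named pipeline stage (kept below 2^31).
#' @keywords internal
stage_seed <- function(global_seed, stage) {
  offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 100000L
  (as.integer(global_seed) %% 2000000000L) + offset
}
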