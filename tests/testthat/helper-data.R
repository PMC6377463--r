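# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Small mixed population over all three tasks; strong effects so the unit
# taxonomy is recoverable.
shared_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    cfg <- simulation_config(
      n_units_per_category = c(ST_action = 3L, OT_action = 3L, SOT_action = 3L,
                               ST_object = 3L, OT_object = 3L, SOT_object = 3L,
                               both = 2L, unresponsive = 4L),
      seed = 20240917L)
    .fixtures$ds <- generate_dataset(cfg)
  }
  .fixtures$ds
}

shared_classification <- function() {
  if (is.null(.fixtures$cl))
    .fixtures$cl <- classify_units(shared_dataset())
  .fixtures$cl
}

# Single-category population generator used by decoding construction tests.
category_dataset <- function(category, n = 24L, seed = 1L, self_bias = 1,
                             tasks = c("execution", "observation")) {
  counts <- setNames(rep(0L, length(mirrorpop:::UNIT_CATEGORIES)),
                     mirrorpop:::UNIT_CATEGORIES)
  counts[category] <- as.integer(n)
  generate_dataset(simulation_config(n_units_per_category = counts,
                                     self_bias = self_bias,
                                     suppressed_fraction = 0,
                                     tasks = tasks, seed = seed))
}

# Long epoch-rate table for one synthetic null unit: i.i.d. Poisson epoch
# rates with no structure, in the shape unit_epoch_anova() expects.
null_unit_rates <- function(n_per_object = 12L, epochs = mirrorpop:::EPOCHS_ACTION,
                            mean_count = 5) {
  objs <- rep(c("ring", "small_cone", "big_cone"), each = n_per_object)
  df <- expand.grid(trial_id = seq_len(3L * n_per_object),
                    epoch = epochs, stringsAsFactors = FALSE)
  df$object <- objs[df$trial_id]
  df$rate <- stats::rpois(nrow(df), mean_count) / 0.5
  df
}
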