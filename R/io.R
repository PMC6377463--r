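# On-disk format: UTF-8 tab-delimited tables with a header row.
#   trials.tsv  trial_id task condition object cue_onset object_presentation
#               go_nogo_signal movement_onset pulling_onset
#   spikes.tsv  unit_id trial_id spike_time
#   units.tsv   unit_id subject session channel
# Timestamps are trial-relative seconds, serialized with 6 decimal places;
# missing events (No-Go movement fields) are empty fields, never sentinels.

TRIAL_TIME_COLS <- c("cue_onset", "object_presentation", "go_nogo_signal",
                     "movement_onset", "pulling_onset")

#' Write a dataset to a directory of TSV files
#'
#' @param dataset list with `trials`, `spikes`, `units` (and optionally
#'   `ground_truth` from the simulator, written as a sidecar).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  tr <- dataset$trials
  for (cc in TRIAL_TIME_COLS) tr[[cc]] <- fmt(tr[[cc]])
  utils::write.table(tr, file.path(dir, "trials.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sp <- dataset$spikes
  sp$spike_time <- sprintf("%.6f", sp$spike_time)
  utils::write.table(sp, file.path(dir, "spikes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$units, file.path(dir, "units.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$ground_truth)) {
    utils::write.table(dataset$ground_truth$units,
                       file.path(dir, "ground_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dataset$ground_truth$expected_rates,
                       file.path(dir, "expected_rates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dataset from a directory of TSV files
#'
#' Validates the schema on load: required columns, referential integrity of
#' trial/unit ids, strictly increasing event order, movement events absent on
#' No-Go trials, and spikes within the trial span. Any violation is a schema
#' error naming the offending row.
#'
#' @param dir directory containing `trials.tsv`, `spikes.tsv`, `units.tsv`
#'   (and optional `ground_truth.tsv` / `expected_rates.tsv`).
#' @return a `mirrorpop_dataset`-shaped list.
#' @export
read_dataset <- function(dir) {
  need <- file.path(dir, c("trials.tsv", "spikes.tsv", "units.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0)
    stop("missing dataset file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  trials <- utils::read.delim(need[1], stringsAsFactors = FALSE)
  spikes <- utils::read.delim(need[2], stringsAsFactors = FALSE)
  units <- utils::read.delim(need[3], stringsAsFactors = FALSE)
  validate_dataset_tables(trials, spikes, units)
  out <- list(trials = trials, spikes = spikes, units = units)
  gt_path <- file.path(dir, "ground_truth.tsv")
  if (file.exists(gt_path)) {
    out$ground_truth <- list(units = utils::read.delim(gt_path,
                                                       stringsAsFactors = FALSE))
    er_path <- file.path(dir, "expected_rates.tsv")
    if (file.exists(er_path))
      out$ground_truth$expected_rates <- utils::read.delim(er_path,
                                                           stringsAsFactors = FALSE)
  }
  class(out) <- "mirrorpop_dataset"
  out
}

#' @keywords internal
validate_dataset_tables <- function(trials, spikes, units) {
  req_tr <- c("trial_id", "task", "condition", "object", TRIAL_TIME_COLS)
  miss <- setdiff(req_tr, names(trials))
  if (length(miss) > 0)
    stop("trials table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(c("unit_id", "trial_id", "spike_time"), names(spikes))
  if (length(miss) > 0)
    stop("spikes table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"unit_id" %in% names(units))
    stop("units table missing column unit_id", call. = FALSE)
  if (anyDuplicated(trials$trial_id))
    stop("duplicated trial_id in trials table", call. = FALSE)

  bad_label <- which(!trials$task %in% TASKS | !trials$condition %in% CONDITIONS |
                       !trials$object %in% OBJECTS)
  if (length(bad_label) > 0)
    stop("trials row ", bad_label[1], ": unknown task/condition/object label",
         call. = FALSE)
  for (i in seq_len(nrow(trials))) {
    ts <- as.numeric(trials[i, TRIAL_TIME_COLS])
    present <- ts[!is.na(ts)]
    if (any(diff(present) <= 0))
      stop("trials row ", i, " (trial_id ", trials$trial_id[i],
           "): event timestamps not strictly increasing", call. = FALSE)
    has_mov <- !is.na(trials$movement_onset[i])
    has_pull <- !is.na(trials$pulling_onset[i])
    if (has_mov != has_pull)
      stop("trials row ", i, " (trial_id ", trials$trial_id[i],
           "): movement_onset and pulling_onset must both be present or absent",
           call. = FALSE)
    if (trials$condition[i] == "nogo" && has_mov)
      stop("trials row ", i, " (trial_id ", trials$trial_id[i],
           "): No-Go trial carries movement events", call. = FALSE)
  }
  dangling_t <- which(!spikes$trial_id %in% trials$trial_id)
  if (length(dangling_t) > 0)
    stop("spikes row ", dangling_t[1], ": unknown trial_id ",
         spikes$trial_id[dangling_t[1]], call. = FALSE)
  dangling_u <- which(!spikes$unit_id %in% units$unit_id)
  if (length(dangling_u) > 0)
    stop("spikes row ", dangling_u[1], ": unknown unit_id ",
         spikes$unit_id[dangling_u[1]], call. = FALSE)
  neg <- which(spikes$spike_time < 0)
  if (length(neg) > 0)
    stop("spikes row ", neg[1], ": negative spike_time", call. = FALSE)
  invisible(TRUE)
}
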