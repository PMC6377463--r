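# Config-driven orchestration: simulate -> classify -> metrics ->
# population -> decode -> report, with per-stage seeds derived from the
# global seed, TSV outputs and a JSON summary manifest carrying the config
# hash.

#' Pipeline configuration
#'
#' All analysis constants live here with their standard defaults (0.5-s
#' epochs, 0.8-s metric windows, 66% burst threshold, 20/60/100/150-ms bins
#' with 20/50-ms steps, 12 trials per condition, 1,000 PI shuffles, 50
#' resample and 50 permutation runs, ANOVA alpha 0.05, Bonferroni post hoc
#' 0.01); never inline in stage code. Every stochastic stage derives its
#' seed deterministically from `seed` and the stage name.
#'
#' @param simulation a [simulation_config()], or `NULL` with `dataset_dir`
#'   pointing at an existing dataset on disk.
#' @param dataset_dir directory with an existing dataset (used when
#'   `simulation` is `NULL`).
#' @param stages stages to run, in dependency order.
#' @param alpha,posthoc_alpha single-unit and population ANOVA criteria.
#' @param pi_shuffles PI shuffle-null size.
#' @param n_resample_runs,n_permutation_runs decoding repetitions.
#' @param decode_labels decoding analyses to run (within-task on
#'   execution, plus exe-trained/obs-tested cross-modal for object).
#' @param seed global pipeline seed.
#' @return object of class `mirrorpop_pipeconfig`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            dataset_dir = NULL,
                            stages = c("simulate", "classify", "metrics",
                                       "population", "decode"),
                            alpha = 0.05, posthoc_alpha = 0.01,
                            pi_shuffles = 1000L,
                            n_resample_runs = 50L,
                            n_permutation_runs = 50L,
                            decode_labels = c("go_nogo", "object", "agent"),
                            seed = 1L) {
  structure(list(simulation = simulation, dataset_dir = dataset_dir,
                 stages = stages, alpha = alpha,
                 posthoc_alpha = posthoc_alpha,
                 pi_shuffles = as.integer(pi_shuffles),
                 n_resample_runs = as.integer(n_resample_runs),
                 n_permutation_runs = as.integer(n_permutation_runs),
                 decode_labels = decode_labels, seed = as.integer(seed)),
            class = "mirrorpop_pipeconfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Every field of [pipeline_config()] and of the nested [simulation_config()]
#' is addressable by key; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `mirrorpop_pipeconfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$simulation
  if (!is.null(sim_args)) {
    bad <- setdiff(names(sim_args), names(formals(simulation_config)))
    if (length(bad) > 0)
      stop("unknown simulation config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (!is.null(sim_args$n_units_per_category))
      sim_args$n_units_per_category <- unlist(sim_args$n_units_per_category)
    if (!is.null(sim_args$event_timing)) {
      sim_args$event_timing$means <- unlist(sim_args$event_timing$means)
      sim_args$event_timing$jitter <- unlist(sim_args$event_timing$jitter)
    }
  }
  pipe_args <- raw[setdiff(names(raw), "simulation")]
  bad <- setdiff(names(pipe_args), names(formals(pipeline_config)))
  if (length(bad) > 0)
    stop("unknown pipeline config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pipe_args$simulation <- if (is.null(sim_args)) NULL
                          else do.call(simulation_config, sim_args)
  do.call(pipeline_config, pipe_args)
}

#' @keywords internal
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass_recursive(config), tmp)
  unname(tools::md5sum(tmp))
}

#' @keywords internal
unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order and writes all outputs
#' under `out_dir`: the dataset tables, `classification.tsv`, per-domain
#' `metrics_*.tsv`, the population report (net-normalized heat-map matrix,
#' trace table, ANOVA tables) and the decoding report, plus
#' `manifest.json` with the config hash, seed and stage list. A missing
#' upstream output makes the dependent stage fail with a clear error.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param verbose print stage progress.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "mirrorpop_pipeconfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  res <- list()

  if ("simulate" %in% config$stages) {
    say("stage simulate")
    sim <- config$simulation
    if (is.null(sim)) stop("simulate stage enabled but no simulation config",
                           call. = FALSE)
    sim$seed <- stage_seed(config$seed, "simulate")
    res$dataset <- generate_dataset(sim)
    write_dataset(res$dataset, file.path(out_dir, "dataset"))
  } else if (!is.null(config$dataset_dir)) {
    res$dataset <- read_dataset(config$dataset_dir)
  }

  need_dataset <- function(stage) {
    if (is.null(res$dataset))
      stop(sprintf("stage '%s' needs a dataset: enable the simulate stage or set dataset_dir",
                   stage), call. = FALSE)
  }

  if ("classify" %in% config$stages) {
    say("stage classify")
    need_dataset("classify")
    res$classification <- classify_units(res$dataset, alpha = config$alpha,
                                         posthoc_alpha = config$posthoc_alpha)
    cls_out <- res$classification
    cls_out$config_hash <- hash
    write_classification(cls_out, file.path(out_dir, "classification.tsv"))
  }

  if ("metrics" %in% config$stages) {
    say("stage metrics")
    need_dataset("metrics")
    if (is.null(res$classification))
      stop("stage 'metrics' needs the classify stage", call. = FALSE)
    set.seed(stage_seed(config$seed, "metrics"))
    cl <- res$classification
    res$metrics <- list()
    for (domain in c("action", "object")) {
      ids <- cl$unit_id[cl[[paste0("agent_type_", domain)]] != "none"]
      if (length(ids) == 0) next
      m <- list()
      for (task in c("execution", "observation"))
        m[[task]] <- tuning_metrics(res$dataset, ids, task, domain,
                                    n_shuffles = config$pi_shuffles)
      sot <- cl$unit_id[cl[[paste0("agent_type_", domain)]] == "SOT"]
      cmp <- if (length(sot) >= 3)
        cross_task_comparison(m$execution[m$execution$unit_id %in% sot, ],
                              m$observation[m$observation$unit_id %in% sot, ])
      res$metrics[[domain]] <- list(by_task = m, sot_comparison = cmp)
      tab <- rbind(m$execution, m$observation)
      tab$config_hash <- hash
      utils::write.table(tab, file.path(out_dir, sprintf("metrics_%s.tsv", domain)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("population" %in% config$stages) {
    say("stage population")
    need_dataset("population")
    if (is.null(res$classification))
      stop("stage 'population' needs the classify stage", call. = FALSE)
    res$population <- population_stage(res$dataset, res$classification,
                                       config, out_dir, hash)
  }

  if ("decode" %in% config$stages) {
    say("stage decode")
    need_dataset("decode")
    res$decoding <- decode_stage(res$dataset, config, out_dir, hash)
  }

  manifest <- list(package = "mirrorpop",
                   version = as.character(utils::packageVersion("mirrorpop")),
                   config_hash = hash, seed = config$seed,
                   stages = config$stages,
                   n_units = if (!is.null(res$dataset)) nrow(res$dataset$units),
                   n_trials = if (!is.null(res$dataset)) nrow(res$dataset$trials))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' @keywords internal
population_stage <- function(dataset, classification, config, out_dir, hash) {
  dir.create(file.path(out_dir, "population_report"), showWarnings = FALSE)
  cl <- classification
  task_rel <- cl$unit_id[cl$task_related]
  out <- list()
  if (length(task_rel) >= 2) {
    go_exe <- dataset$trials$trial_id[dataset$trials$task == "execution" &
                                        dataset$trials$condition == "go"]
    heat_bins <- sliding_binned_rates(dataset, "object_presentation",
                                      c(-0.5, 1.0), 0.100, 0.020,
                                      unit_ids = task_rel, trial_ids = go_exe)
    avg <- apply(heat_bins$rates, c(1, 3), mean)
    base <- baseline_means(dataset, task_rel, "execution")
    supp <- cl$suppressed_action[match(task_rel, cl$unit_id)]
    supp[is.na(supp)] <- cl$suppressed_object[match(task_rel, cl$unit_id)][is.na(supp)]
    nn <- net_normalize(avg, base, supp)
    ord <- order_units_by_peak(nn, seq_along(heat_bins$bin_centers), task_rel)
    heat <- nn$matrix[ord, , drop = FALSE]
    rownames(heat) <- task_rel[ord]
    utils::write.table(cbind(unit_id = rownames(heat), as.data.frame(heat)),
                       file.path(out_dir, "population_report", "heatmap_execution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$selectivity_count <- sliding_object_selectivity_count(heat_bins,
                                                              alpha = config$alpha)
    out$trace <- population_trace(nn)
    utils::write.table(out$trace,
                       file.path(out_dir, "population_report", "trace_execution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    em <- population_epoch_means(dataset, task_rel, "task_epoch")
    out$task_epoch_anova <- population_task_epoch_anova(em, config$alpha,
                                                        config$posthoc_alpha)
    anova_tab <- data.frame(effect = names(out$task_epoch_anova$p),
                            p = unname(out$task_epoch_anova$p),
                            config_hash = hash, stringsAsFactors = FALSE)
    utils::write.table(anova_tab,
                       file.path(out_dir, "population_report", "task_epoch_anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (atype in c("ST", "OT", "SOT")) {
    ids <- cl$unit_id[cl$agent_type_object == atype]
    if (length(ids) < 2) next
    em <- population_epoch_means(dataset, ids, "go_nogo")
    out$go_nogo_anova[[atype]] <- go_nogo_population_anova(em, config$alpha,
                                                           config$posthoc_alpha)
  }
  out
}

#' @keywords internal
baseline_means <- function(dataset, unit_ids, task) {
  trials <- dataset$trials[dataset$trials$task == task &
                             dataset$trials$condition == "go", ]
  vapply(unit_ids, function(u) {
    sp <- dataset$spikes[dataset$spikes$unit_id == u &
                           dataset$spikes$trial_id %in% trials$trial_id, ]
    spl <- split(sp$spike_time, sp$trial_id)
    mean(vapply(seq_len(nrow(trials)), function(i) {
      st <- spl[[as.character(trials$trial_id[i])]]
      if (is.null(st)) st <- numeric(0)
      epoch_rate(st, c(trials$object_presentation[i] - 0.5,
                       trials$object_presentation[i]))
    }, numeric(1)))
  }, numeric(1))
}

#' @keywords internal
decode_stage <- function(dataset, config, out_dir, hash) {
  dir.create(file.path(out_dir, "decoding_report"), showWarnings = FALSE)
  out <- list()
  specs <- list()
  for (lab in config$decode_labels)
    specs[[lab]] <- decoding_spec(lab, train_task = "execution",
                                  n_resample_runs = config$n_resample_runs,
                                  n_permutation_runs = config$n_permutation_runs,
                                  seed = stage_seed(config$seed, paste0("decode_", lab)))
  if ("object" %in% config$decode_labels)
    specs$object_cross <- decoding_spec("object", train_task = "execution",
                                        test_task = "observation",
                                        n_resample_runs = config$n_resample_runs,
                                        n_permutation_runs = config$n_permutation_runs,
                                        seed = stage_seed(config$seed, "decode_object_cross"))
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    curve <- run_decoding(dataset, spec)
    sig <- permutation_significance(dataset, spec, curve)
    out[[nm]] <- list(curve = curve, significance = sig)
    tab <- data.frame(bin = seq_along(curve$accuracy),
                      bin_center = curve$bin_centers,
                      accuracy = curve$accuracy,
                      null_min = apply(sig$null, 2, min),
                      null_mean = colMeans(sig$null),
                      null_max = apply(sig$null, 2, max),
                      significant = sig$significant,
                      config_hash = hash)
    utils::write.table(tab, file.path(out_dir, "decoding_report",
                                      sprintf("decoding_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(sig$intervals) > 0)
      utils::write.table(sig$intervals,
                         file.path(out_dir, "decoding_report",
                                   sprintf("intervals_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
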