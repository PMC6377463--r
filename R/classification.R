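# Single-unit statistics: split-plot repeated-measures ANOVAs on epoch
# firing rates, Bonferroni post hocs, and the task-related / action /
# object / both classification with ST/OT/SOT agent typing.
#
# Design note: each trial presents exactly one object, so Object is a
# between-trial factor while Epoch repeats within trial. The ANOVA is the
# corresponding split-plot model (trials as subjects nested in Object), with
# the Epoch main effect and the Object x Epoch interaction tested in the
# within-trial stratum.

#' Repeated-measures epoch ANOVA for one unit in one task
#'
#' Core test behind unit classification. The action design crosses Object
#' (ring, small cone, big cone; between trials) with four epochs (baseline,
#' premovement, reaching-grasping, holding; within trial); the object design
#' uses two epochs (baseline, object presentation). A unit responds in the
#' design if the Epoch main effect or the Object x Epoch interaction is
#' significant at `alpha`; a significant interaction triggers Bonferroni
#' post hoc paired contrasts at `posthoc_alpha`.
#'
#' @param rates data frame with columns `trial_id`, `object`, `epoch`,
#'   `rate`, one row per trial x epoch (Go trials).
#' @param design `"action"` (4 epochs) or `"object"` (2 epochs).
#' @param alpha significance criterion for the ANOVA effects.
#' @param posthoc_alpha criterion for the Bonferroni-corrected post hocs.
#' @return object of class `mirrorpop_anova`: effect p-values, significance
#'   flag, response direction (`suppressed`), post hoc table when the
#'   interaction is significant, and a `zero_variance` flag for degenerate
#'   inputs (which yield p = 1 rather than an error).
#' @export
unit_epoch_anova <- function(rates, design = c("action", "object"),
                             alpha = 0.05, posthoc_alpha = 0.01) {
  design <- match.arg(design)
  epochs <- if (design == "action") EPOCHS_ACTION else EPOCHS_OBJECT
  df <- rates[rates$epoch %in% epochs, , drop = FALSE]
  cell_n <- table(df$object, df$epoch)
  if (nrow(cell_n) < 2 || any(cell_n < 2))
    stop(sprintf("insufficient data for %s ANOVA: need >= 2 trials per (object, epoch) cell",
                 design), call. = FALSE)
  df$trial_id <- factor(df$trial_id)
  df$object <- factor(df$object)
  df$epoch <- factor(df$epoch, levels = epochs)

  zero_var <- stats::var(df$rate) == 0 || all(is.na(df$rate))
  p <- c(object = 1, epoch = 1, interaction = 1)
  if (!zero_var) {
    fit <- tryCatch(
      stats::aov(rate ~ object * epoch + Error(trial_id), data = df),
      error = function(e) NULL)
    p <- extract_splitplot_p(fit)
    if (anyNA(p)) { p[is.na(p)] <- 1; zero_var <- TRUE }
  }
  significant <- (p[["epoch"]] < alpha) || (p[["interaction"]] < alpha)

  # response direction: sign of the strongest non-baseline epoch deviation
  ep_means <- tapply(df$rate, df$epoch, mean)
  dev <- ep_means[setdiff(epochs, "baseline")] - ep_means[["baseline"]]
  best <- which.max(abs(dev))
  suppressed <- unname(dev[best] < 0)

  posthoc <- NULL
  if (!zero_var && p[["interaction"]] < alpha)
    posthoc <- bonferroni_posthoc(df, epochs, posthoc_alpha)

  structure(list(design = paste0(design, if (design == "action") " 3x4" else " 3x2"),
                 p_object = unname(p[["object"]]),
                 p_epoch = unname(p[["epoch"]]),
                 p_interaction = unname(p[["interaction"]]),
                 alpha = alpha, significant = significant,
                 suppressed = suppressed, effect_size = unname(dev[best]),
                 posthoc = posthoc, zero_variance = zero_var),
            class = "mirrorpop_anova")
}

#' @keywords internal
extract_splitplot_p <- function(fit) {
  out <- c(object = NA_real_, epoch = NA_real_, interaction = NA_real_)
  if (is.null(fit)) return(out)
  s <- summary(fit)
  for (stratum in s) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    pv <- tab[["Pr(>F)"]]
    if ("object" %in% rn) out["object"] <- pv[rn == "object"]
    if ("epoch" %in% rn) out["epoch"] <- pv[rn == "epoch"]
    if ("object:epoch" %in% rn) out["interaction"] <- pv[rn == "object:epoch"]
  }
  out
}

# All pairwise epoch contrasts within each object level, paired by trial,
# Bonferroni-corrected across the whole contrast family of the design.
#' @keywords internal
bonferroni_posthoc <- function(df, epochs, posthoc_alpha) {
  pairs <- utils::combn(epochs, 2, simplify = FALSE)
  objects <- levels(df$object)
  n_contrasts <- length(pairs) * length(objects)
  rows <- list(); k <- 0L
  for (obj in objects) {
    dobj <- df[df$object == obj, ]
    wide <- tapply(dobj$rate, list(dobj$trial_id, dobj$epoch), mean)
    for (pr in pairs) {
      a <- wide[, pr[1]]; b <- wide[, pr[2]]
      keep <- stats::complete.cases(a, b)
      p_raw <- if (sum(keep) < 2 || stats::sd(a[keep] - b[keep]) == 0) 1
               else stats::t.test(a[keep], b[keep], paired = TRUE)$p.value
      k <- k + 1L
      rows[[k]] <- data.frame(object = obj, epoch_a = pr[1], epoch_b = pr[2],
                              p_corrected = min(1, p_raw * n_contrasts),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_corrected < posthoc_alpha
  out
}

#' @export
print.mirrorpop_anova <- function(x, ...) {
  cat(sprintf("%s repeated-measures ANOVA: p(Object)=%.3g p(Epoch)=%.3g p(ObjxEp)=%.3g%s\n",
              x$design, x$p_object, x$p_epoch, x$p_interaction,
              if (x$significant) "  [responsive]" else ""))
  if (x$zero_variance) cat("  (zero-variance input; p-values set to 1)\n")
  invisible(x)
}

#' Action ANOVA (3 objects x 4 epochs) for one unit in one task
#'
#' @param dataset a `mirrorpop_dataset`.
#' @param unit_id,task unit and task context; Go trials only are used.
#' @param ... passed to [unit_epoch_anova()].
#' @export
action_anova <- function(dataset, unit_id, task, ...) {
  assert_label(task, TASKS, "task")
  go <- dataset$trials$trial_id[dataset$trials$task == task &
                                  dataset$trials$condition == "go"]
  rates <- epoch_rate_table(dataset, unit_ids = unit_id, trial_ids = go)
  unit_epoch_anova(rates, design = "action", ...)
}

#' Object ANOVA (3 objects x 2 epochs) for one unit in one task
#' @inheritParams action_anova
#' @export
object_anova <- function(dataset, unit_id, task, ...) {
  assert_label(task, TASKS, "task")
  go <- dataset$trials$trial_id[dataset$trials$task == task &
                                  dataset$trials$condition == "go"]
  rates <- epoch_rate_table(dataset, unit_ids = unit_id, trial_ids = go)
  unit_epoch_anova(rates, design = "object", ...)
}

#' Extrapersonal control ANOVAs for one unit
#'
#' Runs both designs on the extrapersonal task. The result is stored
#' alongside the classification as a control for far-space coding and is
#' never used for ST/OT/SOT assignment.
#'
#' @inheritParams action_anova
#' @return list with elements `action` and `object` (`mirrorpop_anova`).
#' @export
extrapersonal_control <- function(dataset, unit_id, ...) {
  list(action = action_anova(dataset, unit_id, "extrapersonal", ...),
       object = object_anova(dataset, unit_id, "extrapersonal", ...))
}

#' Combine per-task ANOVA outcomes into a unit classification
#'
#' A unit is task related if the Epoch factor is significant (main or
#' interaction effect) in any design/task; it is action related, object
#' related or both depending on which design(s) respond. Within each
#' responding domain the agent type is self-type (ST) if only the execution
#' task responds, other-type (OT) if only observation, self-and-other-type
#' (SOT) if both.
#'
#' @param action_exe,action_obs,object_exe,object_obs `mirrorpop_anova`
#'   results for the two designs in execution and observation.
#' @return one-row data frame with flags, category, per-domain agent type
#'   and suppression direction.
#' @export
classify_unit <- function(action_exe, action_obs, object_exe, object_obs) {
  a_exe <- action_exe$significant; a_obs <- action_obs$significant
  o_exe <- object_exe$significant; o_obs <- object_obs$significant
  action_rel <- a_exe || a_obs
  object_rel <- o_exe || o_obs
  category <- if (action_rel && object_rel) "both"
              else if (action_rel) "action_related"
              else if (object_rel) "object_related" else "none"
  agent <- function(sig_exe, sig_obs) {
    if (sig_exe && sig_obs) "SOT" else if (sig_exe) "ST"
    else if (sig_obs) "OT" else "none"
  }
  # suppression direction taken from the more strongly responding task
  direction <- function(res_exe, res_obs, sig_exe, sig_obs) {
    if (sig_exe && sig_obs)
      if (abs(res_exe$effect_size) >= abs(res_obs$effect_size))
        res_exe$suppressed else res_obs$suppressed
    else if (sig_exe) res_exe$suppressed
    else if (sig_obs) res_obs$suppressed
    else NA
  }
  data.frame(task_related = action_rel || object_rel,
             category = category,
             agent_type_action = agent(a_exe, a_obs),
             agent_type_object = agent(o_exe, o_obs),
             suppressed_action = direction(action_exe, action_obs, a_exe, a_obs),
             suppressed_object = direction(object_exe, object_obs, o_exe, o_obs),
             stringsAsFactors = FALSE)
}

#' Classify every unit of a dataset
#'
#' Runs the action and object ANOVAs in the execution and observation tasks
#' for each unit, derives category and agent types, and (optionally) adds
#' the extrapersonal control ANOVAs.
#'
#' @param dataset a `mirrorpop_dataset`.
#' @param alpha ANOVA significance criterion (default 0.05).
#' @param posthoc_alpha Bonferroni post hoc criterion (default 0.01).
#' @param extrapersonal run the far-space control ANOVAs too (requires
#'   extrapersonal trials in the dataset).
#' @return data frame, one row per unit, with category, agent types,
#'   suppression flags and all effect p-values. The full `mirrorpop_anova`
#'   objects are attached as attribute `"anovas"`.
#' @export
classify_units <- function(dataset, alpha = 0.05, posthoc_alpha = 0.01,
                           extrapersonal = TRUE) {
  unit_ids <- dataset$units$unit_id
  go <- dataset$trials$trial_id[dataset$trials$condition == "go"]
  rates <- epoch_rate_table(dataset, unit_ids = unit_ids, trial_ids = go)
  tasks <- c("execution", "observation", if (extrapersonal) "extrapersonal")
  anovas <- list()
  rows <- vector("list", length(unit_ids))
  for (u in seq_along(unit_ids)) {
    uid <- unit_ids[u]
    res <- list()
    for (task in tasks) {
      sub <- rates[rates$unit_id == uid & rates$task == task, ]
      for (design in c("action", "object"))
        res[[paste(design, task, sep = "_")]] <-
          unit_epoch_anova(sub, design = design, alpha = alpha,
                           posthoc_alpha = posthoc_alpha)
    }
    anovas[[uid]] <- res
    cls <- classify_unit(res$action_execution, res$action_observation,
                         res$object_execution, res$object_observation)
    pcols <- unlist(lapply(names(res), function(nm) {
      r <- res[[nm]]
      stats::setNames(c(r$p_object, r$p_epoch, r$p_interaction),
                      paste0("p_", c("object_", "epoch_", "interaction_"), nm))
    }))
    rows[[u]] <- cbind(data.frame(unit_id = uid, stringsAsFactors = FALSE),
                       cls, as.data.frame(as.list(pcols)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "anovas") <- anovas
  out
}

#' Write the per-unit classification table
#' @param classification result of [classify_units()].
#' @param path output TSV path.
#' @export
write_classification <- function(classification, path) {
  utils::write.table(classification, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
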