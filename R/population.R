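# Net-normalized single-unit and population activity: heat-map matrices
# (100-ms bins, 20-ms steps), peak-time ordering, the bin-wise
# object-selectivity count, population traces (60-ms bins, 20-ms steps) and
# the population-level repeated-measures ANOVAs.

#' Net-normalized activity across conditions
#'
#' For each unit: subtract the mean baseline rate (500 ms before object
#' presentation, averaged over the 36 Go trials), flip the sign for units
#' flagged as suppressed by the single-unit analysis, then scale by the
#' unit's absolute maximum bin across all supplied conditions so every value
#' lies in [-1, 1].
#'
#' @param unit_avg unit x bin matrix of trial-averaged rates (one task or
#'   several tasks' matrices column-bound; normalization is computed across
#'   everything supplied).
#' @param baseline per-unit mean baseline rate (spikes/s).
#' @param suppressed per-unit logical flip flag (`NA` treated as FALSE).
#' @return list of class `mirrorpop_netnorm`: `matrix` (unit x bin, in
#'   [-1, 1]), `norm_constant` (spikes/s), `flipped`, and `all_zero` flag
#'   per unit (all-zero net activity is emitted as zeros, not divided).
#' @export
net_normalize <- function(unit_avg, baseline, suppressed) {
  stopifnot(nrow(unit_avg) == length(baseline),
            nrow(unit_avg) == length(suppressed))
  suppressed[is.na(suppressed)] <- FALSE
  net <- sweep(unit_avg, 1, baseline, "-")
  net[suppressed, ] <- -net[suppressed, , drop = FALSE]
  norm <- apply(abs(net), 1, max)
  all_zero <- norm == 0
  scale <- ifelse(all_zero, 1, norm)
  structure(list(matrix = sweep(net, 1, scale, "/"),
                 norm_constant = norm, flipped = suppressed,
                 all_zero = all_zero),
            class = "mirrorpop_netnorm")
}

#' Order units by their peak time within a period
#'
#' Stable sort of units by the time of their maximum net-normalized bin
#' inside the named bin range; ties are broken by unit id. Used to order
#' heat-map rows (earliest peak at the bottom).
#'
#' @param netnorm a `mirrorpop_netnorm`.
#' @param period integer bin indices defining the reference period (e.g.
#'   the movement-aligned segment).
#' @param unit_ids unit identifiers for tie-breaking; default row order.
#' @return integer permutation of unit rows (earliest peak first).
#' @export
order_units_by_peak <- function(netnorm, period, unit_ids = NULL) {
  m <- netnorm$matrix[, period, drop = FALSE]
  peak_bin <- apply(m, 1, which.max)
  if (is.null(unit_ids)) unit_ids <- seq_len(nrow(m))
  order(peak_bin, unit_ids)
}

#' Bin-wise object-selectivity count
#'
#' For each bin, the number of units whose firing rate differs across the
#' three objects by a one-way ANOVA over the per-trial rates (P < 0.05,
#' uncorrected), as superimposed on the heat maps.
#'
#' @param binned a `mirrorpop_binned` over Go trials of one task.
#' @param alpha significance criterion (default 0.05).
#' @return integer vector, one count per bin (in [0, n_units]).
#' @export
sliding_object_selectivity_count <- function(binned, alpha = 0.05) {
  obj <- factor(binned$trial_info$object)
  n_bin <- dim(binned$rates)[3]
  n_unit <- dim(binned$rates)[1]
  counts <- integer(n_bin)
  for (b in seq_len(n_bin)) {
    sig <- 0L
    for (u in seq_len(n_unit)) {
      y <- binned$rates[u, , b]
      if (stats::var(y) == 0) next
      p <- tryCatch(summary(stats::aov(y ~ obj))[[1]][["Pr(>F)"]][1],
                    error = function(e) NA_real_)
      if (!is.na(p) && p < alpha) sig <- sig + 1L
    }
    counts[b] <- sig
  }
  counts
}

#' Population trace: mean and standard error across units
#'
#' @param netnorm a `mirrorpop_netnorm` (typically built from 60-ms bins at
#'   20-ms steps).
#' @return data frame with bin index, mean and SE across units.
#' @export
population_trace <- function(netnorm) {
  m <- netnorm$matrix
  if (nrow(m) == 0) stop("population_trace: empty unit set", call. = FALSE)
  se <- if (nrow(m) == 1) rep(0, ncol(m))
        else apply(m, 2, stats::sd) / sqrt(nrow(m))
  data.frame(bin = seq_len(ncol(m)), mean = colMeans(m), se = se)
}

# Generic within-subject repeated-measures ANOVA with units as subjects.
# `data` is long with columns unit_id, rate and the factor columns named in
# `factors`; all factors are within-unit.
#' @keywords internal
within_unit_anova <- function(data, factors, alpha = 0.05, posthoc_alpha = 0.01) {
  complete <- stats::aggregate(rate ~ unit_id, data, length)
  n_cells <- prod(vapply(factors, function(f) length(unique(data[[f]])), numeric(1)))
  bad <- complete$unit_id[complete$rate < n_cells]
  if (length(bad) > 0) {
    message(sprintf("excluding %d unit(s) with missing cells: %s",
                    length(bad), paste(utils::head(bad, 5), collapse = ", ")))
    data <- data[!data$unit_id %in% bad, ]
  }
  if (length(unique(data$unit_id)) < 2)
    stop("within_unit_anova: need >= 2 complete units", call. = FALSE)
  for (f in factors) data[[f]] <- factor(data[[f]])
  data$unit_id <- factor(data$unit_id)
  if (stats::var(data$rate) == 0) {
    eff <- stats::setNames(rep(1, 2^length(factors) - 1), anova_effect_names(factors))
    return(list(p = eff, zero_variance = TRUE, posthoc = NULL,
                n_units = length(unique(data$unit_id))))
  }
  rhs <- paste(factors, collapse = " * ")
  err <- sprintf("Error(unit_id/(%s))", rhs)
  fml <- stats::as.formula(paste("rate ~", rhs, "+", err))
  fit <- stats::aov(fml, data = data)
  s <- summary(fit)
  p <- c()
  for (stratum in s) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    pv <- tab[["Pr(>F)"]]
    for (j in seq_along(rn))
      if (rn[j] != "Residuals") p[rn[j]] <- pv[j]
  }
  posthoc <- within_unit_posthoc(data, factors, p, alpha, posthoc_alpha)
  list(p = p, zero_variance = FALSE, posthoc = posthoc,
       n_units = length(unique(data$unit_id)))
}

#' @keywords internal
anova_effect_names <- function(factors) {
  unlist(lapply(seq_along(factors), function(k)
    apply(utils::combn(factors, k), 2, paste, collapse = ":")))
}

# Bonferroni-corrected paired contrasts across the levels of each factor
# involved in a significant effect, within the levels of the other factors.
#' @keywords internal
within_unit_posthoc <- function(data, factors, p, alpha, posthoc_alpha) {
  if (!any(p < alpha)) return(NULL)
  cell_means <- stats::aggregate(
    stats::as.formula(paste("rate ~ unit_id +", paste(factors, collapse = "+"))),
    data, mean)
  cell_means$cell <- interaction(cell_means[factors], drop = TRUE)
  cells <- levels(cell_means$cell)
  pairs <- utils::combn(cells, 2, simplify = FALSE)
  n_contrasts <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- cell_means$rate[cell_means$cell == pr[1]]
    b <- cell_means$rate[cell_means$cell == pr[2]]
    names(a) <- cell_means$unit_id[cell_means$cell == pr[1]]
    b <- b[match(names(a), cell_means$unit_id[cell_means$cell == pr[2]])]
    p_raw <- if (length(a) < 2 || stats::sd(a - b, na.rm = TRUE) == 0) 1
             else stats::t.test(a, b, paired = TRUE)$p.value
    data.frame(cell_a = pr[1], cell_b = pr[2],
               p_corrected = min(1, p_raw * n_contrasts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_corrected < posthoc_alpha
  out
}

#' Task x Epoch population ANOVA (2 x 4)
#'
#' Within-unit repeated-measures ANOVA on per-unit mean net activity over
#' four epochs (baseline, object presentation extended to 800 ms,
#' premovement, reaching-grasping extended to 800 ms) in execution and
#' observation; units are the repeated-measures subjects.
#'
#' @param epoch_means long data frame: unit_id, task (2 levels), epoch
#'   (4 levels), rate.
#' @param alpha,posthoc_alpha significance criteria (0.05 / Bonferroni 0.01).
#' @return list with effect p-values (`p`), post hoc table and bookkeeping.
#' @export
population_task_epoch_anova <- function(epoch_means, alpha = 0.05,
                                        posthoc_alpha = 0.01) {
  within_unit_anova(epoch_means, c("task", "epoch"), alpha, posthoc_alpha)
}

#' Task x Condition x Epoch population ANOVA (3 x 2 x 2)
#'
#' Within-unit ANOVA on per-unit mean activity in the baseline and
#' object-presentation epochs, for Go and No-Go conditions, in the
#' execution, observation and extrapersonal tasks; applied separately to
#' each neuronal subpopulation (ST/OT/SOT object-related units).
#'
#' @param epoch_means long data frame: unit_id, task (3), condition (2),
#'   epoch (2), rate.
#' @inheritParams population_task_epoch_anova
#' @export
go_nogo_population_anova <- function(epoch_means, alpha = 0.05,
                                     posthoc_alpha = 0.01) {
  within_unit_anova(epoch_means, c("task", "condition", "epoch"),
                    alpha, posthoc_alpha)
}

#' Per-unit epoch mean rates for the population ANOVAs
#'
#' The 2 x 4 design uses Go trials with epochs baseline, object presentation
#' (800 ms), premovement and reaching-grasping (800 ms after movement
#' onset); the 3 x 2 x 2 design uses baseline and object presentation
#' (500 ms) for both conditions.
#'
#' @param dataset a `mirrorpop_dataset`.
#' @param unit_ids units to include.
#' @param design `"task_epoch"` (2 x 4, Go trials, execution/observation) or
#'   `"go_nogo"` (3 x 2 x 2, all tasks and conditions).
#' @return long data frame ready for the population ANOVAs.
#' @export
population_epoch_means <- function(dataset, unit_ids,
                                   design = c("task_epoch", "go_nogo")) {
  design <- match.arg(design)
  trials <- dataset$trials
  if (design == "task_epoch")
    trials <- trials[trials$condition == "go" &
                       trials$task %in% c("execution", "observation"), ]
  sp <- dataset$spikes[dataset$spikes$unit_id %in% unit_ids &
                         dataset$spikes$trial_id %in% trials$trial_id, ]
  key <- paste(sp$unit_id, sp$trial_id, sep = "\r")
  spl <- split(sp$spike_time, key)
  ep_names <- if (design == "task_epoch")
    c("baseline", "object_presentation", "premovement", "reaching_grasping")
  else c("baseline", "object_presentation")
  n_ep <- length(ep_names)
  n_row <- nrow(trials) * length(unit_ids) * n_ep
  out_u <- character(n_row); out_t <- character(n_row)
  out_c <- character(n_row); out_e <- character(n_row)
  out_r <- numeric(n_row)
  k <- 0L
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    win <- if (design == "task_epoch") {
      list(c(tr$object_presentation - 0.5, tr$object_presentation),
           c(tr$object_presentation, tr$object_presentation + 0.8),
           c(tr$movement_onset - 0.5, tr$movement_onset),
           c(tr$movement_onset, tr$movement_onset + 0.8))
    } else {
      list(c(tr$object_presentation - 0.5, tr$object_presentation),
           c(tr$object_presentation, tr$object_presentation + 0.5))
    }
    starts <- vapply(win, `[`, numeric(1), 1)
    ends <- vapply(win, `[`, numeric(1), 2)
    for (u in unit_ids) {
      st <- spl[[paste(u, tr$trial_id, sep = "\r")]]
      if (is.null(st)) st <- numeric(0)
      rates <- bin_counts(sort(st), starts, ends) / (ends - starts)
      idx <- k + seq_len(n_ep)
      out_u[idx] <- u; out_t[idx] <- tr$task; out_c[idx] <- tr$condition
      out_e[idx] <- ep_names; out_r[idx] <- rates
      k <- k + n_ep
    }
  }
  long <- data.frame(unit_id = out_u, task = out_t, condition = out_c,
                     epoch = out_e, rate = out_r, stringsAsFactors = FALSE)
  stats::aggregate(rate ~ unit_id + task + condition + epoch, long, mean)
}
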