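# Pseudopopulation decoding: 150-ms/50-ms binned format, random splits with
# one trial per unit per (class, split), train-only z-scoring, a maximum
# correlation-coefficient classifier with leave-one-split-out
# cross-validation, resampling, cross-modal (train one task / test another)
# generalization, single-epoch decoding and a permutation significance test.

#' Decoding specification
#'
#' @param label variable to decode: `"go_nogo"` (Go vs No-Go), `"object"`
#'   (three objects, Go trials) or `"agent"` (monkey vs experimenter, i.e.
#'   execution vs observation, Go trials).
#' @param train_task task whose data train the classifier (ignored for
#'   `"agent"`, which pools execution and observation).
#' @param test_task task whose data are tested; same as `train_task` for
#'   within-task decoding, another task for cross-modal generalization.
#' @param trials_per_class data points drawn per class and resample run;
#'   defaults follow the printed data-point counts: 30 per class for
#'   Go/No-Go and agent decoding (60 data points), 10 per object (30 data
#'   points).
#' @param bin_width,step decoding bin parameters (s); 150-ms bins at 50-ms
#'   intervals.
#' @param seg_object,seg_signal bin-center ranges (s) of the two alignment
#'   segments (relative to object presentation and to the Go/No-Go signal).
#' @param n_resample_runs decoding repetitions with fresh splits (50).
#' @param n_permutation_runs label-shuffle runs of the null distribution
#'   (50).
#' @param null_resample_runs resample runs inside each permutation run (1:
#'   each shuffle is one run of the decoding procedure).
#' @param seed RNG seed for splits, subsampling and shuffles.
#' @return object of class `mirrorpop_decspec`.
#' @export
decoding_spec <- function(label = c("go_nogo", "object", "agent"),
                          train_task = "execution",
                          test_task = train_task,
                          trials_per_class = NULL,
                          bin_width = 0.150, step = 0.050,
                          seg_object = c(-0.5, 1.0),
                          seg_signal = c(-0.1, 1.9),
                          n_resample_runs = 50L,
                          n_permutation_runs = 50L,
                          null_resample_runs = 1L,
                          seed = 1L) {
  label <- match.arg(label)
  if (is.null(trials_per_class))
    trials_per_class <- if (label == "object") 10L else 30L
  if (label != "agent") {
    assert_label(train_task, TASKS, "task")
    assert_label(test_task, TASKS, "task")
  }
  structure(list(label = label, train_task = train_task, test_task = test_task,
                 trials_per_class = as.integer(trials_per_class),
                 bin_width = bin_width, step = step,
                 seg_object = seg_object, seg_signal = seg_signal,
                 n_resample_runs = as.integer(n_resample_runs),
                 n_permutation_runs = as.integer(n_permutation_runs),
                 null_resample_runs = as.integer(null_resample_runs),
                 seed = as.integer(seed)),
            class = "mirrorpop_decspec")
}

#' Binned data for decoding
#'
#' Average firing rate in 150-ms bins sampled at 50-ms intervals for each
#' trial, dual-aligned: a first segment aligned to object presentation and,
#' after the gap, a second segment aligned to the Go/No-Go signal (present
#' on every trial, so No-Go trials keep a full time axis).
#'
#' @param dataset a `mirrorpop_dataset`.
#' @param trial_ids trials to include.
#' @param bin_width,step bin parameters (s).
#' @param seg_object,seg_signal bin-center ranges (s) relative to object
#'   presentation and to the Go/No-Go signal.
#' @param unit_ids optional unit subset.
#' @return a dual-aligned `mirrorpop_binned`.
#' @export
bin_for_decoding <- function(dataset, trial_ids, bin_width = 0.150, step = 0.050,
                             seg_object = c(-0.5, 1.0),
                             seg_signal = c(-0.1, 1.9),
                             unit_ids = NULL) {
  a <- sliding_binned_rates(dataset, "object_presentation", seg_object,
                            bin_width, step, unit_ids = unit_ids,
                            trial_ids = trial_ids)
  b <- sliding_binned_rates(dataset, "go_nogo_signal", seg_signal,
                            bin_width, step, unit_ids = unit_ids,
                            trial_ids = trial_ids)
  dual_align(a, b)
}

#' Assemble a pseudopopulation
#'
#' Groups the available data points into `trials_per_class` splits: for each
#' unit and class, `trials_per_class` trials are drawn without replacement
#' and assigned one per split, independently across units, so each split
#' holds one data point per class from every unit (a population recorded
#' separately but treated as simultaneous).
#'
#' @param binned a `mirrorpop_binned` whose trials carry the labels.
#' @param labels character vector of class labels, one per trial of
#'   `binned` (in `binned$trial_ids` order).
#' @param trials_per_class data points per class; also the number of splits.
#' @return array of class `mirrorpop_pseudopop`, dimensions
#'   `[split, class, unit, bin]`, with attribute `classes`.
#' @export
build_pseudopopulation <- function(binned, labels, trials_per_class) {
  stopifnot(length(labels) == length(binned$trial_ids))
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("build_pseudopopulation: need >= 2 label classes", call. = FALSE)
  n_unit <- dim(binned$rates)[1]
  n_bin <- dim(binned$rates)[3]
  P <- array(NA_real_, dim = c(trials_per_class, length(classes), n_unit, n_bin))
  for (ci in seq_along(classes)) {
    avail <- which(labels == classes[ci])
    if (length(avail) < trials_per_class)
      stop(sprintf("class '%s' has %d trials; %d needed per unit",
                   classes[ci], length(avail), trials_per_class), call. = FALSE)
    for (u in seq_len(n_unit)) {
      take <- avail[sample.int(length(avail), trials_per_class)]
      P[, ci, u, ] <- binned$rates[u, take, ]
    }
  }
  attr(P, "classes") <- classes
  class(P) <- "mirrorpop_pseudopop"
  P
}

# Pearson correlation of each column of A with each column of B (features in
# rows). Zero-variance columns give NA correlations.
#' @keywords internal
cor_columns <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  r <- crossprod(A, B) / outer(na, nb)
  r[!is.finite(r)] <- NA_real_
  r
}

#' Maximum correlation-coefficient classification
#'
#' Assigns each test vector to the class whose training mean vector has the
#' highest Pearson correlation with it. Ties go to the smallest class
#' index; a test vector with zero variance (undefined correlation) draws a
#' class at random from the tied/undefined set under the caller's RNG.
#'
#' @param train_means units x classes matrix of class mean vectors.
#' @param test units x n_test matrix of test vectors.
#' @return integer vector of predicted class indices (length n_test).
#' @export
max_correlation_classify <- function(train_means, test) {
  r <- cor_columns(test, train_means)
  as.integer(unname(apply(r, 1, function(row) {
    if (all(is.na(row))) sample.int(length(row), 1)
    else which.max(row)  # earliest index on exact ties
  })))
}

# One full leave-one-split-out decoding pass. P_train: [split, class, unit,
# bin]; P_test defaults to P_train (within-task decoding). For cross-modal
# decoding P_test comes from another task: training data, class means and
# z-scoring statistics never see the test task. Vectorised over bins:
# per-class unit vectors are laid out as U x (B*C) matrices and the Pearson
# correlations come from column-wise cross products.
#' @keywords internal
decode_core <- function(P_train, P_test = NULL) {
  if (is.null(P_test)) P_test <- P_train
  ns <- dim(P_train)[1]; nc <- dim(P_train)[2]
  nu <- dim(P_train)[3]; nb <- dim(P_train)[4]
  correct <- matrix(0, ns, nb)
  for (k in seq_len(ns)) {
    tr <- P_train[-k, , , , drop = FALSE]                  # [ns-1, C, U, B]
    s1 <- ns - 1L; n_tr <- s1 * nc
    M <- matrix(tr, nrow = n_tr)                           # cols: U*B
    mu <- colMeans(M)                                      # length U*B
    sdv <- sqrt(pmax(0, (colSums(M^2) - n_tr * mu^2) / (n_tr - 1)))
    ok <- sdv > 0
    # class means over training splits, z-scored with train statistics;
    # zero-SD (unit, bin) features pass through as 0
    zscore <- function(v) { z <- (v - mu) / sdv; z[!ok] <- 0; z }
    CM <- vapply(seq_len(nc), function(ci)
      zscore(colMeans(matrix(tr[, ci, , ], nrow = s1))), numeric(nu * nb))
    TE <- vapply(seq_len(nc), function(ci)
      zscore(as.numeric(P_test[k, ci, , ])), numeric(nu * nb))
    # center and normalise each (bin, class) unit-vector for correlations
    prep <- function(X) {
      X <- matrix(X, nrow = nu)                            # U x (B*C)
      X <- sweep(X, 2, colMeans(X))
      list(x = X, norm = sqrt(colSums(X^2)))
    }
    ptr <- prep(CM); pte <- prep(TE)
    hits <- numeric(nb)
    for (i in seq_len(nc)) {
      ii <- (i - 1L) * nb + seq_len(nb)
      R <- matrix(NA_real_, nb, nc)                        # r(test_i, mean_j)
      for (j in seq_len(nc)) {
        jj <- (j - 1L) * nb + seq_len(nb)
        R[, j] <- colSums(pte$x[, ii, drop = FALSE] * ptr$x[, jj, drop = FALSE]) /
          (pte$norm[ii] * ptr$norm[jj])
      }
      undef <- rowSums(is.finite(R)) == 0
      R[!is.finite(R)] <- -Inf
      pred <- max.col(R, ties.method = "first")
      if (any(undef)) pred[undef] <- sample.int(nc, sum(undef), replace = TRUE)
      hits <- hits + (pred == i)
    }
    correct[k, ] <- hits / nc
  }
  colMeans(correct)
}

# Trials and labels backing one decoding problem for a given task.
#' @keywords internal
decoding_trials <- function(dataset, label, task) {
  tr <- dataset$trials
  if (label == "go_nogo") {
    tr <- tr[tr$task == task, ]
    list(trial_ids = tr$trial_id, labels = tr$condition)
  } else if (label == "object") {
    tr <- tr[tr$task == task & tr$condition == "go", ]
    list(trial_ids = tr$trial_id, labels = tr$object)
  } else { # agent: monkey (execution) vs experimenter (observation), Go trials
    tr <- tr[tr$task %in% c("execution", "observation") & tr$condition == "go", ]
    list(trial_ids = tr$trial_id, labels = tr$task)
  }
}

#' Run a pseudopopulation decoding analysis
#'
#' Resampled leave-one-split-out cross-validation of the maximum
#' correlation-coefficient classifier on dual-aligned 150-ms/50-ms binned
#' data. For cross-modal specs (`test_task != train_task`) the classifier
#' and the z-scoring statistics are built entirely on the train task and
#' tested on the test task's held-out splits.
#'
#' @param dataset a `mirrorpop_dataset`.
#' @param spec a [decoding_spec()].
#' @param unit_ids optional unit subset (default: all units).
#' @param shuffle_labels internal: permute labels before splitting (used by
#'   the permutation test).
#' @param n_resample_runs override of `spec$n_resample_runs`.
#' @return object of class `mirrorpop_decoding`: per-bin `accuracy`
#'   (averaged over runs and folds), `bin_centers`, `gap_after`, `classes`,
#'   and the `spec`.
#' @export
run_decoding <- function(dataset, spec, unit_ids = NULL,
                         shuffle_labels = FALSE, n_resample_runs = NULL) {
  prep <- prepare_decoding(dataset, spec, unit_ids)
  # the real curve re-seeds for reproducibility; shuffled (null) calls run on
  # the caller's RNG stream so permutation runs differ
  if (!shuffle_labels) set.seed(spec$seed)
  out <- run_decoding_prepared(prep, spec, shuffle_labels, n_resample_runs)
  out$prep <- prep
  out
}

# Bin once; decoding and permutation runs reuse the binned data.
#' @keywords internal
prepare_decoding <- function(dataset, spec, unit_ids = NULL) {
  cross <- spec$label != "agent" && !identical(spec$test_task, spec$train_task)
  dt_train <- decoding_trials(dataset, spec$label, spec$train_task)
  b_train <- bin_for_decoding(dataset, dt_train$trial_ids,
                              spec$bin_width, spec$step,
                              seg_object = spec$seg_object,
                              seg_signal = spec$seg_signal,
                              unit_ids = unit_ids)
  out <- list(b_train = b_train, labels_train = dt_train$labels,
              cross = cross)
  if (cross) {
    dt_test <- decoding_trials(dataset, spec$label, spec$test_task)
    out$b_test <- bin_for_decoding(dataset, dt_test$trial_ids,
                                   spec$bin_width, spec$step,
                                   seg_object = spec$seg_object,
                                   seg_signal = spec$seg_signal,
                                   unit_ids = unit_ids)
    out$labels_test <- dt_test$labels
  }
  out
}

#' @keywords internal
run_decoding_prepared <- function(prep, spec, shuffle_labels = FALSE,
                                  n_resample_runs = NULL) {
  if (is.null(n_resample_runs)) n_resample_runs <- spec$n_resample_runs
  acc <- 0
  for (run in seq_len(n_resample_runs)) {
    lab_tr <- prep$labels_train
    if (shuffle_labels) lab_tr <- lab_tr[sample.int(length(lab_tr))]
    P_train <- build_pseudopopulation(prep$b_train, lab_tr,
                                      spec$trials_per_class)
    P_test <- NULL
    if (prep$cross) {
      lab_te <- prep$labels_test
      if (shuffle_labels) lab_te <- lab_te[sample.int(length(lab_te))]
      P_test <- build_pseudopopulation(prep$b_test, lab_te,
                                       spec$trials_per_class)
    }
    acc <- acc + decode_core(P_train, P_test)
  }
  structure(list(accuracy = acc / n_resample_runs,
                 bin_centers = prep$b_train$bin_centers,
                 gap_after = prep$b_train$gap_after,
                 align_event = prep$b_train$align_event,
                 classes = sort(unique(prep$labels_train)),
                 n_classes = length(unique(prep$labels_train)),
                 spec = spec),
            class = "mirrorpop_decoding")
}

#' Permutation significance of a decoding curve
#'
#' Reruns the decoding with the class labels randomly shuffled
#' (`n_permutation_runs` times, same resampling structure) to build a null
#' distribution per bin. A bin is significant only if the real accuracy is
#' greater than all null values at that bin; reported intervals are maximal
#' runs of at least `min_consecutive` significant bins that do not cross
#' the alignment gap, with their durations so a minimum-duration rule (e.g.
#' 200 ms) can also be applied.
#'
#' @param dataset,spec,unit_ids as in [run_decoding()].
#' @param real a `mirrorpop_decoding` computed with the same spec.
#' @param min_consecutive minimum run length of significant bins (3).
#' @return list of class `mirrorpop_significance`: `significant` (per-bin
#'   logical), `null` (matrix runs x bins), `intervals` (data frame with
#'   bin range, start/end times and duration in s).
#' @export
permutation_significance <- function(dataset, spec, real, unit_ids = NULL,
                                     min_consecutive = 3L) {
  if (length(real$accuracy) == 0)
    stop("empty decoding curve", call. = FALSE)
  set.seed(stage_seed(spec$seed, "permutation"))
  prep <- if (!is.null(real$prep)) real$prep
          else prepare_decoding(dataset, spec, unit_ids)
  null <- matrix(NA_real_, spec$n_permutation_runs, length(real$accuracy))
  for (i in seq_len(spec$n_permutation_runs))
    null[i, ] <- run_decoding_prepared(prep, spec, shuffle_labels = TRUE,
                                       n_resample_runs = spec$null_resample_runs)$accuracy
  sig <- vapply(seq_along(real$accuracy),
                function(b) all(real$accuracy[b] > null[, b]), logical(1))
  intervals <- significant_intervals(sig, real$bin_centers, real$gap_after,
                                     spec$bin_width, min_consecutive)
  structure(list(significant = sig, null = null, intervals = intervals,
                 min_consecutive = min_consecutive),
            class = "mirrorpop_significance")
}

#' @keywords internal
significant_intervals <- function(sig, centers, gap_after, bin_width,
                                  min_consecutive) {
  seg <- rep(1L, length(sig))
  if (!is.null(gap_after) && gap_after < length(sig))
    seg[(gap_after + 1L):length(sig)] <- 2L
  rows <- list(); k <- 0L
  for (s in unique(seg)) {
    idx <- which(seg == s)
    r <- rle(sig[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] < min_consecutive) next
      b0 <- idx[starts[j]]; b1 <- idx[ends[j]]
      k <- k + 1L
      rows[[k]] <- data.frame(segment = s, bin_start = b0, bin_end = b1,
                              n_bins = b1 - b0 + 1L,
                              t_start = centers[b0] - bin_width / 2,
                              t_end = centers[b1] + bin_width / 2,
                              duration = centers[b1] - centers[b0] + bin_width,
                              stringsAsFactors = FALSE)
    }
  }
  if (k == 0)
    return(data.frame(segment = integer(0), bin_start = integer(0),
                      bin_end = integer(0), n_bins = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0)))
  do.call(rbind, rows)
}

#' Single-epoch cross-decoding matrix
#'
#' Decodes a variable from the mean rate in a single epoch (the 1,300-ms
#' action epoch from 500 ms before to 800 ms after movement onset, or the
#' 800-ms object-presentation epoch), for every train-task x test-task
#' pair: diagonal entries are within-task accuracies, off-diagonal entries
#' are cross-modal generalization.
#'
#' @param dataset a `mirrorpop_dataset`.
#' @param label `"go_nogo"` or `"object"`.
#' @param epoch `"action"` (movement-anchored; Go trials only) or
#'   `"object_presentation"`.
#' @param tasks tasks to cross (default execution and observation).
#' @param spec a [decoding_spec()] providing trial counts, runs and seed.
#' @param unit_ids optional unit subset.
#' @return numeric matrix `accuracy[train_task, test_task]` (mean over the
#'   single epoch's accuracy).
#' @export
single_epoch_decoding <- function(dataset, label, epoch = c("object_presentation", "action"),
                                  tasks = c("execution", "observation"),
                                  spec = decoding_spec(label), unit_ids = NULL) {
  epoch <- match.arg(epoch)
  label <- match.arg(label, c("go_nogo", "object"))
  if (label == "go_nogo" && epoch == "action")
    stop("the movement-anchored epoch exists only on Go trials; ",
         "Go/No-Go decoding cannot use it", call. = FALSE)
  set.seed(spec$seed)
  out <- matrix(NA_real_, length(tasks), length(tasks),
                dimnames = list(train = tasks, test = tasks))
  for (tr_task in tasks) for (te_task in tasks) {
    s <- spec
    s$label <- label; s$train_task <- tr_task; s$test_task <- te_task
    out[tr_task, te_task] <-
      mean(run_decoding_epoch(dataset, s, epoch, unit_ids = unit_ids)$accuracy)
  }
  out
}

# Decoding on one named epoch: a single bin spanning the whole window.
#' @keywords internal
run_decoding_epoch <- function(dataset, spec, epoch, unit_ids = NULL) {
  win <- if (epoch == "action") list(event = "movement_onset", range = c(-0.5, 0.8))
         else list(event = "object_presentation", range = c(0, 0.8))
  width <- diff(win$range)
  center <- mean(win$range)
  spec$bin_width <- width; spec$step <- width
  cross <- !identical(spec$test_task, spec$train_task)
  dt_train <- decoding_trials(dataset, spec$label, spec$train_task)
  bin1 <- function(ids) sliding_binned_rates(dataset, win$event,
                                             range = c(center, center),
                                             bin_width = width, step = width,
                                             unit_ids = unit_ids, trial_ids = ids)
  b_train <- bin1(dt_train$trial_ids)
  b_test <- NULL; dt_test <- NULL
  if (cross) {
    dt_test <- decoding_trials(dataset, spec$label, spec$test_task)
    b_test <- bin1(dt_test$trial_ids)
  }
  acc <- 0
  for (run in seq_len(spec$n_resample_runs)) {
    P_train <- build_pseudopopulation(b_train, dt_train$labels,
                                      spec$trials_per_class)
    P_test <- if (cross) build_pseudopopulation(b_test, dt_test$labels,
                                                spec$trials_per_class)
    acc <- acc + decode_core(P_train, P_test)
  }
  structure(list(accuracy = acc / spec$n_resample_runs,
                 bin_centers = center, gap_after = NULL,
                 n_classes = length(unique(dt_train$labels)), spec = spec),
            class = "mirrorpop_decoding")
}

#' @export
print.mirrorpop_decoding <- function(x, ...) {
  cat(sprintf("mirrorpop decoding: %s, train %s / test %s\n", x$spec$label,
              paste(x$spec$train_task, collapse = "+"),
              paste(x$spec$test_task, collapse = "+")))
  cat(sprintf("  %d bins, mean accuracy %.3f (chance %.3f), max %.3f\n",
              length(x$accuracy), mean(x$accuracy), 1 / x$n_classes,
              max(x$accuracy)))
  invisible(x)
}

#' Plot a decoding accuracy curve
#'
#' Accuracy against bin center with the chance level and, optionally, the
#' permutation-null envelope and significant bins.
#'
#' @param x a `mirrorpop_decoding`.
#' @param significance optional `mirrorpop_significance` for the same curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mirrorpop_decoding <- function(x, significance = NULL, ...) {
  n <- length(x$accuracy)
  idx <- seq_len(n)
  graphics::plot(idx, x$accuracy, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "bin", ylab = "decoding accuracy", ...)
  graphics::abline(h = 1 / x$n_classes, lty = 2)
  if (!is.null(x$gap_after) && x$gap_after < n)
    graphics::abline(v = x$gap_after + 0.5, col = "grey60")
  if (!is.null(significance)) {
    graphics::lines(idx, apply(significance$null, 2, max), col = "grey40")
    sig <- which(significance$significant)
    if (length(sig) > 0)
      graphics::points(sig, x$accuracy[sig], pch = 16, col = "red", cex = 0.6)
  }
  invisible(x)
}
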