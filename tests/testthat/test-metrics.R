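test_that("preference index evaluates the selectivity formula", {
  expect_equal(preference_index(c(7.3, 0, 0)), 1)
  expect_equal(preference_index(c(4.2, 4.2, 4.2)), 0)
  expect_equal(preference_index(c(2, 1, 1)), 0.5)
  # scale invariance and range, over random rate triples
  set.seed(41)
  for (i in 1:50) {
    r <- runif(3, 0, 30)
    pi1 <- preference_index(r)
    expect_gte(pi1, 0); expect_lte(pi1, 1)
    expect_equal(preference_index(r * runif(1, 0.1, 10)), pi1)
  }
  expect_error(preference_index(c(0, 0, 0)), "undefined")
  expect_error(preference_index(c(-1, 2, 3)), "non-negative")
})

test_that("peak and burst duration recover constructed profiles", {
  centers <- seq(0.01, 0.79, by = 0.02)
  # rectangular bump of width 0.2 s on zero background
  rect <- ifelse(centers >= 0.3 & centers < 0.5, 30, 0)
  pk <- mirrorpop:::peak_from_average(rect, centers)
  expect_equal(pk$peak_rate, 30)
  expect_equal(pk$peak_time, 0.31)  # earliest bin wins ties
  bd <- burst_duration(rect, centers, pk)
  expect_lt(abs(bd$duration - 0.2), 0.045)
  expect_false(bd$censored)

  # triangular profile peaking at p: burst spans the region above 0.66 p
  tri <- pmax(0, 1 - abs(centers - 0.4) / 0.3) * 20
  pkt <- mirrorpop:::peak_from_average(tri, centers)
  bdt <- burst_duration(tri, centers, pkt)
  expect_lt(abs(bdt$duration - 2 * 0.34 * 0.3), 0.05)

  # burst duration grows with bump width
  widths <- c(0.1, 0.2, 0.3, 0.4)
  durs <- vapply(widths, function(w) {
    prof <- ifelse(abs(centers - 0.4) < w / 2, 10, 0)
    p <- mirrorpop:::peak_from_average(prof, centers)
    burst_duration(prof, centers, p)$duration
  }, numeric(1))
  expect_true(all(diff(durs) >= 0))

  # constant positive rate: censored at both edges, full window length
  flat <- rep(12, length(centers))
  pkf <- mirrorpop:::peak_from_average(flat, centers)
  bdf <- burst_duration(flat, centers, pkf)
  expect_true(bdf$censored)
  expect_equal(bdf$duration, centers[length(centers)] - centers[1])

  # silent unit: peak 0 at the first bin, burst undefined and flagged
  silent <- rep(0, length(centers))
  pks <- mirrorpop:::peak_from_average(silent, centers)
  expect_equal(pks$peak_rate, 0)
  expect_equal(pks$peak_time, centers[1])
  expect_true(pks$flagged)
  expect_true(is.na(burst_duration(silent, centers, pks)$duration))
})

test_that("peak equals a brute-force max over the binned trial average", {
  ds <- shared_dataset()
  gt <- ds$ground_truth$units
  uid <- gt$unit_id[gt$category == "SOT_object"][1]
  pk <- peak_activity(ds, uid, "execution", "object")

  # oracle: rebin by hand at 20 ms over [0, 0.8] after object presentation
  go <- ds$trials[ds$trials$task == "execution" & ds$trials$condition == "go", ]
  sp <- ds$spikes[ds$spikes$unit_id == uid &
                    ds$spikes$trial_id %in% go$trial_id, ]
  edges <- seq(0, 0.8, by = 0.02)
  counts <- numeric(length(edges) - 1)
  for (i in seq_len(nrow(go))) {
    rel <- sp$spike_time[sp$trial_id == go$trial_id[i]] -
      go$object_presentation[i]
    for (b in seq_len(length(edges) - 1))
      counts[b] <- counts[b] + sum(rel >= edges[b] & rel < edges[b + 1])
  }
  avg <- counts / nrow(go) / 0.02
  expect_equal(pk$peak_rate, max(avg))
  expect_equal(pk$peak_time, edges[which.max(avg)] + 0.01)
})

test_that("the PI shuffle null behaves under the null and under selectivity", {
  set.seed(43)
  # label-independent unit: real PI inside the central 95% of its null
  inside <- replicate(20, {
    net <- data.frame(object = rep(c("a", "b", "c"), each = 12),
                      net = rpois(36, 8))
    ns <- pi_shuffle_null(net, n_shuffles = 200)
    ns$percentile > 0.025 && ns$percentile < 0.975
  })
  expect_gte(mean(inside), 0.8)

  # strongly selective unit (>= 3:1 contrast): real PI above the 95th pct
  net <- data.frame(object = rep(c("a", "b", "c"), each = 12),
                    net = c(rpois(12, 30), rpois(12, 8), rpois(12, 8)))
  ns <- pi_shuffle_null(net, n_shuffles = 500)
  expect_gt(ns$real_pi, stats::quantile(ns$null, 0.95, na.rm = TRUE))

  # identity permutation: the null equals the real PI
  ns_id <- pi_shuffle_null(net, n_shuffles = 1, permute = function(n) seq_len(n))
  expect_equal(ns_id$null[1], ns_id$real_pi)

  expect_error(pi_shuffle_null(data.frame(object = c("a", "a", "b"),
                                          net = 1:3)),
               "unbalanced")
})

test_that("cross-task comparisons behave on identity and independent inputs", {
  set.seed(44)
  m <- data.frame(unit_id = sprintf("u%03d", 1:30),
                  peak_rate = runif(30, 5, 50),
                  peak_time = runif(30, -0.4, 0.7),
                  burst_duration = runif(30, 0.05, 0.6),
                  censored = FALSE,
                  pi = runif(30))
  # identical metrics in both tasks: r = 1, paired-t flat
  cmp <- cross_task_comparison(m, m)
  expect_true(all(abs(cmp$pearson_r - 1) < 1e-12))
  expect_true(all(cmp$p_paired_t == 1))

  # independent metrics, n = 200: negligible correlation
  big <- function() data.frame(unit_id = sprintf("u%03d", 1:200),
                               peak_rate = runif(200, 5, 50),
                               peak_time = runif(200, -0.4, 0.7),
                               burst_duration = runif(200, 0.05, 0.6),
                               censored = FALSE, pi = runif(200))
  cmp2 <- cross_task_comparison(big(), big())
  expect_true(all(abs(cmp2$pearson_r) < 0.2))

  # censored burst durations drop out of that comparison only
  mc <- m; mc$censored[1:10] <- TRUE
  cmp3 <- cross_task_comparison(mc, m)
  expect_equal(cmp3$n[cmp3$parameter == "burst_duration"], 20)
  expect_equal(cmp3$n[cmp3$parameter == "pi"], 30)

  expect_error(cross_task_comparison(m[1:2, ], m[1:2, ]), ">= 3 paired")
})
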