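test_that("pseudopopulation splits follow the data-point bookkeeping", {
  ds <- shared_dataset()
  exe <- ds$trials$trial_id[ds$trials$task == "execution"]
  uid <- ds$units$unit_id[1:4]
  b <- bin_for_decoding(ds, exe, unit_ids = uid)

  # Go/No-Go: 30 data points per condition -> 60 in 30 splits of 2
  labs <- ds$trials$condition[match(b$trial_ids, ds$trials$trial_id)]
  P <- build_pseudopopulation(b, labs, trials_per_class = 30)
  expect_equal(dim(P)[1:2], c(30L, 2L))
  expect_equal(prod(dim(P)[1:2]), 60)
  expect_equal(attr(P, "classes"), c("go", "nogo"))

  # object decoding on Go trials: 10 x 3 = 30 data points
  go <- ds$trials$trial_id[ds$trials$task == "execution" &
                             ds$trials$condition == "go"]
  bg <- bin_for_decoding(ds, go, unit_ids = uid)
  labs_o <- ds$trials$object[match(bg$trial_ids, ds$trials$trial_id)]
  Po <- build_pseudopopulation(bg, labs_o, trials_per_class = 10)
  expect_equal(prod(dim(Po)[1:2]), 30)

  # insufficient trials name the class
  expect_error(build_pseudopopulation(bg, labs_o, trials_per_class = 13),
               "big_cone")
})

test_that("max-correlation classification matches a brute-force oracle", {
  set.seed(61)
  # >= 3 units: with 2 units every Pearson correlation is exactly +/-1, so
  # class order among ties is arbitrary and the comparison is meaningless
  for (i in 1:20) {
    nu <- sample(3:5, 1); nc <- sample(2:3, 1)
    means <- matrix(rnorm(nu * nc), nu, nc)
    test <- matrix(rnorm(nu * 7), nu, 7)
    pred <- max_correlation_classify(means, test)
    oracle <- apply(test, 2, function(v)
      which.max(apply(means, 2, function(m) cor(v, m))))
    expect_equal(pred, unname(oracle))
  }
  # exact tie: smallest class index wins
  means <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(max_correlation_classify(means, cbind(c(2, 4, 6))), 1L)
  # a perfectly matching class mean is recovered with noiseless data
  means <- cbind(a = c(1, 0, 0, 2), b = c(0, 3, 1, 0))
  expect_equal(max_correlation_classify(means, means), c(1L, 2L))
})

test_that("decoding is scale-invariant, deterministic and leak-free", {
  set.seed(62)
  P <- array(rnorm(8 * 2 * 6 * 5, mean = 10), dim = c(8, 2, 6, 5))
  P[, 1, 1:3, ] <- P[, 1, 1:3, ] + 1.5   # class signal on three units
  acc <- mirrorpop:::decode_core(P)
  # scaling any unit leaves the z-scored decoding unchanged
  P2 <- P; P2[, , 2, ] <- P2[, , 2, ] * 100
  expect_equal(mirrorpop:::decode_core(P2), acc)
  # within-task testing equals explicitly passing the same tensor
  expect_equal(mirrorpop:::decode_core(P, P), acc)

  # full runs: identical seeds give identical curves
  ds <- shared_dataset()
  spec <- decoding_spec("object", n_resample_runs = 2, seed = 77)
  c1 <- run_decoding(ds, spec)
  c2 <- run_decoding(ds, spec)
  expect_identical(c1$accuracy, c2$accuracy)
  expect_equal(c1$n_classes, 3)
  expect_true(all(c1$accuracy >= 0 & c1$accuracy <= 1))
})

test_that("shuffled labels decode at chance", {
  ds <- shared_dataset()
  spec <- decoding_spec("object", n_resample_runs = 3, seed = 63)
  set.seed(63)
  null_curve <- run_decoding(ds, spec, shuffle_labels = TRUE,
                             n_resample_runs = 3)
  # mean over bins and runs close to 1/3
  expect_lt(abs(mean(null_curve$accuracy) - 1 / 3), 0.05)
})

test_that("significance intervals apply the consecutive-bin rule", {
  centers <- seq(0.05, 1.0, by = 0.05)
  sig <- rep(FALSE, 20)
  sig[c(3, 7, 8)] <- TRUE              # two isolated short runs
  iv <- mirrorpop:::significant_intervals(sig, centers, NULL, 0.15, 3)
  expect_equal(nrow(iv), 0)

  sig[7:10] <- TRUE                    # one qualifying run of 4
  iv <- mirrorpop:::significant_intervals(sig, centers, NULL, 0.15, 3)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$bin_start, 7); expect_equal(iv$bin_end, 10)
  expect_equal(iv$duration, centers[10] - centers[7] + 0.15)
  expect_gte(iv$duration, 0.2)

  # a run straddling the alignment gap is split, never merged
  sig2 <- rep(FALSE, 20); sig2[9:12] <- TRUE
  iv2 <- mirrorpop:::significant_intervals(sig2, centers, gap_after = 10,
                                           0.15, 3)
  expect_equal(nrow(iv2), 0)
  sig2[6:12] <- TRUE
  iv3 <- mirrorpop:::significant_intervals(sig2, centers, gap_after = 10,
                                           0.15, 3)
  expect_equal(nrow(iv3), 1)
  expect_equal(iv3$bin_end, 10)
})

test_that("permutation test flags a decodable population and intervals", {
  ds <- category_dataset("SOT_object", n = 16, seed = 64)
  spec <- decoding_spec("object", n_resample_runs = 3,
                        n_permutation_runs = 10, seed = 64)
  curve <- run_decoding(ds, spec)
  sig <- permutation_significance(ds, spec, curve)
  # strong object tuning: significant bins during object presentation
  obj_bins <- which(curve$bin_centers >= 0 & curve$bin_centers <= 0.8 &
                      seq_along(curve$bin_centers) <= curve$gap_after)
  expect_gt(mean(sig$significant[obj_bins]), 0.5)
  expect_gt(nrow(sig$intervals), 0)
  expect_true(all(sig$intervals$n_bins >= 3))
})

test_that("cross-modal transfer separates agent-invariant from agent-specific codes", {
  # agent-invariant SOT object population: training on execution
  # generalizes to observation
  ds_sot <- category_dataset("SOT_object", n = 16, seed = 65, self_bias = 1)
  within <- run_decoding(ds_sot, decoding_spec("object", n_resample_runs = 3,
                                               seed = 65))
  cross <- run_decoding(ds_sot, decoding_spec("object",
                                              test_task = "observation",
                                              n_resample_runs = 3, seed = 65))
  resp <- which(within$bin_centers >= 0.1 & within$bin_centers <= 0.7 &
                  seq_along(within$bin_centers) <= within$gap_after)
  expect_gt(mean(within$accuracy[resp]), 0.6)
  expect_lt(abs(mean(within$accuracy[resp]) - mean(cross$accuracy[resp])), 0.15)

  # agent-specific (ST) population: no transfer to observation
  ds_st <- category_dataset("ST_object", n = 16, seed = 66)
  cross_st <- run_decoding(ds_st, decoding_spec("object",
                                                test_task = "observation",
                                                n_resample_runs = 3, seed = 66))
  expect_lt(abs(mean(cross_st$accuracy[resp]) - 1 / 3), 0.08)
})

test_that("single-epoch decoding yields a train-by-test accuracy matrix", {
  ds <- category_dataset("SOT_object", n = 12, seed = 67, self_bias = 1)
  M <- single_epoch_decoding(ds, "object", "object_presentation",
                             spec = decoding_spec("object",
                                                  n_resample_runs = 2,
                                                  seed = 67))
  expect_equal(dim(M), c(2, 2))
  expect_true(all(M > 0.5))             # strong invariant object code
  expect_lt(max(abs(diag(M) - M[1, 2])), 0.35)
  expect_error(single_epoch_decoding(ds, "go_nogo", "action"),
               "Go trials")
})
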