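test_that("epoch ANOVA detects programmed epoch effects and not constants", {
  set.seed(31)
  # a large additive premovement offset in every trial
  df <- null_unit_rates()
  df$rate[df$epoch == "premovement"] <- df$rate[df$epoch == "premovement"] + 20
  res <- unit_epoch_anova(df, "action")
  expect_lt(res$p_epoch, 0.05)
  expect_true(res$significant)
  expect_false(res$suppressed)

  # suppression direction: strongest epoch deviation below baseline
  df2 <- null_unit_rates(mean_count = 10)
  df2$rate[df2$epoch == "reaching_grasping"] <-
    pmax(df2$rate[df2$epoch == "reaching_grasping"] - 15, 0)
  res2 <- unit_epoch_anova(df2, "action")
  expect_true(res2$suppressed)

  # constant (noise-free) unit: degenerate variance gives p = 1, flagged
  df3 <- null_unit_rates(); df3$rate <- 7
  res3 <- unit_epoch_anova(df3, "action")
  expect_false(res3$significant)
  expect_true(res3$zero_variance)
  expect_equal(res3$p_epoch, 1)

  # too few trials per (object, epoch) cell
  df4 <- null_unit_rates(n_per_object = 1L)
  expect_error(unit_epoch_anova(df4, "action"), "insufficient data")
})

test_that("ANOVA type-I error of the Epoch main effect is near alpha", {
  set.seed(32)
  n <- 400
  hits <- c(action = 0, object = 0)
  for (i in seq_len(n)) {
    a <- unit_epoch_anova(null_unit_rates(), "action")
    o <- unit_epoch_anova(null_unit_rates(epochs = mirrorpop:::EPOCHS_OBJECT),
                          "object")
    hits["action"] <- hits["action"] + (a$p_epoch < 0.05)
    hits["object"] <- hits["object"] + (o$p_epoch < 0.05)
  }
  # binomial(400, 0.05): 3 SD ~ 0.033
  expect_lt(abs(hits[["action"]] / n - 0.05), 0.035)
  expect_lt(abs(hits[["object"]] / n - 0.05), 0.035)
})

test_that("post hoc table appears only with a significant interaction", {
  set.seed(33)
  df <- null_unit_rates()
  # object-specific epoch response: only 'ring' trials respond premovement
  sel <- df$epoch == "premovement" & df$object == "ring"
  df$rate[sel] <- df$rate[sel] + 30
  res <- unit_epoch_anova(df, "action")
  expect_lt(res$p_interaction, 0.05)
  expect_s3_class(res$posthoc, "data.frame")
  # the contrast family: all epoch pairs within each object level
  expect_equal(nrow(res$posthoc), 3 * choose(4, 2))
  expect_true(any(res$posthoc$significant[res$posthoc$object == "ring"]))

  null_res <- unit_epoch_anova(null_unit_rates(), "action")
  if (null_res$p_interaction >= 0.05) expect_null(null_res$posthoc)
})

test_that("agent typing follows the task pattern of significance", {
  mk <- function(sig, eff = 10, sup = FALSE)
    structure(list(significant = sig, effect_size = eff, suppressed = sup),
              class = "mirrorpop_anova")
  # significant action ANOVA in execution only: action-related ST
  cls <- classify_unit(mk(TRUE), mk(FALSE), mk(FALSE), mk(FALSE))
  expect_equal(cls$category, "action_related")
  expect_equal(cls$agent_type_action, "ST")
  expect_equal(cls$agent_type_object, "none")
  # object ANOVA significant in both tasks: object-related SOT
  cls <- classify_unit(mk(FALSE), mk(FALSE), mk(TRUE), mk(TRUE))
  expect_equal(cls$category, "object_related")
  expect_equal(cls$agent_type_object, "SOT")
  # both domains: category 'both'
  cls <- classify_unit(mk(FALSE), mk(TRUE), mk(TRUE), mk(FALSE))
  expect_equal(cls$category, "both")
  expect_equal(cls$agent_type_action, "OT")
  expect_equal(cls$agent_type_object, "ST")
  # nothing significant: none, excluded from the task-related set
  cls <- classify_unit(mk(FALSE), mk(FALSE), mk(FALSE), mk(FALSE))
  expect_equal(cls$category, "none")
  expect_false(cls$task_related)
  # suppression direction follows the stronger responding task
  cls <- classify_unit(mk(TRUE, eff = -8, sup = TRUE), mk(TRUE, eff = 3),
                       mk(FALSE), mk(FALSE))
  expect_true(cls$suppressed_action)
})

test_that("classification partitions task-related units coherently", {
  cl <- shared_classification()
  expect_true(all(cl$category %in% c("action_related", "object_related",
                                     "both", "none")))
  # agent type defined exactly when the domain criterion is met
  expect_true(all((cl$agent_type_action != "none") ==
                    (cl$category %in% c("action_related", "both"))))
  expect_true(all((cl$agent_type_object != "none") ==
                    (cl$category %in% c("object_related", "both"))))
  expect_true(all(cl$task_related == (cl$category != "none")))

  # recovery on the shared strong-effect population: responsive units keep
  # their ground-truth domain, and most agent types match
  gt <- shared_dataset()$ground_truth$units
  m <- merge(cl, gt, by = "unit_id")
  resp <- m[m$category.y != "unresponsive" & m$category.y != "both", ]
  domain <- ifelse(grepl("action", resp$category.y), "action", "object")
  gt_type <- sub("_.*", "", resp$category.y)
  got_type <- ifelse(domain == "action", resp$agent_type_action,
                     resp$agent_type_object)
  expect_gt(mean(got_type == gt_type), 0.8)
})

test_that("extrapersonal control mirrors the designs without affecting typing", {
  ds <- shared_dataset()
  gt <- ds$ground_truth$units
  # an SOT object unit responds in observation but not extrapersonally
  uid <- gt$unit_id[gt$category == "SOT_object" & !gt$suppressed][1]
  ctrl <- extrapersonal_control(ds, uid)
  expect_named(ctrl, c("action", "object"))
  expect_false(ctrl$object$significant)
  obs <- object_anova(ds, uid, "observation")
  expect_true(obs$significant)
})
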