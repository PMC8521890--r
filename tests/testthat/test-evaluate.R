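test_that("confusion counts what happened and conserves the sample count", {
  truth <- c("Walking", "Walking", "Jogging", "Standing")
  cm <- confusion(truth, truth)
  expect_s3_class(cm, "har_confusion")
  expect_equal(sum(diag(cm)), 4)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  cm2 <- confusion(rep("LFD", 3), rep("LS", 3))
  expect_equal(cm2["LFD", "LS"], 3)
  expect_equal(sum(cm2), 3)

  set.seed(20)
  t10k <- sample(activity_levels(), 1e4, replace = TRUE)
  p10k <- sample(activity_levels(), 1e4, replace = TRUE)
  expect_equal(sum(confusion(t10k, p10k)), 1e4)

  expect_error(confusion(t10k, p10k[-1]), "equal length")
  expect_error(confusion("Running", "Walking"), "outside the class set")
})

test_that("per-class percentages reproduce the printed reference tables", {
  totals <- c(ear = 487023L, waist = 487140L, ear_waist = 486726L)
  for (which in c("ear", "waist", "ear_waist")) {
    cm <- benchmark_confusion(which)
    expect_equal(sum(cm), totals[[which]])
    got <- vapply(rownames(cm), class_recall, numeric(1), cm = cm)
    expect_equal(unname(got), printed_row_C[[which]])
    # row-wise C + NC = 100
    s <- class_summary(cm)
    expect_equal(s$recall_pct + s$miss_pct, rep(100, 9))
  }
  ear <- benchmark_confusion("ear")
  got_prec <- vapply(colnames(ear), class_precision, numeric(1), cm = ear)
  expect_equal(unname(got_prec), printed_col_C_ear)
  expect_equal(class_recall(ear, "LFD"), 82.73)
  expect_equal(class_recall(ear, "Sitting"), 6.55)
  expect_equal(class_precision(ear, "Jogging"), 99.69)
})

test_that("degenerate matrices give exact percentages, absent classes NA", {
  diag_cm <- confusion(rep(activity_levels(), 2), rep(activity_levels(), 2))
  for (cl in activity_levels()) {
    expect_equal(class_recall(diag_cm, cl), 100)
    expect_equal(class_precision(diag_cm, cl), 100)
  }
  expect_equal(overall_accuracy(diag_cm), 100)
  # one class never observed: NA, never 0
  cm <- confusion(rep("Walking", 5), rep("Walking", 5))
  expect_true(is.na(class_recall(cm, "Sitting")))
  expect_true(is.na(class_precision(cm, "Sitting")))
  # zero diagonal in a used column
  cm2 <- confusion(rep("LFD", 4), rep("LS", 4))
  expect_equal(class_precision(cm2, "LS"), 0)
})

test_that("overall accuracy equals the row-sum-weighted mean of recalls", {
  set.seed(21)
  t_lab <- sample(activity_levels(), 2000, replace = TRUE)
  p_lab <- ifelse(runif(2000) < 0.6, t_lab,
                  sample(activity_levels(), 2000, replace = TRUE))
  cm <- confusion(t_lab, p_lab)
  rec <- vapply(rownames(cm), function(cl) {
    100 * cm[cl, cl] / sum(cm[cl, ])
  }, numeric(1))
  weighted <- sum(rec * rowSums(cm)) / sum(cm)
  expect_equal(overall_accuracy(cm, digits = NULL), weighted)
  # large balanced random predictions sit near 100/9
  u <- confusion(sample(activity_levels(), 3e4, replace = TRUE),
                 sample(activity_levels(), 3e4, replace = TRUE))
  expect_lt(abs(overall_accuracy(u) - 100 / 9), 1)
})

test_that("tidy and autoplot views of a confusion matrix work", {
  cm <- benchmark_confusion("ear")
  td <- tidy(cm)
  expect_equal(nrow(td), 81)
  expect_equal(sum(td$n), sum(cm))
  p <- autoplot(cm, normalize = TRUE)
  expect_s3_class(p, "ggplot")
})

# shared small cohort for the two harnesses
harness_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- make_cohort(4, sim_config(default_script(rest_s = 3, gait_s = 4,
                                                      fall_s = 1),
                                       trn_duration = 1, seed = 31), seed = 31)
      cache <<- extract_features(coh, stride = 10)
    }
    cache
  }
})

test_that("the ablation harness reports a zero-delta base row per activity", {
  f <- concat_sensors(harness_features(), "ear_left")
  groups <- feature_groups()[c("Mean + SD", "AVC")]
  tab <- ablation_run(f, groups = groups, n_trees = 10, seed = 31)
  expect_equal(nrow(tab), 3 * 10)  # base + 2 groups, OA + 9 activities
  base <- dplyr::filter(tab, feature_set == "ACC only")
  expect_true(all(base$delta_pct == 0))
  expect_identical(ablation_run(f, groups = groups, n_trees = 10, seed = 31),
                   tab)
  expect_error(ablation_run(f, groups = list(Bogus = "wibble"),
                            n_trees = 5, seed = 1), "Unknown feature")
  expect_error(ablation_run(f, groups = c(groups, groups["AVC"]),
                            n_trees = 5, seed = 1), "Duplicate")
})

test_that("the sensor-combination harness counts sensors and features", {
  f <- harness_features()
  combos <- list(L = "ear_left", W = "waist",
                 `L & R` = c("ear_left", "ear_right"),
                 `L, R & W` = c("ear_left", "ear_right", "waist"))
  tab <- sensor_combination_run(f, combos = combos, n_trees = 10, seed = 31)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$n_features[tab$combo == "L"], 33)
  expect_equal(tab$n_features[tab$combo == "L & R"], 66)
  expect_equal(tab$n_features[tab$combo == "L, R & W"], 99)
  expect_true(all(tab$accuracy_pct >= 0 & tab$accuracy_pct <= 100))
  expect_error(sensor_combination_run(f, combos = list(A = "ear_left",
                                                       A = "waist")),
               "Duplicate")
  expect_error(sensor_combination_run(f, combos = list(X = "ankle"),
                                      n_trees = 5), "missing")
})
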