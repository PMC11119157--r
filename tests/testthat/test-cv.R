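test_that("fold plans are stratified, exhaustive and disjoint", {
  trials <- make_random_trials(10, C = 3, fs = 16, dur_s = 1)
  plan <- make_fold_plan(trials, n_outer = 5, n_inner = 4, seed = 3)
  labs <- stats::setNames(vapply(trials, `[[`, "", "label"),
                          vapply(trials, `[[`, "", "trial_id"))
  all_test <- unlist(lapply(plan$outer, `[[`, "test"))
  expect_setequal(all_test, names(labs))       # every trial tested once
  expect_identical(anyDuplicated(all_test), 0L)
  for (f in plan$outer) {
    expect_identical(sum(labs[f$test] == "positive"), 2L)  # 10/5 per class
    expect_identical(sum(labs[f$test] == "negative"), 2L)
    for (g in f$inner) {
      expect_length(intersect(f$test, c(g$train, g$val)), 0L)
      expect_length(intersect(g$train, g$val), 0L)
      expect_setequal(c(g$train, g$val), setdiff(names(labs), f$test))
    }
  }
})

test_that("13 trials split over 5 folds as sizes 3,3,3,2,2", {
  trials <- c(make_random_trials(13, C = 3, fs = 16,
                                 dur_s = 1)[1:13],       # 13 positive
              make_random_trials(6, C = 3, fs = 16, dur_s = 1)[7:12])
  plan <- make_fold_plan(trials, n_outer = 5, n_inner = 4, seed = 9)
  labs <- stats::setNames(vapply(trials, `[[`, "", "label"),
                          vapply(trials, `[[`, "", "trial_id"))
  sizes <- sort(vapply(plan$outer, function(f)
    sum(labs[f$test] == "positive"), 0L))
  expect_identical(sizes, c(2L, 2L, 3L, 3L, 3L))
  expect_error(make_fold_plan(trials[1:13], n_outer = 5),
               "two classes")
  expect_error(make_fold_plan(trials[c(1:13, 14)], n_outer = 5),
               "at least 5 trials")
})

test_that("fold plans are reproducible from the seed alone", {
  trials <- make_random_trials(7, C = 3, fs = 16, dur_s = 1)
  p1 <- make_fold_plan(trials, seed = 42)
  p2 <- make_fold_plan(trials, seed = 42)
  expect_identical(p1, p2)
  p3 <- make_fold_plan(trials, seed = 43)
  expect_false(identical(p1$outer, p3$outer))
})

test_that("confusion-matrix metrics follow the printed formulas", {
  m <- compute_metrics(50, 50, 0, 0)
  expect_identical(m$ACC, 1)
  expect_identical(m$F1, 1)
  m2 <- compute_metrics(3, 4, 1, 2)
  expect_equal(m2$ACC, 0.7)
  expect_equal(m2$Precision, 0.75)
  expect_equal(m2$Recall, 0.6)
  expect_equal(m2$F1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_warning(expect_warning(m3 <- compute_metrics(0, 5, 0, 2),
                                "precision"), "F1")
  expect_identical(m3$Precision, 0)
  expect_identical(m3$F1, 0)
  expect_error(compute_metrics(0, 0, 0, 0), "no test samples")
})

test_that("early stopping with patience 0 stops at the first stall", {
  trials <- tiny_sim_dataset(4, seed = 91)
  segs <- segment_trials(trials, 4, 2)
  ctrl <- tiny_control(max_epochs = 6, patience = 0,
                       learning_rate = 0.5)    # large step forces a stall
  fit <- emognn(segs[1:16], tiny_model_config(), ctrl,
                validation = segs[17:24])
  h <- fit$history
  stalls <- which(diff(c(Inf, cummin(h$val_loss))) >= 0)
  if (length(stalls)) {
    # training ran exactly one epoch beyond the last improvement
    expect_identical(fit$epochs_run, min(stalls))
  } else {
    expect_identical(fit$epochs_run, ctrl$max_epochs)
  }
})

test_that("train_fold and finetune_and_test respect the fold boundaries", {
  trials <- tiny_sim_dataset(5, seed = 92)
  segs <- segment_trials(trials, 4, 2)
  plan <- make_fold_plan(trials, n_outer = 5, n_inner = 4, seed = 5)
  cfg <- tiny_model_config()
  cfg$labels <- sort(unique(vapply(trials, `[[`, "", "label")))
  ctrl <- tiny_control(max_epochs = 2, fine_tune_epochs = 1)
  fits <- lapply(1:4, function(g)
    train_fold(plan, 1, g, segs, cfg, ctrl))
  for (g in 1:4) {
    src <- unlist(lapply(fits[[g]]$adjacency, `[[`, "source_ids"))
    expect_length(intersect(src, plan$outer[[1]]$test), 0L)
    expect_setequal(src, plan$outer[[1]]$inner[[g]]$train)
    expect_true(fits[[g]]$val_acc >= 0 && fits[[g]]$val_acc <= 1)
  }
  res <- finetune_and_test(plan, 1, fits, segs, cfg, ctrl)
  expect_s3_class(res$metrics, "data.frame")
  expect_identical(res$metrics$TP + res$metrics$TN + res$metrics$FP +
                     res$metrics$FN,
                   length(emognn:::segments_of(segs,
                                               plan$outer[[1]]$test)))
  expect_true(res$best_inner %in% 1:4)
  # the selected model maximizes inner validation accuracy
  accs <- vapply(fits, `[[`, 0, "val_acc")
  expect_identical(accs[res$best_inner], max(accs))
  # fine_tune_epochs = 0 evaluates the inner-best parameters directly
  ctrl0 <- tiny_control(max_epochs = 2, fine_tune_epochs = 0)
  res0 <- finetune_and_test(plan, 1, fits, segs, cfg, ctrl0)
  expect_s3_class(res0$metrics, "data.frame")
})

test_that("nested cross-validation reports coherent per-fold metrics", {
  trials <- tiny_sim_dataset(5, seed = 93)
  cv <- emognn_cv(trials, window_s = 4, overlap_s = 2,
                  config = tiny_model_config(),
                  control = tiny_control(max_epochs = 2,
                                         fine_tune_epochs = 1))
  expect_identical(nrow(cv$metrics), 5L)
  expect_true(all(cv$metrics$ACC >= 0 & cv$metrics$ACC <= 1))
  # reported mean equals the arithmetic mean of the fold ACCs
  expect_equal(cv$summary$mean[cv$summary$metric == "ACC"],
               mean(cv$metrics$ACC), tolerance = 1e-12)
  expect_identical(nrow(cv$trial_metrics), 5L)
  expect_identical(dim(cv$inner_val_acc), c(5L, 4L))
  expect_output(print(cv), "Nested cross-validation")
})
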