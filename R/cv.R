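# Trial-wise stratified nested cross-validation: a 5-fold outer loop gives
# unbiased test estimates; a 4-fold inner loop drives early stopping and
# model selection; segments always follow their parent trial, so no segment
# of a test trial can leak into training, validation or adjacency
# construction.

balanced_split <- function(ids, k) {
  n <- length(ids)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  split(ids, rep(seq_len(k), times = sizes))
}

#' Build a stratified trial-wise nested cross-validation plan
#'
#' Trials of each class are shuffled and split into `n_outer` near-equal
#' outer folds; within each outer training set, `n_inner` inner folds per
#' class define train/validation splits.  All assignments are keyed on trial
#' ids -- segments inherit their parent trial's fold.
#'
#' @param trials list of labelled [eeg_trial()] objects.
#' @param n_outer,n_inner fold counts (defaults 5 and 4).
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return An object of class `fold_plan`: `labels`, and `outer`, a list of
#'   `n_outer` folds each holding `test` trial ids and `inner`, a list of
#'   `n_inner` `(train, val)` id sets.
#' @export
make_fold_plan <- function(trials, n_outer = 5L, n_inner = 4L, seed = 1L) {
  labs <- vapply(trials, function(tr) tr$label, "")
  ids <- vapply(trials, function(tr) tr$trial_id, "")
  if (anyDuplicated(ids)) stop("trial ids must be unique")
  labels <- sort(unique(labs))
  if (length(labels) != 2L) stop("exactly two classes are required")
  counts <- table(labs)
  if (any(counts < n_outer))
    stop(sprintf("need at least %d trials per class, have %s", n_outer,
                 paste(sprintf("%s: %d", names(counts), counts),
                       collapse = ", ")))
  with_seed(seed, {
    outer_by_class <- lapply(labels, function(l)
      balanced_split(sample(ids[labs == l]), n_outer))
    outer <- lapply(seq_len(n_outer), function(f) {
      test <- unlist(lapply(outer_by_class, `[[`, f), use.names = FALSE)
      rest_by_class <- lapply(labels, function(l) {
        pool <- setdiff(ids[labs == l], test)
        balanced_split(sample(pool), n_inner)
      })
      inner <- lapply(seq_len(n_inner), function(g) {
        val <- unlist(lapply(rest_by_class, `[[`, g), use.names = FALSE)
        train <- setdiff(unlist(rest_by_class, use.names = FALSE), val)
        list(train = train, val = val)
      })
      list(test = test, inner = inner)
    })
    structure(list(labels = labels, n_outer = as.integer(n_outer),
                   n_inner = as.integer(n_inner), seed = as.integer(seed),
                   outer = outer),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d outer x %d inner folds, classes %s (seed %d)\n",
              x$n_outer, x$n_inner, paste(x$labels, collapse = "/"),
              x$seed))
  for (f in seq_len(x$n_outer))
    cat(sprintf("  outer %d: %d test trials\n", f,
                length(x$outer[[f]]$test)))
  invisible(x)
}

segments_of <- function(segments, trial_ids) {
  pid <- vapply(segments, function(s) s$parent_trial_id %||% s$trial_id, "")
  segments[pid %in% trial_ids]
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 from the four confusion-matrix counts.
#' Ratios with zero denominators are reported as 0 with a warning.
#'
#' @param tp,tn,fp,fn nonnegative counts; their sum must be positive.
#' @return A one-row data frame with columns `TP`, `TN`, `FP`, `FN`, `ACC`,
#'   `Precision`, `Recall`, `F1`.
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("no test samples: all counts are zero")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0")
      0
    } else num / den
  }
  acc <- (tp + tn) / total
  prec <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * prec * rec, prec + rec, "F1")
  data.frame(TP = tp, TN = tn, FP = fp, FN = fn, ACC = acc,
             Precision = prec, Recall = rec, F1 = f1)
}

confusion_counts <- function(true, pred, positive) {
  list(tp = sum(true == positive & pred == positive),
       tn = sum(true != positive & pred != positive),
       fp = sum(true != positive & pred == positive),
       fn = sum(true == positive & pred != positive))
}

# Internal: train one model on given train/val segment sets using
# precomputed per-segment connectivity matrices when available.
fit_inner <- function(train_segs, val_segs, config, control, seed,
                      conn_cache = NULL, init = NULL, n_epochs = NULL,
                      early_stop = TRUE) {
  labels <- config$labels %||% sort(unique(seg_labels(train_segs)))
  adjacency <- NULL
  an <- NULL
  if (config$gcn_block) {
    adjacency <- if (is.null(conn_cache)) {
      stats::setNames(lapply(config$variants, function(v)
        build_task_adjacency(train_segs, config$conn[[v]],
                             labels = labels)), config$variants)
    } else {
      sl <- seg_labels(train_segs)
      sid <- vapply(train_segs, function(s) s$trial_id, "")
      pids <- vapply(train_segs,
                     function(s) s$parent_trial_id %||% s$trial_id, "")
      stats::setNames(lapply(config$variants, function(v)
        task_adjacency_from_mats(conn_cache[[v]][sid], sl, labels, v,
                                 source_ids = unique(pids))),
        config$variants)
    }
    an <- adj_norm_list(adjacency, config)
  }
  fit <- with_seed(seed,
    fit_core(lapply(train_segs, seg_data),
             match(seg_labels(train_segs), labels), an, config, control,
             val_xs = if (length(val_segs)) lapply(val_segs, seg_data),
             val_ys = if (length(val_segs))
               match(seg_labels(val_segs), labels),
             init = init, n_epochs = n_epochs, early_stop = early_stop))
  list(fit = fit, adjacency = adjacency, an = an, labels = labels)
}

#' Train one inner fold of the nested cross-validation
#'
#' Builds the task adjacencies from the inner-loop *training* segments only,
#' trains with early stopping on the fold's validation segments, and
#' returns the best-epoch model with its validation score.
#'
#' @param plan a [make_fold_plan()].
#' @param outer_fold,inner_fold fold indices.
#' @param segments list of all segments (their parent trial ids route them
#'   to folds).
#' @param config an [emognn_config()].
#' @param control an [emognn_control()]; the fit's seed is derived from
#'   `control$seed` and the fold indices.
#' @return List with `params` (best-epoch parameters), `val_acc`,
#'   `val_loss`, `adjacency`, `history`.
#' @export
train_fold <- function(plan, outer_fold, inner_fold, segments, config,
                       control = emognn_control()) {
  fold <- plan$outer[[outer_fold]]$inner[[inner_fold]]
  r <- fit_inner(segments_of(segments, fold$train),
                 segments_of(segments, fold$val),
                 config, control,
                 seed = control$seed + 1000L * outer_fold + inner_fold)
  list(params = r$fit$params, val_acc = r$fit$val_acc,
       val_loss = r$fit$val_loss, adjacency = r$adjacency,
       history = r$fit$history, labels = r$labels)
}

#' Fine-tune the best inner model and evaluate on the outer test fold
#'
#' The inner model with the highest validation accuracy (ties broken by
#' lowest validation loss, then lowest fold index) is trained for
#' `control$fine_tune_epochs` more epochs on all training + validation
#' segments -- with the task adjacencies rebuilt from that pooled set --
#' and evaluated once on the untouched outer test segments.
#'
#' @inheritParams train_fold
#' @param inner_fits list of [train_fold()] results, one per inner fold.
#' @return List with `metrics` (a [compute_metrics()] row), `pred`, `true`,
#'   `best_inner`.
#' @export
finetune_and_test <- function(plan, outer_fold, inner_fits, segments,
                              config, control = emognn_control()) {
  accs <- vapply(inner_fits, `[[`, 0, "val_acc")
  losses <- vapply(inner_fits, `[[`, 0, "val_loss")
  best_inner <- order(-accs, losses, seq_along(accs))[1L]
  fold <- plan$outer[[outer_fold]]
  trainval_ids <- unique(unlist(lapply(fold$inner, function(f)
    c(f$train, f$val)), use.names = FALSE))
  stopifnot(!any(fold$test %in% trainval_ids))
  trainval <- segments_of(segments, trainval_ids)
  test <- segments_of(segments, fold$test)
  labels <- inner_fits[[best_inner]]$labels
  cfg <- config
  cfg$labels <- labels
  r <- fit_inner(trainval, NULL, cfg, control,
                 seed = control$seed + 1000L * outer_fold,
                 init = inner_fits[[best_inner]]$params,
                 n_epochs = control$fine_tune_epochs, early_stop = FALSE)
  if (config$gcn_block)
    stopifnot(!any(fold$test %in% unlist(lapply(r$adjacency,
                                                `[[`, "source_ids"))))
  logits <- t(vapply(test, function(s)
    forward_segment(r$fit$final_params, seg_data(s), r$an, cfg)$logits,
    numeric(2L)))
  pred <- labels[max.col(logits, ties.method = "first")]
  true <- seg_labels(test)
  cc <- confusion_counts(true, pred, labels[1L])
  list(metrics = compute_metrics(cc$tp, cc$tn, cc$fp, cc$fn),
       pred = pred, true = true,
       test_trial = vapply(test, function(s)
         s$parent_trial_id %||% s$trial_id, ""),
       best_inner = best_inner)
}

#' Nested cross-validation of the EEG graph-attention classifier
#'
#' Runs the full protocol: segment the trials, split them into stratified
#' trial-wise outer/inner folds, train each inner fold with early stopping
#' (task adjacencies from inner training segments only), select the best
#' inner model per outer fold, fine-tune it on the pooled
#' training + validation segments, and test once on the outer test
#' segments.  Per-segment connectivity matrices are computed once and
#' averaged per fold, which is equivalent to building each fold's
#' adjacencies from scratch.
#'
#' @param trials list of labelled [eeg_trial()] objects.
#' @param window_s,overlap_s segmentation parameters (see
#'   [segment_trial()]).
#' @param config an [emognn_config()].
#' @param control an [emognn_control()]; `control$seed` drives fold
#'   shuffling, weight initialization and batch order.
#' @param n_outer,n_inner fold counts.
#' @return An object of class `emognn_cv`: per-fold `metrics`
#'   (segment-level), `trial_metrics` (majority vote per trial), `summary`
#'   (mean and sd of the fold metrics), the `fold_plan`, and per-fold
#'   validation accuracies.
#' @export
emognn_cv <- function(trials, window_s, overlap_s, config,
                      control = emognn_control(), n_outer = 5L,
                      n_inner = 4L) {
  plan <- make_fold_plan(trials, n_outer, n_inner, seed = control$seed)
  labels <- config$labels %||% plan$labels
  config$labels <- labels
  segments <- segment_trials(trials, window_s, overlap_s)
  conn_cache <- NULL
  if (config$gcn_block) {
    conn_cache <- stats::setNames(lapply(config$variants, function(v) {
      mats <- lapply(segments, connectivity_matrix,
                     spec = config$conn[[v]])
      names(mats) <- vapply(segments, function(s) s$trial_id, "")
      mats
    }), config$variants)
  }
  fold_rows <- vector("list", n_outer)
  trial_rows <- vector("list", n_outer)
  inner_acc <- matrix(NA_real_, n_outer, n_inner)
  for (f in seq_len(n_outer)) {
    fits <- vector("list", n_inner)
    for (g in seq_len(n_inner)) {
      fold <- plan$outer[[f]]$inner[[g]]
      r <- fit_inner(segments_of(segments, fold$train),
                     segments_of(segments, fold$val),
                     config, control,
                     seed = control$seed + 1000L * f + g,
                     conn_cache = conn_cache)
      if (config$gcn_block)
        stopifnot(!any(plan$outer[[f]]$test %in%
                         unlist(lapply(r$adjacency, `[[`, "source_ids"))))
      fits[[g]] <- list(params = r$fit$params, val_acc = r$fit$val_acc,
                        val_loss = r$fit$val_loss, labels = r$labels)
      inner_acc[f, g] <- r$fit$val_acc
    }
    res <- finetune_and_test(plan, f, fits, segments, config, control)
    fold_rows[[f]] <- cbind(fold = f, res$metrics)
    # trial-level majority vote (secondary report)
    votes <- tapply(res$pred == labels[1L], res$test_trial, mean)
    tr_pred <- ifelse(votes >= 0.5, labels[1L], labels[2L])
    tr_true <- vapply(names(votes), function(id)
      trials[[which(vapply(trials, function(tr) tr$trial_id, "") == id)]]$label,
      "")
    cc <- confusion_counts(tr_true, tr_pred, labels[1L])
    trial_rows[[f]] <- cbind(fold = f,
                             compute_metrics(cc$tp, cc$tn, cc$fp, cc$fn))
  }
  metrics <- do.call(rbind, fold_rows)
  trial_metrics <- do.call(rbind, trial_rows)
  cols <- c("ACC", "Precision", "Recall", "F1")
  structure(list(metrics = metrics, trial_metrics = trial_metrics,
                 summary = data.frame(
                   metric = cols,
                   mean = vapply(cols, function(cl) mean(metrics[[cl]]), 0),
                   sd = vapply(cols, function(cl) stats::sd(metrics[[cl]]),
                               0)),
                 inner_val_acc = inner_acc, fold_plan = plan,
                 labels = labels, config = config, control = control,
                 seed = control$seed),
            class = "emognn_cv")
}

#' @export
print.emognn_cv <- function(x, ...) {
  cat(sprintf("Nested cross-validation (%d outer x %d inner folds, seed %d)\n",
              x$fold_plan$n_outer, x$fold_plan$n_inner, x$seed))
  cat(sprintf("  variants: %s\n", paste(x$config$variants, collapse = ", ")))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  mean %-9s %.4f (sd %.4f)\n", s$metric[i], s$mean[i],
                s$sd[i]))
  invisible(x)
}

#' @export
summary.emognn_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold segment-level metrics:\n")
  print(object$metrics, row.names = FALSE)
  cat("\nPer-fold trial-level (majority vote) metrics:\n")
  print(object$trial_metrics, row.names = FALSE)
  invisible(object)
}
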