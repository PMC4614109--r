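#' Confusion counts with active (1) as the positive class
#'
#' @param predicted,truth integer vectors of class codes in `{1, 2}`, equal
#'   length.
#' @return An object of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn` (their sum equals the number of evaluated compounds).
#' @export
confusion_counts <- function(predicted, truth) {
  elm_assert(length(predicted) == length(truth), "elm_dimension_error",
             "predicted and true labels must have equal length")
  elm_assert(all(predicted %in% c(1L, 2L)) && all(truth %in% c(1L, 2L)),
             "elm_label_error", "labels must be 1 (active) or 2 (inactive)")
  structure(list(tp = sum(predicted == 1 & truth == 1),
                 tn = sum(predicted == 2 & truth == 2),
                 fp = sum(predicted == 1 & truth == 2),
                 fn = sum(predicted == 2 & truth == 1)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity and MCC from confusion counts
#'
#' `Sen = TP/(TP+FN) * 100`, `Spec = TN/(TN+FP) * 100`,
#' `Acc = (TP+TN)/(TP+TN+FP+FN) * 100` (all percentages), and the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` in
#' `[-1, 1]`. When the MCC denominator is zero (a degenerate margin) the MCC
#' is defined as 0; an undefined sensitivity/specificity (empty class) is
#' reported as `NaN`.
#'
#' @param counts a [confusion_counts()] object, or predicted labels (then
#'   `truth` must be given).
#' @param truth true labels, when `counts` holds predictions.
#' @return An object of class `metrics_report` with fields `acc`, `sen`,
#'   `spec` (percent), `mcc`, and `counts`.
#' @export
classification_metrics <- function(counts, truth = NULL) {
  if (!inherits(counts, "confusion_counts"))
    counts <- confusion_counts(counts, truth)
  tp <- as.double(counts$tp); tn <- as.double(counts$tn)
  fp <- as.double(counts$fp); fn <- as.double(counts$fn)
  total <- tp + tn + fp + fn
  elm_assert(total > 0, "elm_dimension_error", "metrics need at least one prediction")
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  structure(list(acc = 100 * (tp + tn) / total,
                 sen = 100 * tp / (tp + fn),
                 spec = 100 * tn / (tn + fp),
                 mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom,
                 counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Acc %.2f%%  Sen %.2f%%  Spec %.2f%%  MCC %.3f  (tp=%d tn=%d fp=%d fn=%d)\n",
              x$acc, x$sen, x$spec, x$mcc,
              x$counts$tp, x$counts$tn, x$counts$fp, x$counts$fn))
  invisible(x)
}

# stratified fold ids: within each class, shuffle and deal out 1..k cyclically,
# so fold sizes differ by at most one within each class.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    folds <- integer(length(labels))
    for (cls in c(1L, 2L)) {
      idx <- which(labels == cls)
      elm_assert(length(idx) >= k, "elm_fold_error",
                 sprintf("class %d has %d members, fewer than k = %d folds",
                         cls, length(idx), k))
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

#' Stratified k-fold cross-validation
#'
#' Randomly partitions the compounds into `k` class-stratified folds, then
#' for each fold fits the full training procedure on the other `k - 1` folds
#' and evaluates predictions on the held-out fold. Reported are per-fold
#' metrics, their per-fold average (the "averaged across the validated
#' subsets" convention), and pooled metrics over all held-out predictions.
#'
#' @param dataset a curated [labeled_dataset()]; each class needs at least
#'   `k` compounds.
#' @param trainer a function `(dataset, seed) -> model` where the returned
#'   model supports `predict(model, x)` returning 1/2 labels; see
#'   [elm_trainer()]. It is called with fold-specific seeds derived from
#'   `seed`, so every fold's training (including any internal GA) is
#'   reproducible.
#' @param k number of folds (default 10).
#' @param seed seed controlling both fold assignment and the per-fold
#'   training seeds.
#' @return An object of class `cv_result`: `folds` (fold id per compound),
#'   `per_fold` (list of `metrics_report`), `averaged` (per-fold mean of each
#'   metric), `pooled` (metrics over all validation predictions), `k`,
#'   `seed`.
#' @export
kfold_cv <- function(dataset, trainer, k = 10, seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"), is.function(trainer))
  assert_trainable(dataset)
  folds <- stratified_folds(dataset$labels, k, derive_seed(seed, 0))
  per_fold <- vector("list", k)
  pooled_pred <- integer(length(folds))
  for (j in seq_len(k)) {
    hold <- folds == j
    train_ds <- labeled_dataset(dataset$x[!hold, , drop = FALSE],
                                dataset$labels[!hold],
                                if (!is.null(dataset$pic50)) dataset$pic50[!hold])
    model <- trainer(train_ds, derive_seed(seed, j))
    pred <- predict(model, dataset$x[hold, , drop = FALSE])
    pooled_pred[hold] <- pred
    per_fold[[j]] <- classification_metrics(pred, dataset$labels[hold])
  }
  avg <- function(field) mean(vapply(per_fold, `[[`, numeric(1), field))
  structure(list(folds = folds, per_fold = per_fold,
                 averaged = list(acc = avg("acc"), sen = avg("sen"),
                                 spec = avg("spec"), mcc = avg("mcc")),
                 pooled = classification_metrics(pooled_pred, dataset$labels),
                 k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV (seed %d)\n  pooled:   ", x$k, x$seed))
  print(x$pooled)
  cat(sprintf("  averaged: Acc %.2f%%  Sen %.2f%%  Spec %.2f%%  MCC %.3f\n",
              x$averaged$acc, x$averaged$sen, x$averaged$spec, x$averaged$mcc))
  invisible(x)
}

#' Default ELM trainer for the CV and experiment harnesses
#'
#' Returns a `(dataset, seed) -> model` closure wrapping [elm_train()]. With
#' `nested = TRUE` descriptor selection ([select_descriptors_ga()]) is re-run
#' inside every training fold (no information leak from validation folds);
#' with the default `nested = FALSE` the supplied descriptor set — typically
#' selected once on the full data, as the original protocol does — is reused
#' in every fold.
#'
#' @param descriptors descriptor names (or a `selection_result`) used when
#'   `nested = FALSE`.
#' @param optimizer an [optimizer_config()]; its seed is replaced by the
#'   per-call seed.
#' @param nested re-run GA selection inside each training fold.
#' @param selection a [selection_config()] used when `nested = TRUE`.
#' @param standardize,threshold_mode passed to [elm_train()].
#' @return A trainer function for [kfold_cv()] / [repeat_experiments()].
#' @export
elm_trainer <- function(descriptors = NULL, optimizer = optimizer_config(),
                        nested = FALSE, selection = selection_config(),
                        standardize = TRUE, threshold_mode = "midpoint") {
  if (inherits(descriptors, "selection_result")) descriptors <- descriptors$selected
  force(optimizer); force(selection); force(standardize); force(threshold_mode)
  function(dataset, seed) {
    opt <- optimizer
    opt$seed <- as.integer(seed)
    desc <- descriptors
    if (nested) {
      sel_cfg <- selection
      sel_cfg$seed <- derive_seed(seed, 15)
      sel <- select_descriptors_ga(dataset, sel_cfg)
      desc <- if (length(sel$selected)) sel$selected else sel$best_subset
    }
    elm_assert(length(desc) >= 1, "elm_empty_selection_error",
               "trainer has no descriptors to train on")
    elm_train(dataset, desc, config = opt, standardize = standardize,
              threshold_mode = threshold_mode)
  }
}

#' Repeated train + cross-validation experiments
#'
#' Runs the full protocol `R` times (the method is stochastic, so repeated
#' experiments with different seeds characterize its variability): for run
#' `r` the trainer is fitted on the full data with seed `base_seed + r - 1`
#' (training metrics) and evaluated by [kfold_cv()] with the same run seed.
#' Reports per-run rows plus the mean and sample standard deviation of every
#' metric, and identifies the best run by CV MCC.
#'
#' @param dataset a curated [labeled_dataset()].
#' @param trainer see [kfold_cv()].
#' @param R number of repeated experiments (default 10).
#' @param k folds per experiment (default 10).
#' @param base_seed seed of the first run; run `r` uses `base_seed + r - 1`.
#' @param cv_metric `"pooled"` or `"averaged"` CV metrics in the summary
#'   table.
#' @return An object of class `experiment_summary`: `runs` (data frame, one
#'   row per run: seed, train and CV Acc/Sen/Spec/MCC), `mean`, `sd` (named
#'   vectors over the metric columns; sample sd, 0 when `R = 1`),
#'   `best_run` (index, by CV MCC), `cv_results` and `models` (per-run
#'   objects), `base_seed`.
#' @export
repeat_experiments <- function(dataset, trainer, R = 10, k = 10, base_seed = 1,
                               cv_metric = c("pooled", "averaged")) {
  cv_metric <- match.arg(cv_metric)
  elm_assert(R >= 1, "elm_config_error", "need R >= 1 experiments")
  rows <- vector("list", R)
  cvs <- vector("list", R)
  models <- vector("list", R)
  for (r in seq_len(R)) {
    run_seed <- as.integer(base_seed + r - 1)
    model <- trainer(dataset, run_seed)
    models[[r]] <- model
    tr <- classification_metrics(predict(model, dataset$x), dataset$labels)
    cv <- kfold_cv(dataset, trainer, k = k, seed = run_seed)
    cvs[[r]] <- cv
    cvm <- if (cv_metric == "pooled")
      list(acc = cv$pooled$acc, sen = cv$pooled$sen,
           spec = cv$pooled$spec, mcc = cv$pooled$mcc)
    else cv$averaged
    rows[[r]] <- data.frame(run = r, seed = run_seed,
                            train_acc = tr$acc, train_sen = tr$sen,
                            train_spec = tr$spec, train_mcc = tr$mcc,
                            cv_acc = cvm$acc, cv_sen = cvm$sen,
                            cv_spec = cvm$spec, cv_mcc = cvm$mcc)
  }
  runs <- do.call(rbind, rows)
  metric_cols <- setdiff(names(runs), c("run", "seed"))
  means <- vapply(runs[metric_cols], mean, numeric(1))
  sds <- if (R == 1) stats::setNames(rep(0, length(metric_cols)), metric_cols)
         else vapply(runs[metric_cols], stats::sd, numeric(1))
  structure(list(runs = runs, mean = means, sd = sds,
                 best_run = which.max(runs$cv_mcc), cv_results = cvs,
                 models = models, R = R, k = k, base_seed = base_seed,
                 cv_metric = cv_metric),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, digits = 2, ...) {
  cat(sprintf("%d repeated experiments (%d-fold CV, %s CV metrics, seeds %d..%d)\n",
              x$R, x$k, x$cv_metric, x$base_seed, x$base_seed + x$R - 1))
  print(format(x$runs, digits = digits + 2), row.names = FALSE)
  ms <- sprintf("%.*f ± %.*f", digits, x$mean, digits, x$sd)
  cat("  mean ± sd: ",
      paste(names(x$mean), ms, sep = " = ", collapse = ", "), "\n", sep = "")
  cat(sprintf("  best run by CV MCC: run %d (MCC %.3f)\n",
              x$best_run, x$runs$cv_mcc[x$best_run]))
  invisible(x)
}
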