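test_that("confusion counting matches a brute-force loop", {
  cc <- confusion_counts(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_identical(unclass(cc)[c("tp", "tn", "fp", "fn")],
                   list(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  inv <- confusion_counts(3 - c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_identical(c(inv$tp, inv$tn), c(0L, 0L))

  set.seed(101)
  pred <- sample(1:2, 200, replace = TRUE)
  truth <- sample(1:2, 200, replace = TRUE)
  cc <- confusion_counts(pred, truth)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:200) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    if (pred[i] == 2 && truth[i] == 2) tn <- tn + 1L
    if (pred[i] == 1 && truth[i] == 2) fp <- fp + 1L
    if (pred[i] == 2 && truth[i] == 1) fn <- fn + 1L
  }
  expect_identical(c(cc$tp, cc$tn, cc$fp, cc$fn), c(tp, tn, fp, fn))
  expect_identical(cc$tp + cc$tn + cc$fp + cc$fn, 200L)
  expect_error(confusion_counts(c(1, 3), c(1, 2)), class = "elm_label_error")
})

test_that("metric formulas and their conventions are exact", {
  perfect <- classification_metrics(structure(list(tp = 5L, tn = 5L, fp = 0L, fn = 0L),
                                              class = "confusion_counts"))
  expect_identical(c(perfect$acc, perfect$sen, perfect$spec, perfect$mcc),
                   c(100, 100, 100, 1))
  chance <- classification_metrics(structure(list(tp = 25L, tn = 25L, fp = 25L, fn = 25L),
                                             class = "confusion_counts"))
  expect_identical(c(chance$acc, chance$mcc), c(50, 0))
  m <- classification_metrics(structure(list(tp = 90L, tn = 50L, fp = 50L, fn = 10L),
                                        class = "confusion_counts"))
  expect_equal(c(m$sen, m$spec, m$acc), c(90, 50, 70))
  expect_equal(m$mcc, (90 * 50 - 50 * 10) / sqrt(140 * 100 * 100 * 60), tolerance = 1e-12)
})

test_that("MCC equals the Pearson correlation of the indicator vectors", {
  set.seed(111)
  for (rep in 1:20) {
    pred <- sample(1:2, 80, replace = TRUE)
    truth <- sample(1:2, 80, replace = TRUE)
    m <- classification_metrics(pred, truth)
    r <- suppressWarnings(cor(as.numeric(pred == 1), as.numeric(truth == 1)))
    if (is.na(r)) r <- 0  # degenerate margin: MCC convention is 0
    expect_equal(m$mcc, r, tolerance = 1e-12)
  }
})

test_that("class-label swap exchanges Sen/Spec and leaves MCC unchanged", {
  set.seed(121)
  pred <- sample(1:2, 100, replace = TRUE)
  truth <- sample(1:2, 100, replace = TRUE)
  m <- classification_metrics(pred, truth)
  sw <- classification_metrics(3L - pred, 3L - truth)
  expect_identical(c(sw$sen, sw$spec), c(m$spec, m$sen))
  expect_identical(c(sw$counts$tp, sw$counts$tn, sw$counts$fp, sw$counts$fn),
                   c(m$counts$tn, m$counts$tp, m$counts$fn, m$counts$fp))
  expect_equal(sw$mcc, m$mcc, tolerance = 1e-12)
})

test_that("metrics stay in range on random confusion tables", {
  set.seed(131)
  for (i in 1:1000) {
    cts <- structure(as.list(sample(0:30, 4, replace = TRUE)),
                     names = c("tp", "tn", "fp", "fn"), class = "confusion_counts")
    if (cts$tp + cts$tn + cts$fp + cts$fn == 0) next
    m <- classification_metrics(cts)
    expect_true(m$acc >= 0 && m$acc <= 100)
    expect_true(is.nan(m$sen) || (m$sen >= 0 && m$sen <= 100))
    expect_true(is.nan(m$spec) || (m$spec >= 0 && m$spec <= 100))
    expect_true(m$mcc >= -1 && m$mcc <= 1)
  }
})

test_that("cross-validation folds are a stratified partition and metrics pool correctly", {
  ds <- make_tiny_dataset(n = 46, seed = 141)
  cv <- kfold_cv(ds, elm_trainer(c("D1", "D2"),
                                 optimizer_config(max_generations = 10)),
                 k = 5, seed = 2)
  # partition: every compound in exactly one fold
  expect_identical(length(cv$folds), nrow(ds$x))
  expect_true(all(cv$folds %in% 1:5))
  # stratified: within each class fold sizes differ by at most 1
  for (cls in 1:2) {
    sizes <- table(cv$folds[ds$labels == cls])
    expect_lte(diff(range(sizes)), 1)
  }
  # pooled counts cover the whole dataset
  cts <- cv$pooled$counts
  expect_identical(cts$tp + cts$tn + cts$fp + cts$fn, nrow(ds$x))
  # averaged = mean of per-fold metrics
  expect_equal(cv$averaged$acc, mean(sapply(cv$per_fold, `[[`, "acc")), tolerance = 1e-12)

  # leave-one-out on a tiny set: every compound validated exactly once
  tiny <- make_tiny_dataset(n = 8, seed = 151)
  loo <- kfold_cv(tiny, function(dataset, seed) constant_model(1L), k = 4, seed = 1)
  expect_true(all(table(loo$folds) == 2))

  # constant-predictor closed form: everything called active
  call_all <- kfold_cv(ds, function(dataset, seed) constant_model(1L), k = 5, seed = 3)
  expect_identical(call_all$pooled$sen, 100)
  expect_identical(call_all$pooled$spec, 0)

  expect_error(kfold_cv(make_tiny_dataset(n = 10), function(d, s) constant_model(1L),
                        k = 8, seed = 1),
               class = "elm_fold_error")
})

test_that("repeated experiments report exact means and sds over per-run rows", {
  ds <- make_tiny_dataset(n = 44, seed = 161)
  trainer <- elm_trainer(c("D1", "D2"), optimizer_config(max_generations = 10))
  exps <- repeat_experiments(ds, trainer, R = 3, k = 4, base_seed = 5)
  expect_identical(nrow(exps$runs), 3L)
  expect_identical(exps$runs$seed, 5:7)
  for (col in names(exps$mean)) {
    expect_equal(exps$mean[[col]], mean(exps$runs[[col]]), tolerance = 1e-12)
    expect_equal(exps$sd[[col]], sd(exps$runs[[col]]), tolerance = 1e-12)
  }
  expect_identical(exps$best_run, which.max(exps$runs$cv_mcc))

  # R = 1: sd reported as exact 0
  one <- repeat_experiments(ds, trainer, R = 1, k = 4, base_seed = 5)
  expect_true(all(one$sd == 0))

  # deterministic (constant) trainer: identical runs, sd exactly 0
  const <- repeat_experiments(ds, function(d, s) constant_model(1L),
                              R = 3, k = 4, base_seed = 1)
  expect_true(all(const$sd == 0))
})
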