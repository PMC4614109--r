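test_that("CSV loading maps labels and preserves values, IDs and column order", {
  path <- write_tiny_csv(c("Compound,CLASS,D1,D2",
                           "c1,active,1.5,2.0",
                           "c2,inactive,-0.5,0.25",
                           "c3,active,3.25,-1.0"))
  ds <- load_dataset(path, "CLASS")
  expect_s3_class(ds, "labeled_dataset")
  expect_identical(ds$labels, c(1L, 2L, 1L))
  expect_identical(rownames(ds$x), c("c1", "c2", "c3"))
  expect_identical(colnames(ds$x), c("D1", "D2"))
  expect_equal(ds$x[, "D1"], c(c1 = 1.5, c2 = -0.5, c3 = 3.25))

  # numeric 1/2 codes are accepted directly
  path2 <- write_tiny_csv(c("Compound,CLASS,D1", "c1,1,0.1", "c2,2,0.2"))
  expect_identical(load_dataset(path2, "CLASS")$labels, c(1L, 2L))
})

test_that("save_dataset -> load_dataset is the identity", {
  ds <- make_tiny_dataset()
  path <- tempfile(fileext = ".csv")
  save_dataset(ds, path)
  back <- load_dataset(path, "CLASS")
  expect_identical(back$labels, ds$labels)
  expect_identical(dimnames(back$x), dimnames(ds$x))
  expect_equal(back$x, ds$x, tolerance = 1e-12)
})

test_that("loading failures raise distinct named errors", {
  base <- c("Compound,CLASS,D1,D2", "c1,active,1.0,2.0", "c2,inactive,3.0,4.0")
  expect_error(load_dataset(write_tiny_csv(base), "NOPE"),
               class = "elm_missing_column_error")
  dup <- c("Compound,CLASS,D1", "c1,active,1.0", "c1,inactive,2.0")
  expect_error(load_dataset(write_tiny_csv(dup), "CLASS"),
               class = "elm_duplicate_id_error")
  tok <- c("Compound,CLASS,D1", "c1,active,1.0", "c2,maybe,2.0")
  expect_error(load_dataset(write_tiny_csv(tok), "CLASS", label_mode = "class"),
               class = "elm_label_error")
  txt <- c("Compound,CLASS,D1", "c1,active,abc", "c2,inactive,2.0")
  expect_error(load_dataset(write_tiny_csv(txt), "CLASS"),
               class = "elm_nonnumeric_error")
})

test_that("non-finite descriptor cells: strict mode names the cell, permissive drops the column", {
  lines <- c("Compound,CLASS,D1,D2", "c1,active,NaN,2.0", "c2,inactive,3.0,4.0",
             "c3,active,1.0,5.0")
  err <- expect_error(load_dataset(write_tiny_csv(lines), "CLASS"),
                      class = "elm_nonfinite_error")
  expect_match(conditionMessage(err), "row 1")
  expect_match(conditionMessage(err), "D1")

  expect_message(
    ds <- load_dataset(write_tiny_csv(lines), "CLASS", na_action = "drop_columns"),
    "D1")
  expect_identical(colnames(ds$x), "D2")
  expect_identical(attr(ds, "dropped_columns"), "D1")
  expect_identical(nrow(ds$x), 3L)  # compounds are never dropped
})

test_that("activity curation removes the open intermediate band and keeps boundaries", {
  x <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("c", 1:4), paste0("D", 1:3)))
  ds <- labeled_dataset(x, rep(NA_integer_, 4), pic50 = c(7.0, 5.5, 4.0, 6.0))
  cur <- curate_by_activity(ds)
  expect_identical(rownames(cur$x), c("c1", "c3", "c4"))
  expect_identical(cur$labels, c(1L, 2L, 1L))  # 6.0 is a kept boundary -> active
  rep <- attr(cur, "curation_report")
  expect_identical(rep$n_removed + nrow(cur$x), 4L)
  expect_identical(c(rep$n_active, rep$n_inactive), c(2L, 1L))

  # boundary at the low end -> inactive
  ds2 <- labeled_dataset(x[1:2, ], c(NA_integer_, NA_integer_), pic50 = c(5.0, 6.0))
  expect_identical(curate_by_activity(ds2)$labels, c(2L, 1L))

  # one class empty after curation
  ds3 <- labeled_dataset(x[1:2, ], c(NA_integer_, NA_integer_), pic50 = c(6.5, 6.5))
  expect_error(curate_by_activity(ds3), class = "elm_empty_class_error")
  # everything intermediate
  ds4 <- labeled_dataset(x[1:2, ], c(NA_integer_, NA_integer_), pic50 = c(5.5, 5.7))
  expect_error(curate_by_activity(ds4), class = "elm_all_removed_error")
})

test_that("standardization is exact, invertible, idempotent and flags constants", {
  x <- cbind(A = c(1, 2, 3), B = c(5, 5, 5), C = c(2, 4, 6))
  rownames(x) <- paste0("c", 1:3)
  std <- standardize_descriptors(x)
  expect_equal(unname(std$values[, "A"]), c(-1, 0, 1))
  expect_identical(std$stats$dropped, "B")
  expect_identical(colnames(std$values), c("A", "C"))

  # round trip and idempotence
  back <- invert_standardization(std$stats, std$values)
  expect_equal(back, x[, c("A", "C")], tolerance = 1e-12)
  again <- standardize_descriptors(std$values)
  expect_equal(again$values, std$values, tolerance = 1e-12)

  expect_error(standardize_descriptors(cbind(A = c(2, 2, 2))),
               class = "elm_constant_matrix_error")

  # stats fitted on training data apply to new data with the training moments
  new <- cbind(A = c(10, 0), C = c(1, 2))
  expect_equal(unname(apply_standardization(std$stats, new)[, "A"]),
               (c(10, 0) - 2) / 1)
})

test_that("model files round-trip exactly and reject corruption", {
  ds <- make_tiny_dataset(n = 30)
  model <- elm_train(ds, c("D1", "D2"),
                     optimizer_config(max_generations = 20, seed = 7))
  path <- tempfile(fileext = ".elm")
  save_elm_model(model, path)
  back <- load_elm_model(path)
  expect_identical(back$weights, model$weights)
  expect_identical(back$initial_weights, model$initial_weights)
  expect_identical(back$threshold, model$threshold)
  expect_identical(back$threshold_mode, model$threshold_mode)
  expect_identical(back$standardization$center, model$standardization$center)
  expect_identical(back$standardization$scale, model$standardization$scale)
  expect_identical(back$seed, model$seed)
  # the reloaded model predicts identically
  expect_identical(predict(back, ds$x), predict(model, ds$x))

  # truncated file -> parse error naming the missing field
  lines <- readLines(path)
  trunc <- tempfile(fileext = ".elm")
  writeLines(lines[1:4], trunc)
  expect_error(load_elm_model(trunc), class = "elm_model_parse_error")

  # version mismatch
  bad <- tempfile(fileext = ".elm")
  writeLines(sub("^format_version: .*", "format_version: 99", lines), bad)
  expect_error(load_elm_model(bad), class = "elm_model_version_error")

  # empty descriptor subset refused at save time
  broken <- model
  broken$descriptor_names <- character(0)
  expect_error(save_elm_model(broken, tempfile()), class = "elm_empty_model_error")
})
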