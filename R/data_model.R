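#' Construct a labeled descriptor dataset
#'
#' A labeled dataset couples a compounds-by-descriptors matrix of real-valued
#' molecular descriptors with per-compound activity class codes (1 = active,
#' 2 = inactive) and, optionally, pIC50 potencies (-log10 of the IC50 in M).
#' Datasets that still carry uncurated pIC50 values may hold `NA` labels for
#' compounds of intermediate activity; such datasets must pass through
#' [curate_by_activity()] before any training operation.
#'
#' @param x numeric matrix, compounds in rows and descriptors in columns;
#'   row names are compound IDs and column names descriptor names (both
#'   unique). All entries must be finite.
#' @param labels integer/numeric vector of class codes in `{1, 2}`, one per
#'   compound. `NA` is allowed only when `pic50` is supplied.
#' @param pic50 optional numeric vector of pIC50 values, one per compound.
#' @return An object of class `labeled_dataset`: a list with elements `x`,
#'   `labels` and `pic50`.
#' @seealso [load_dataset()], [curate_by_activity()]
#' @export
labeled_dataset <- function(x, labels, pic50 = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  elm_assert(!is.null(rownames(x)) && !anyDuplicated(rownames(x)),
             "elm_duplicate_id_error", "compound IDs (row names) must be present and unique")
  elm_assert(!is.null(colnames(x)) && !anyDuplicated(colnames(x)),
             "elm_descriptor_name_error", "descriptor names (column names) must be present and unique")
  elm_assert(all(is.finite(x)), "elm_nonfinite_error",
             "descriptor matrix contains non-finite values")
  labels <- as.integer(labels)
  elm_assert(length(labels) == nrow(x), "elm_label_error",
             "need exactly one label per compound")
  elm_assert(all(labels %in% c(1L, 2L) | is.na(labels)), "elm_label_error",
             "labels must be 1 (active) or 2 (inactive)")
  if (anyNA(labels)) {
    elm_assert(!is.null(pic50), "elm_label_error",
               "NA labels are only allowed for uncurated pIC50 datasets")
  }
  if (!is.null(pic50)) {
    pic50 <- as.double(pic50)
    elm_assert(length(pic50) == nrow(x) && all(is.finite(pic50)),
               "elm_pic50_error", "pIC50 must be finite with one value per compound")
  }
  structure(list(x = x, labels = labels, pic50 = pic50), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d compounds x %d descriptors\n", nrow(x$x), ncol(x$x)))
  tab <- table(factor(x$labels, levels = c(1, 2), labels = c("active", "inactive")),
               useNA = "ifany")
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$pic50)) cat(sprintf("  pIC50 range: [%.3g, %.3g]\n",
                                     min(x$pic50), max(x$pic50)))
  invisible(x)
}

# guard used by every training operation
assert_trainable <- function(dataset) {
  elm_assert(!anyNA(dataset$labels), "elm_label_error",
             "dataset has NA labels; run curate_by_activity() first")
  elm_assert(all(c(1L, 2L) %in% dataset$labels), "elm_empty_class_error",
             "both classes (1 = active, 2 = inactive) must be present for training")
  invisible(dataset)
}

#' Activity curation rule
#'
#' Compounds with pIC50 strictly inside `(low, high)` are of intermediate
#' activity and are removed; pIC50 >= `high` is active, <= `low` inactive.
#' Boundary values are kept (a documented choice: the removal interval is
#' open, so boundary compounds are assigned to a class deterministically).
#'
#' @param low lower pIC50 bound (default 5).
#' @param high upper pIC50 bound (default 6); must exceed `low`.
#' @return An object of class `curation_rule`.
#' @export
curation_rule <- function(low = 5, high = 6) {
  elm_assert(is.numeric(low) && is.numeric(high) && low < high,
             "elm_config_error", "curation rule requires low < high")
  structure(list(low = as.double(low), high = as.double(high)), class = "curation_rule")
}

#' Remove intermediate-activity compounds and assign class labels
#'
#' Applies the standard QSAR curation step: compounds of intermediate potency
#' (pIC50 strictly between `rule$low` and `rule$high`) are discarded, the
#' remainder are labeled active (1) when pIC50 >= `rule$high` and inactive (2)
#' when pIC50 <= `rule$low`.
#'
#' @param dataset a [labeled_dataset()] in which every compound has a pIC50.
#' @param rule a [curation_rule()].
#' @return A curated `labeled_dataset` with a `curation_report` attribute
#'   (counts of removed / active / inactive compounds).
#' @export
curate_by_activity <- function(dataset, rule = curation_rule()) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(rule, "curation_rule"))
  elm_assert(!is.null(dataset$pic50), "elm_pic50_error",
             "curation requires pIC50 values for every compound")
  p <- dataset$pic50
  keep <- !(p > rule$low & p < rule$high)
  elm_assert(any(keep), "elm_all_removed_error",
             "curation removed every compound")
  labels <- ifelse(p[keep] >= rule$high, 1L, 2L)
  elm_assert(any(labels == 1L), "elm_empty_class_error",
             "active class empty after curation")
  elm_assert(any(labels == 2L), "elm_empty_class_error",
             "inactive class empty after curation")
  out <- labeled_dataset(dataset$x[keep, , drop = FALSE], labels, p[keep])
  attr(out, "curation_report") <- list(
    n_input = length(p), n_removed = sum(!keep),
    n_active = sum(labels == 1L), n_inactive = sum(labels == 2L),
    rule = unclass(rule))
  out
}

#' Load a descriptor table from delimited text
#'
#' Reads a CSV descriptor table (UTF-8, comma separator, `.` decimal, header
#' row mandatory) into a [labeled_dataset()]. The label column may hold 1/2
#' class codes, the strings `"active"`/`"inactive"`, or pIC50 values
#' (`label_mode = "pic50"`); with pIC50 values all labels are `NA` until
#' [curate_by_activity()] is applied.
#'
#' @param path path to the CSV file.
#' @param label_column name of the label (or pIC50) column.
#' @param id_column name of the compound-ID column; defaults to the first
#'   column of the file.
#' @param label_mode `"auto"` (detect), `"class"` (1/2 or active/inactive), or
#'   `"pic50"` (numeric potencies).
#' @param na_action `"error"` (strict: any non-finite descriptor cell is an
#'   error naming row and column) or `"drop_columns"` (permissive: descriptor
#'   columns containing non-finite cells are dropped and reported; compounds
#'   are never dropped).
#' @return A `labeled_dataset`; in permissive mode the names of dropped
#'   columns are attached as attribute `dropped_columns`.
#' @export
load_dataset <- function(path, label_column, id_column = NULL,
                         label_mode = c("auto", "class", "pic50"),
                         na_action = c("error", "drop_columns")) {
  label_mode <- match.arg(label_mode)
  na_action <- match.arg(na_action)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (is.null(id_column)) id_column <- names(df)[1]
  for (col in c(id_column, label_column)) {
    elm_assert(col %in% names(df), "elm_missing_column_error",
               sprintf("column '%s' not found in %s", col, path))
  }
  ids <- as.character(df[[id_column]])
  elm_assert(!anyDuplicated(ids), "elm_duplicate_id_error",
             sprintf("duplicate compound IDs in column '%s'", id_column))
  raw_labels <- df[[label_column]]
  desc <- df[setdiff(names(df), c(id_column, label_column))]

  # descriptor cells must be numeric and finite
  bad_cols <- character(0)
  for (nm in names(desc)) {
    v <- desc[[nm]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !all(is.na(v) == is.na(vn))) {
        if (na_action == "error") {
          row <- which(is.na(vn) & !is.na(v))[1]
          elm_abort("elm_nonnumeric_error",
                    sprintf("non-numeric descriptor cell at row %d, column '%s'", row, nm))
        }
        bad_cols <- c(bad_cols, nm)
        next
      }
      v <- vn
      desc[[nm]] <- v
    }
    if (!all(is.finite(v))) {
      if (na_action == "error") {
        row <- which(!is.finite(v))[1]
        elm_abort("elm_nonfinite_error",
                  sprintf("missing/non-finite descriptor cell at row %d, column '%s'", row, nm))
      }
      bad_cols <- c(bad_cols, nm)
    }
  }
  if (length(bad_cols)) {
    message("load_dataset: dropping ", length(bad_cols), " descriptor column(s): ",
            paste(bad_cols, collapse = ", "))
    desc <- desc[setdiff(names(desc), bad_cols)]
  }
  x <- as.matrix(desc)
  rownames(x) <- ids

  pic50 <- NULL
  if (label_mode == "auto") {
    label_mode <- if (is.character(raw_labels)) "class"
                  else if (all(raw_labels %in% c(1, 2))) "class" else "pic50"
  }
  if (label_mode == "class") {
    if (is.character(raw_labels)) {
      tok <- tolower(trimws(raw_labels))
      elm_assert(all(tok %in% c("active", "inactive", "1", "2")), "elm_label_error",
                 sprintf("unknown label token(s): %s",
                         paste(unique(tok[!tok %in% c("active", "inactive", "1", "2")]),
                               collapse = ", ")))
      labels <- ifelse(tok %in% c("active", "1"), 1L, 2L)
    } else {
      elm_assert(all(raw_labels %in% c(1, 2)), "elm_label_error",
                 "numeric class labels must be 1 or 2")
      labels <- as.integer(raw_labels)
    }
  } else {
    elm_assert(is.numeric(raw_labels) && all(is.finite(raw_labels)),
               "elm_pic50_error", "pIC50 column must be finite numeric")
    pic50 <- as.double(raw_labels)
    labels <- rep(NA_integer_, length(pic50))
  }
  out <- labeled_dataset(x, labels, pic50)
  if (length(bad_cols)) attr(out, "dropped_columns") <- bad_cols
  out
}

#' Write a labeled dataset to CSV
#'
#' Inverse of [load_dataset()]: one row per compound with the ID column first,
#' the label (or pIC50) column second, then the descriptors.
#'
#' @param dataset a [labeled_dataset()].
#' @param path output file path.
#' @param label_column,id_column column names to write.
#' @param write_pic50 write the pIC50 column instead of class codes.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path, label_column = "CLASS", id_column = "Compound",
                         write_pic50 = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  lab <- if (write_pic50) {
    elm_assert(!is.null(dataset$pic50), "elm_pic50_error", "dataset has no pIC50 values")
    dataset$pic50
  } else dataset$labels
  df <- data.frame(id = rownames(dataset$x), lab = lab,
                   dataset$x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1:2] <- c(id_column, label_column)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Z-score standardization of a descriptor matrix
#'
#' Centers each descriptor to mean 0 and scales to sample standard deviation
#' 1. Zero-variance descriptors are excluded (their least-squares slope is
#' undefined) and reported in the returned statistics. The statistics can be
#' re-applied to new data with [apply_standardization()] and inverted with
#' [invert_standardization()].
#'
#' @param x numeric matrix (compounds x descriptors) with at least 2 rows.
#' @return A list with `values` (the standardized matrix, zero-variance
#'   columns removed) and `stats`, an object of class `standardization`
#'   holding `center`, `scale` and `dropped`.
#' @export
standardize_descriptors <- function(x) {
  x <- as.matrix(x)
  elm_assert(nrow(x) >= 2, "elm_config_error", "standardization needs n >= 2")
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  elm_assert(length(dropped) < ncol(x), "elm_constant_matrix_error",
             "all descriptor columns are constant")
  keep <- sds > 0
  stats <- structure(list(center = ctr[keep], scale = sds[keep], dropped = dropped),
                     class = "standardization")
  list(values = apply_standardization(stats, x), stats = stats)
}

#' @rdname standardize_descriptors
#' @param stats a `standardization` object.
#' @export
apply_standardization <- function(stats, x) {
  stopifnot(inherits(stats, "standardization"))
  x <- as.matrix(x)
  nm <- names(stats$center)
  elm_assert(all(nm %in% colnames(x)), "elm_missing_column_error",
             sprintf("matrix lacks descriptor column(s): %s",
                     paste(setdiff(nm, colnames(x)), collapse = ", ")))
  xs <- x[, nm, drop = FALSE]
  sweep(sweep(xs, 2, stats$center, "-"), 2, stats$scale, "/")
}

#' @rdname standardize_descriptors
#' @export
invert_standardization <- function(stats, x) {
  stopifnot(inherits(stats, "standardization"))
  x <- as.matrix(x)
  sweep(sweep(x, 2, stats$scale, "*"), 2, stats$center, "+")
}

# ---- model file I/O ----------------------------------------------------

MODEL_FORMAT_VERSION <- 1L

#' Save and load an ELM model as flat key-value text
#'
#' The model file is a versioned, line-oriented `key: value` text format.
#' Numeric fields are written with 17 significant digits so a save/load
#' round-trip reproduces the model exactly.
#'
#' @param model an `elm_model` (see [elm_train()]).
#' @param path file path.
#' @return `save_elm_model` returns `path` invisibly; `load_elm_model`
#'   returns the reconstructed `elm_model`.
#' @export
save_elm_model <- function(model, path) {
  stopifnot(inherits(model, "elm_model"))
  elm_assert(length(model$descriptor_names) >= 1, "elm_empty_model_error",
             "refusing to save a model with an empty descriptor subset")
  num_vec <- function(v) paste(vapply(v, fmt_num, ""), collapse = ",")
  st <- model$standardization
  lines <- c(
    sprintf("format_version: %d", MODEL_FORMAT_VERSION),
    "model: elm",
    "class_encoding: 1=active,2=inactive",
    sprintf("descriptor_names: %s", paste(model$descriptor_names, collapse = ",")),
    sprintf("weights: %s", num_vec(model$weights)),
    sprintf("initial_weights: %s", num_vec(model$initial_weights)),
    sprintf("threshold: %s", fmt_num(model$threshold)),
    sprintf("threshold_mode: %s", model$threshold_mode),
    sprintf("standardized: %s", if (is.null(st)) "no" else "yes"),
    sprintf("fitness_kind: %s", model$fitness_kind),
    sprintf("andrews_a: %s", fmt_num(model$andrews_a)),
    sprintf("seed: %d", as.integer(model$seed))
  )
  if (!is.null(st)) {
    lines <- c(lines,
               sprintf("center: %s", num_vec(st$center)),
               sprintf("scale: %s", num_vec(st$scale)),
               sprintf("dropped: %s", paste(st$dropped, collapse = ",")))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_elm_model
#' @export
load_elm_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  ok <- lengths(kv) == 2
  elm_assert(length(lines) > 0 && all(ok | !nzchar(lines)), "elm_model_parse_error",
             sprintf("malformed model file: %s", path))
  kv <- kv[ok]
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  need <- function(key) {
    elm_assert(key %in% names(vals), "elm_model_parse_error",
               sprintf("model file is missing field '%s' (truncated?)", key))
    vals[[key]]
  }
  ver <- suppressWarnings(as.integer(need("format_version")))
  elm_assert(isTRUE(ver == MODEL_FORMAT_VERSION), "elm_model_version_error",
             sprintf("unsupported model format version '%s'", vals[["format_version"]]))
  num_vec <- function(s) as.double(strsplit(s, ",", fixed = TRUE)[[1]])
  nm <- strsplit(need("descriptor_names"), ",", fixed = TRUE)[[1]]
  w <- num_vec(need("weights"))
  w0 <- num_vec(need("initial_weights"))
  thr <- as.double(need("threshold"))
  elm_assert(length(w) == length(nm) && all(is.finite(w)) && is.finite(thr),
             "elm_model_parse_error", "model file has inconsistent weights/threshold")
  st <- NULL
  if (identical(need("standardized"), "yes")) {
    st <- structure(list(
      center = stats::setNames(num_vec(need("center")), nm),
      scale = stats::setNames(num_vec(need("scale")), nm),
      dropped = {
        d <- vals[["dropped"]]
        if (is.null(d) || !nzchar(d)) character(0) else strsplit(d, ",", fixed = TRUE)[[1]]
      }), class = "standardization")
  }
  new_elm_model(descriptor_names = nm, weights = w, initial_weights = w0,
                threshold = thr, threshold_mode = need("threshold_mode"),
                standardization = st, fitness_kind = need("fitness_kind"),
                andrews_a = as.double(need("andrews_a")),
                seed = as.integer(need("seed")))
}
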