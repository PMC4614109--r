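#' Full-run configuration
#'
#' Bundles every stage configuration plus one master seed from which all
#' stage seeds are derived (stage k gets `(master_seed * 16 + k) mod
#' (2^31 - 1)`; simulate = 1, selection = 2, training = 3, CV = 4). A given
#' configuration therefore maps inputs to results as a pure function.
#'
#' @param input path to a CSV descriptor table, or `NULL` to generate
#'   synthetic data from `synthetic`.
#' @param label_column,id_column,label_mode passed to [load_dataset()] when
#'   `input` is a path.
#' @param synthetic a [synthetic_config()] used when `input` is `NULL`; its
#'   seed is overridden by the derived stage seed.
#' @param curation a [curation_rule()] applied when the data carry pIC50
#'   values, or `NULL` to skip curation.
#' @param selection a [selection_config()] (seed overridden).
#' @param optimizer an [optimizer_config()] (seed overridden).
#' @param k,repeats cross-validation folds and number of repeated
#'   experiments.
#' @param nested re-run descriptor selection inside each CV training fold.
#' @param threshold_mode see [compute_threshold()].
#' @param master_seed single reproducibility knob for the whole run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, label_column = "CLASS", id_column = NULL,
                       label_mode = "auto", synthetic = synthetic_config(),
                       curation = curation_rule(), selection = selection_config(),
                       optimizer = optimizer_config(), k = 10, repeats = 1,
                       nested = FALSE, threshold_mode = "midpoint",
                       master_seed = 1) {
  structure(list(input = input, label_column = label_column,
                 id_column = id_column, label_mode = label_mode,
                 synthetic = synthetic, curation = curation,
                 selection = selection, optimizer = optimizer,
                 k = as.integer(k), repeats = as.integer(repeats),
                 nested = nested, threshold_mode = threshold_mode,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

config_fingerprint <- function(config) {
  fnv1a32(paste(deparse(unclass(config)), collapse = "\n"))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    elm_abort("elm_pipeline_error",
              sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
              stage = stage, parent = e)
  })
}

#' Run the full ELM workflow and write its artifacts
#'
#' Executes load/simulate -> curate -> select -> train -> predict ->
#' cross-validate and writes five artifacts into `out_dir`:
#' `selection.json` (per-descriptor usage and prefilter p-values),
#' `model.elm` (the trained model, flat text), `predictions.csv`
#' (compound ID, score, predicted and true class), `cv_report.json`
#' (per-run and mean +/- sd metrics) and `run.log`. Every artifact is
#' stamped with the config fingerprint and master seed; re-running the same
#' configuration reproduces byte-identical files (no timestamps are
#' written).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory results: `dataset`,
#'   `selection`, `model`, `experiments`, `fingerprint` and the artifact
#'   `paths`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- config_fingerprint(config)
  log_lines <- c(sprintf("elmqsar pipeline | config %s | master seed %d",
                         fp, config$master_seed))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  truth <- NULL
  ds <- pipeline_stage("input", {
    if (is.null(config$input)) {
      syn_cfg <- config$synthetic
      syn_cfg$seed <- derive_seed(config$master_seed, 1)
      syn <- generate_synthetic(syn_cfg)
      truth <- syn$informative
      note("input: synthetic, n=%d p=%d informative=%d seed=%d",
           syn_cfg$n_compounds, syn_cfg$n_descriptors, syn_cfg$n_informative,
           syn_cfg$seed)
      syn$dataset
    } else {
      note("input: %s", config$input)
      load_dataset(config$input, config$label_column, config$id_column,
                   config$label_mode)
    }
  })
  if (!is.null(ds$pic50) && !is.null(config$curation)) {
    ds <- pipeline_stage("curation", curate_by_activity(ds, config$curation))
    rep <- attr(ds, "curation_report")
    note("curation: removed %d of %d -> %d active / %d inactive",
         rep$n_removed, rep$n_input, rep$n_active, rep$n_inactive)
  }
  pipeline_stage("cv_guard", {
    tab <- table(ds$labels)
    elm_assert(all(tab >= config$k), "elm_fold_error",
               sprintf("smallest class has %d compounds, fewer than k = %d folds",
                       min(tab), config$k))
  })

  sel_cfg <- config$selection
  sel_cfg$seed <- derive_seed(config$master_seed, 2)
  sel <- pipeline_stage("selection", select_descriptors_ga(ds, sel_cfg))
  descriptors <- if (length(sel$selected)) sel$selected else sel$best_subset
  note("selection: %d descriptors selected (cutoff %d), %d generations",
       length(descriptors), sel_cfg$usage_cutoff, sel$generations)

  opt_cfg <- config$optimizer
  opt_cfg$seed <- derive_seed(config$master_seed, 3)
  model <- pipeline_stage("training",
    elm_train(ds, descriptors, config = opt_cfg,
              threshold_mode = config$threshold_mode))
  note("training: RSS %.6g -> %.6g, threshold %.6g",
       model$rss_initial, model$rss_optimized, model$threshold)

  trainer <- elm_trainer(descriptors, optimizer = opt_cfg,
                         nested = config$nested, selection = sel_cfg,
                         threshold_mode = config$threshold_mode)
  exps <- pipeline_stage("cv",
    repeat_experiments(ds, trainer, R = config$repeats, k = config$k,
                       base_seed = derive_seed(config$master_seed, 4)))
  note("cv: mean Acc %.2f%%, mean MCC %.3f over %d run(s)",
       exps$mean[["cv_acc"]], exps$mean[["cv_mcc"]], exps$R)

  paths <- list(selection = file.path(out_dir, "selection.json"),
                model = file.path(out_dir, "model.elm"),
                predictions = file.path(out_dir, "predictions.csv"),
                cv_report = file.path(out_dir, "cv_report.json"),
                log = file.path(out_dir, "run.log"))
  pipeline_stage("report", {
    ord <- order(-sel$usage, names(sel$usage))
    jsonlite::write_json(list(
      config_fingerprint = fp, seed = sel$seed,
      usage_cutoff = sel$usage_cutoff,
      selected = sel$selected,
      descriptors = data.frame(name = names(sel$usage)[ord],
                               usage = unname(sel$usage[ord]),
                               prefilter_pvalue = unname(sel$prefilter_pvalues[ord]))),
      paths$selection, auto_unbox = TRUE, digits = NA, pretty = TRUE)

    save_elm_model(model, paths$model)

    scores <- predict(model, ds$x, type = "score")
    utils::write.csv(data.frame(Compound = rownames(ds$x),
                                score = scores,
                                predicted = ifelse(scores < model$threshold, 1L, 2L),
                                threshold = model$threshold,
                                true_class = ds$labels),
                     paths$predictions, row.names = FALSE, quote = FALSE)

    jsonlite::write_json(list(
      config_fingerprint = fp, master_seed = config$master_seed,
      k = exps$k, repeats = exps$R,
      informative_truth = truth,
      runs = exps$runs, mean = as.list(exps$mean), sd = as.list(exps$sd),
      best_run = exps$best_run),
      paths$cv_report, auto_unbox = TRUE, digits = NA, pretty = TRUE)

    writeLines(log_lines, paths$log, useBytes = TRUE)
  })
  invisible(list(dataset = ds, selection = sel, model = model,
                 experiments = exps, fingerprint = fp, paths = paths))
}
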