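#' Run configuration
#'
#' Assembles and validates the configuration of a full pipeline run. All
#' defaults are the pipeline's canonical settings: 20 rounds x 5 folds,
#' round threshold 15/20, 2 consensus iterations, 60% selection cutoff,
#' prevalence-derived decision threshold.
#'
#' @param cohort Either a list of [cohort_config()] arguments (synthetic
#'   source) or a string path to a cohort CSV written by [write_cohort()].
#' @param n_rounds,n_folds Cross-validation plan.
#' @param n_iterations Consensus iterations.
#' @param round_threshold Misclassified-rounds threshold (NULL = default
#'   rule).
#' @param selection_cutoff Nested selection-frequency cutoff.
#' @param nested_selection Run nested Boruta inside the consensus CV
#'   (default FALSE; the standalone selection stage always runs).
#' @param models Per-family hyperparameter override lists, e.g.
#'   `list(RF = list(n_trees = 100))`.
#' @param explain_method,n_coalitions,bg_k Explainer settings.
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed for every stochastic stage.
#' @return A validated `run_config`.
#' @export
run_config <- function(cohort = list(), n_rounds = 20L, n_folds = 5L,
                       n_iterations = 2L, round_threshold = NULL,
                       selection_cutoff = 0.60, nested_selection = FALSE,
                       models = list(), explain_method = "kernel",
                       n_coalitions = 2048L, bg_k = 50L,
                       out_dir = "idex_run", seed = 1L) {
  if (n_rounds < 1L) stop_idex("n_rounds must be positive")
  if (n_folds < 2L) stop_idex("n_folds must be at least 2")
  if (n_iterations < 0L) stop_idex("n_iterations must be non-negative")
  assert_fraction(selection_cutoff, "selection_cutoff")
  if (!explain_method %in% c("auto", "exact", "kernel"))
    stop_idex("explain_method must be auto/exact/kernel")
  bad <- setdiff(names(models), c("RF", "SVM", "XGB", "NB"))
  if (length(bad))
    stop_idex("unknown model families in config: %s",
              paste(bad, collapse = ", "))
  structure(list(cohort = cohort, n_rounds = as.integer(n_rounds),
                 n_folds = as.integer(n_folds),
                 n_iterations = as.integer(n_iterations),
                 round_threshold = round_threshold,
                 selection_cutoff = selection_cutoff,
                 nested_selection = isTRUE(nested_selection),
                 models = models, explain_method = explain_method,
                 n_coalitions = n_coalitions, bg_k = bg_k,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

config_keys <- c("cohort", "n_rounds", "n_folds", "n_iterations",
                 "round_threshold", "selection_cutoff", "nested_selection",
                 "models", "explain_method", "n_coalitions", "bg_k",
                 "out_dir", "seed")

#' Load and validate a run configuration file
#'
#' Accepts YAML (`.yaml`/`.yml`, requires the yaml package) or JSON. Unknown
#' keys are rejected with the offending name; missing keys get the pipeline
#' defaults. `load -> dump -> load` round-trips to an equal config.
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop_idex("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_idex("the yaml package is needed for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), config_keys)
  if (length(bad))
    stop_idex("unknown config key(s): %s (allowed: %s)",
              paste(bad, collapse = ", "), paste(config_keys,
                                                 collapse = ", "))
  if (!is.null(raw$models)) raw$models <- lapply(raw$models, as.list)
  if (!is.null(raw$cohort) && !is.character(raw$cohort))
    raw$cohort <- as.list(raw$cohort)
  do.call(run_config, raw)
}

#' Dump a run configuration to JSON
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

load_pipeline_cohort <- function(config) {
  if (is.character(config$cohort)) {
    list(cohort = read_cohort(config$cohort), truth = NULL)
  } else {
    args <- config$cohort
    if (is.null(args$seed)) args$seed <- config$seed
    gen <- do.call(cohort_config, args)
    generate_cohort(gen)
  }
}

#' Run the full pipeline
#'
#' Executes generate (or load) -> nested selection -> consensus ->
#' performance -> explanation, writing every stage artifact as CSV/JSON
#' under `config$out_dir` and returning a manifest. Re-running with the
#' same config + seed reproduces the outputs byte for byte.
#'
#' @param config A `run_config`.
#' @param quiet Suppress stage logging.
#' @return A `run_manifest`: list with `outputs` (named file paths),
#'   `config`, `seconds` per stage and headline numbers per stage.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  timing <- numeric()
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop_idex("stage `%s` failed: %s", name, conditionMessage(e)))
    timing[[name]] <<- round(proc.time()[3] - t0, 2)
    res
  }
  emit <- function(key, path) outputs[[key]] <<- path

  say("[idex] seed %d, output -> %s", config$seed, config$out_dir)

  src <- stage("cohort", load_pipeline_cohort(config))
  cohort <- src$cohort
  p <- file.path(config$out_dir, "cohort.csv")
  write_cohort(cohort, p); emit("cohort", p)
  if (!is.null(src$truth)) {
    p <- file.path(config$out_dir, "ground_truth.json")
    write_truth(src$truth, p); emit("ground_truth", p)
  }
  say("[idex] cohort: %d patients, prevalence %.3f",
      length(cohort$patient_ids), mean(cohort$labels))

  em <- stage("encode", impute(encode(cohort)))
  p <- file.path(config$out_dir, "encoded.csv")
  write_encoded(em, p); emit("encoded", p)

  plan <- cv_plan(config$n_rounds, config$n_folds,
                  master_seed = config$seed)
  specs <- do.call(default_model_specs, config$models)

  freq <- stage("selection",
                nested_selection_frequency(em$x, cohort$labels, plan))
  p <- file.path(config$out_dir, "selection_frequency.csv")
  write_selection_frequency(freq, p); emit("selection_frequency", p)
  kept <- select_features(freq, config$selection_cutoff)
  say("[idex] %d features at frequency >= %.2f",
      length(kept), config$selection_cutoff)
  if (length(kept) < 2L) {
    say("[idex] fewer than 2 features selected; keeping all")
    kept <- colnames(em$x)
  }

  consensus <- stage("consensus", iterate_consensus(
    cohort, specs, plan, n_iterations = config$n_iterations,
    round_threshold = config$round_threshold,
    selection = if (config$nested_selection) list() else kept))
  p <- file.path(config$out_dir, "consensus_report.json")
  write_consensus_report(consensus, p)
  emit("consensus_report", p)
  emit("kappa_table", paste0(p, ".kappa.csv"))
  say("[idex] consensus removed %d of %d patients",
      length(consensus$confounding_ids), consensus$n_initial)

  if (!is.null(consensus$final_tensor)) {
    p <- file.path(config$out_dir, "score_tensor.csv")
    write_score_tensor(consensus$final_tensor, p); emit("score_tensor", p)
    perf <- consensus$final_performance
    p <- file.path(config$out_dir, "performance.csv")
    write.csv(perf$summary, p, row.names = FALSE); emit("performance", p)
    inc_lab <- cohort$labels[match(consensus$included_ids,
                                   cohort$patient_ids)]
    pair <- c("RF", "NB")
    if (all(pair %in% consensus$final_tensor$classifiers)) {
      ct <- concordance_table(consensus$final_tensor, inc_lab,
                              consensus$threshold, pair)
      p <- file.path(config$out_dir, "concordance_RF_NB.csv")
      write.csv(as.data.frame(ct$table), p); emit("concordance", p)
    }
  }

  expl <- stage("explain", {
    x <- em$x[, kept, drop = FALSE]
    inc <- match(consensus$included_ids, rownames(x))
    y_inc <- cohort$labels[match(consensus$included_ids,
                                 cohort$patient_ids)]
    best <- specs[["XGB"]] %||% specs[[1]]
    model <- fit_model(best, x[inc, , drop = FALSE], y_inc,
                       seed = config$seed)
    explain_patients(model, x[inc, , drop = FALSE],
                     x[inc, , drop = FALSE],
                     method = config$explain_method, bg_k = config$bg_k,
                     n_coalitions = config$n_coalitions,
                     seed = config$seed)
  })
  x_inc <- em$x[match(consensus$included_ids, rownames(em$x)), kept,
                drop = FALSE]
  p <- file.path(config$out_dir, "explanations.csv")
  write_explanations(expl, p, x_inc); emit("explanations", p)
  gs <- global_summary(expl, x_inc)
  p <- file.path(config$out_dir, "global_importance.csv")
  write.csv(gs$ranking, p, row.names = FALSE); emit("global_importance", p)

  if (length(consensus$confounding_ids) > 0L) {
    conf_expl <- stage("explain_confounders", explain_confounders(
      consensus, cohort, specs[["XGB"]] %||% specs[[1]],
      method = config$explain_method, features = kept,
      bg_k = config$bg_k, n_coalitions = config$n_coalitions,
      seed = config$seed))
    x_conf <- em$x[match(consensus$confounding_ids, rownames(em$x)), kept,
                   drop = FALSE]
    p <- file.path(config$out_dir, "confounder_explanations.csv")
    write_explanations(conf_expl, p, x_conf)
    emit("confounder_explanations", p)
  }

  manifest <- structure(
    list(outputs = outputs, seconds = timing,
         config = unclass(config),
         n_patients = length(cohort$patient_ids),
         n_selected_features = length(kept),
         n_confounders = length(consensus$confounding_ids)),
    class = "run_manifest")
  p <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    list(outputs = as.list(outputs), seconds = as.list(timing),
         config = unclass(config)),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  manifest$outputs[["manifest"]] <- p
  say("[idex] done: %d artifacts", length(manifest$outputs))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d outputs, %d patients, %d confounders\n",
              length(x$outputs), x$n_patients, x$n_confounders))
  for (k in names(x$outputs)) cat(sprintf("  %-24s %s\n", k, x$outputs[[k]]))
  invisible(x)
}
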