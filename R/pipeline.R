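#' Run the full diagnostic-modeling pipeline
#'
#' Orchestrates simulate/ingest -> preprocess -> robust filter -> beam
#' search -> final model selection -> evaluation, writing each stage's
#' artifacts plus a run manifest into `out_dir`. The manifest (config
#' snapshot, input file digests, package version, seed, timestamp) is
#' written before any result so that every artifact is attributable to
#' it; re-running with the same config reproduces identical results.
#'
#' @param config A configuration list, or the path to a YAML file
#'   holding one. Recognized sections: `simulate` (arguments of
#'   [simulation_config()]) or `input` (`expr`/`meta` paths for
#'   [read_expression_table()]); `normalization` and `filter`
#'   (arguments of [normalization_config()] /
#'   [robust_filter_config()]); `search` (`beam_width`,
#'   `max_features`, `epsilon`, `ridge`, `prior`); `validate`
#'   (logical; simulated runs only, scores an independent cohort);
#'   `seed` (overrides `simulate$seed`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `bundle`, `search`, `selected`,
#'   `training_report`, `validation_report` (or `NULL`), and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", stage, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  seed <- config$seed
  sim_args <- config$simulate
  if (!is.null(seed) && !is.null(sim_args)) sim_args$seed <- seed

  inputs <- character(0)
  if (!is.null(config$input)) {
    inputs <- c(expr = config$input$expr, meta = config$input$meta)
  }
  manifest <- list(
    package = "ecindex",
    version = as.character(utils::packageVersion("ecindex")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (!is.null(sim_args)) sim_args$seed else seed,
    config = config,
    input_digests = if (length(inputs) > 0L) {
      as.list(tools::md5sum(inputs))
    } else {
      NULL
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  truth <- NULL
  study <- run_stage("ingest", {
    if (!is.null(sim_args)) {
      sim <- simulate_cohort(do.call(simulation_config, sim_args))
      truth <- sim$truth
      sim$study
    } else if (!is.null(config$input)) {
      read_expression_table(config$input$expr,
                            format = config$input$format %||% "wide_tsv",
                            meta = config$input$meta)
    } else {
      stop("config needs a 'simulate' or 'input' section")
    }
  })

  norm_cfg <- do.call(normalization_config,
                      config$normalization %||% list())
  filter_cfg <- do.call(robust_filter_config, config$filter %||% list())
  bundle <- run_stage("preprocess",
                      preprocess_study(study, norm_cfg, filter_cfg))
  writeLines(bundle$selected_mirnas,
             file.path(out_dir, "robust_mirnas.txt"))

  sc <- config$search %||% list()
  search_cfg <- search_config(beam_width = sc$beam_width %||% 20,
                              max_features = sc$max_features %||% 8)
  lda_cfg <- lda_config(prior = sc$prior %||% "equal",
                        ridge = sc$ridge %||% 1e-8)
  epsilon <- sc$epsilon %||% 0.005

  result <- run_stage("search", {
    X <- feature_matrix(bundle, pseudo_floor = norm_cfg$pseudo_floor)
    beam_search(X, bundle$samples$group, cfg = search_cfg,
                lda_cfg = lda_cfg)
  })
  tab <- run_stage("report", report_table(result))
  utils::write.table(tab, file.path(out_dir, "search_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  selected <- run_stage("select", select_final_model(result, epsilon))
  result$selected <- selected
  write_model(selected$model, file.path(out_dir, "selected_model.json"))

  training_report <- run_stage("evaluate", {
    cv <- loocv_accuracy(result$X, result$y, selected$features, lda_cfg)
    evaluate_scores(cv$scores, result$y, meta = bundle$samples)
  })
  jsonlite::write_json(
    list(n_case = training_report$n_case,
         n_control = training_report$n_control,
         metrics = training_report$metrics,
         auc = training_report$auc,
         per_stratum = training_report$per_stratum),
    file.path(out_dir, "training_evaluation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  validation_report <- NULL
  if (isTRUE(config$validate) && !is.null(sim_args)) {
    validation_report <- run_stage("validate", {
      val_args <- sim_args
      val_args$seed <- (sim_args$seed %||% 1L) + 100003L
      val <- simulate_cohort(do.call(simulation_config, val_args))
      val_norm <- norm_cfg
      # freeze the training reference so single new arrays score
      # identically regardless of cohort composition
      val_norm$reference_level <- "fixed_value"
      val_norm$fixed_reference <- attr(bundle, "reference")
      normed <- normalize_internal_controls(
        positive_call_subtract(val$study,
                               pseudo_floor = norm_cfg$pseudo_floor),
        val_norm)
      Xv <- feature_matrix(normed, selected$model$mirna_ids,
                           pseudo_floor = norm_cfg$pseudo_floor)
      scores <- score_samples(selected$model, Xv)
      evaluate_scores(scores, val$study$samples$group,
                      meta = val$study$samples)
    })
    jsonlite::write_json(
      list(n_case = validation_report$n_case,
           n_control = validation_report$n_control,
           metrics = validation_report$metrics,
           auc = validation_report$auc,
           per_stratum = validation_report$per_stratum),
      file.path(out_dir, "validation_evaluation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(bundle = bundle, search = result, selected = selected,
                 truth = truth,
                 training_report = training_report,
                 validation_report = validation_report,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
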