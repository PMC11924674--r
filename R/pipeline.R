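#' Pipeline configuration
#'
#' Bundles every stage's configuration so that a run is a pure function of
#' (config, seeds): generator settings, preprocessing parameters, the quality
#' threshold, the model seed and the task list.
#'
#' @param generator A [generator_config()].
#' @param preprocess A [preprocess_params()].
#' @param qf_threshold Quality-factor cutoff (default 0.3).
#' @param model_seed Seed for splits/folds (defaults to the generator seed).
#' @param tasks Subset of `c("similarity", "model_I", "model_II", "transfer")`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            preprocess = preprocess_params(),
                            qf_threshold = 0.3, model_seed = NULL,
                            tasks = c("similarity", "model_I", "model_II",
                                      "transfer")) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(preprocess, "preprocess_params"))
  bad <- setdiff(tasks, c("similarity", "model_I", "model_II", "transfer"))
  if (length(bad)) abort_config(sprintf("unknown task(s): %s",
                                        paste(bad, collapse = ", ")))
  if (is.null(model_seed)) model_seed <- generator$seed
  structure(list(generator = generator, preprocess = preprocess,
                 qf_threshold = qf_threshold,
                 model_seed = as.integer(model_seed), tasks = tasks),
            class = "pipeline_config")
}

write_csv_det <- function(df, path) {
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> quality gate -> similarity analyses -> binary
#' model suite -> four-class model -> preparation-method transfer, writing
#' every artifact (processed dataset, QC report, SAM matrix, variance tables,
#' confusion matrices, summary) under `out_dir` together with a manifest
#' recording the config hash and seed. Two runs of the same config produce
#' identical summaries. If the quality gate eliminates every record, the run
#' halts gracefully before training with a warning and a summary noting the
#' empty gate.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param profiles Tissue profile map for the generator.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the run artifacts (`dataset`, `qc`,
#'   `similarity`, `model_I`, `model_II`, `transfer`, `summary`, `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         profiles = default_profiles(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort_io(sprintf("cannot create output directory '%s'", out_dir))
  say <- function(stage, t0) if (!quiet)
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(Sys.time()) - t0))

  cfg_json <- jsonlite::toJSON(list(
    generator = unclass(config$generator),
    preprocess = unclass(config$preprocess),
    qf_threshold = config$qf_threshold,
    model_seed = config$model_seed, tasks = config$tasks),
    auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)

  t0 <- as.numeric(Sys.time())
  raw <- generate_raw(config$generator, profiles)
  say("simulate", t0)

  t0 <- as.numeric(Sys.time())
  calib <- default_calibration(config$generator$n_pixels,
                               config$generator$shift_range)
  processed <- preprocess_dataset(raw, calib, config$preprocess)
  say("preprocess", t0)

  t0 <- as.numeric(Sys.time())
  gated <- gate_quality(processed, config$qf_threshold)
  writeLines(jsonlite::toJSON(list(
    threshold = gated$report$threshold,
    n_kept = length(gated$report$kept),
    n_eliminated = length(gated$report$eliminated),
    eliminated = gated$report$eliminated,
    class_balance = gated$report$class_balance),
    auto_unbox = TRUE, digits = I(17), pretty = TRUE),
    file.path(out_dir, "qc_report.json"))
  say("quality gate", t0)

  summary <- list(seed = config$generator$seed,
                  n_records = n_records(processed),
                  n_kept = length(gated$report$kept))
  result <- list(dataset = gated$dataset, qc = gated$report, out_dir = out_dir)

  if (!length(gated$report$kept)) {
    summary$halted <- "quality gate eliminated every record"
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(out_dir, "summary.json"))
    write_manifest(out_dir, cfg_path, config)
    warning("pipeline halted: quality gate eliminated every record", call. = FALSE)
    result$summary <- summary
    return(invisible(result))
  }

  write_dataset(gated$dataset, file.path(out_dir, "processed"))
  ds <- gated$dataset

  if ("similarity" %in% config$tasks) {
    t0 <- as.numeric(Sys.time())
    sm <- pairwise_sam(ds)
    write_csv_det(as.data.frame(round(sm$angles, 6)),
                  file.path(out_dir, "sam_matrix.csv"))
    if (sum(ds$meta$tissue == "pituitary_gland" &
            ds$meta$prep_method != "in_situ") > 0) {
      pc <- prep_method_comparison(ds)
      write_csv_det(pc$variance, file.path(out_dir, "prep_variance.csv"))
      write_csv_det(pc$sam, file.path(out_dir, "prep_sam.csv"))
      result$prep_comparison <- pc
      pooled <- pc$variance[pc$variance$head == "pooled", ]
      summary$prep_variance <- stats::setNames(as.list(pooled$total_variance),
                                               pooled$method)
    }
    result$similarity <- sm
    summary$mean_offdiag_sam_deg <- sm$mean_offdiag
    say("similarity", t0)
  }

  if ("model_I" %in% config$tasks) {
    t0 <- as.numeric(Sys.time())
    suite <- run_model_I(ds, seed = config$model_seed)
    tab <- do.call(rbind, lapply(names(suite), function(nm) data.frame(
      task = nm, n_features = length(suite[[nm]]$selected_bins),
      validation_accuracy = suite[[nm]]$cv$accuracy,
      test_accuracy = suite[[nm]]$test$accuracy,
      test_auc = if (!is.null(suite[[nm]]$test$auc)) suite[[nm]]$test$auc else NA,
      stringsAsFactors = FALSE)))
    write_csv_det(tab, file.path(out_dir, "model_I_summary.csv"))
    result$model_I <- suite
    summary$model_I <- stats::setNames(as.list(tab$test_accuracy), tab$task)
    say("model I", t0)
  }

  if ("model_II" %in% config$tasks) {
    t0 <- as.numeric(Sys.time())
    m2 <- run_model_II(ds, seed = config$model_seed)
    utils::write.csv(as.data.frame(m2$cv$confusion),
                     file.path(out_dir, "model_II_validation_confusion.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(m2$test$confusion),
                     file.path(out_dir, "model_II_test_confusion.csv"),
                     row.names = FALSE)
    result$model_II <- m2
    summary$model_II <- list(validation_accuracy = m2$cv$accuracy,
                             test_accuracy = m2$test$accuracy,
                             n_features = length(m2$selected_bins))
    say("model II", t0)

    if ("transfer" %in% config$tasks &&
        any(ds$meta$prep_method != "in_situ")) {
      tr <- transfer_to_methods(m2, ds)
      summary$transfer_gland_recall <- as.list(tr$gland_recall)
      result$transfer <- tr
      counts <- do.call(rbind, lapply(names(tr$counts), function(m)
        data.frame(method = m, class = names(tr$counts[[m]]),
                   n = as.integer(tr$counts[[m]]), stringsAsFactors = FALSE)))
      write_csv_det(counts, file.path(out_dir, "transfer_counts.csv"))
    }
  }

  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "summary.json"))
  write_manifest(out_dir, cfg_path, config)
  result$summary <- summary
  invisible(result)
}

write_manifest <- function(out_dir, cfg_path, config) {
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  writeLines(jsonlite::toJSON(list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$generator$seed,
    files = sort(files)), auto_unbox = TRUE, pretty = TRUE),
    file.path(out_dir, "manifest.json"))
}
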