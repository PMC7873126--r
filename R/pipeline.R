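#' Configuration of the full cleaning pipeline
#'
#' Stage toggles and parameter blocks for [run_pipeline()]. Stages always
#' execute in the fixed order: retention-time ROI filter, noise imputation,
#' QC-anchored batch correction, removal of the QC injections, blank-based
#' feature filter, fingerprint construction, sample validity check.
#'
#' @param roi_filter,impute,batch_correct,blank_filter,fingerprints,validate
#'   logical stage toggles.
#' @param rt_min,rt_max ROI bounds in seconds.
#' @param imputation an [imputation_params()].
#' @param k number of correction components; `NULL` selects it by
#'   [scree_select_k()] with `k_max` and `scree_tol`.
#' @param k_max,scree_tol scree-selection controls.
#' @param min_blank_detections blank-filter threshold.
#' @param min_fraction,min_count fingerprint detection rule.
#' @param validity a [validity_params()].
#' @param output_variants subset of `c("imputed", "zeros", "NA")`: matrix
#'   variants to emit at the end. The zero/NA variants restore empty markers
#'   at the imputed-cell positions, discarding corrected noise there.
#' @param seed seed forwarded to the imputation stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(roi_filter = TRUE, rt_min = 80, rt_max = 840,
                            impute = TRUE,
                            imputation = imputation_params(),
                            batch_correct = TRUE, k = NULL, k_max = 10L,
                            scree_tol = 0.01,
                            blank_filter = TRUE, min_blank_detections = 1L,
                            fingerprints = TRUE, min_fraction = 0.25,
                            min_count = 8L,
                            validate = TRUE, validity = validity_params(),
                            output_variants = c("imputed", "zeros", "NA"),
                            seed = 1L) {
  output_variants <- match.arg(output_variants, several.ok = TRUE)
  structure(list(roi_filter = roi_filter, rt_min = rt_min, rt_max = rt_max,
                 impute = impute, imputation = imputation,
                 batch_correct = batch_correct, k = k, k_max = as.integer(k_max),
                 scree_tol = scree_tol,
                 blank_filter = blank_filter,
                 min_blank_detections = as.integer(min_blank_detections),
                 fingerprints = fingerprints, min_fraction = min_fraction,
                 min_count = as.integer(min_count),
                 validate = validate, validity = validity,
                 output_variants = output_variants, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full feature-table cleaning pipeline
#'
#' Executes the configured stages in fixed order on a feature table, keeping
#' the per-stage tables, diagnostic reports and a machine-readable log of
#' sample/feature counts. If `out_dir` is given, every stage's table is
#' written as a stage-suffixed W4M triplet, the log as TSV, and the final
#' matrix in each requested variant. A stage failure aborts with the stage
#' name after flushing the partial log.
#'
#' @param x input `feature_table` (or a named list with the three triplet
#'   paths, forwarded to [read_w4m()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return object of class `pipeline_run`: `tables` (per stage), `final`,
#'   `variants`, `log` (data.frame stage/n_features/n_samples), and reports
#'   (`scree`, `model`, `batch_distances`, `removed_features`,
#'   `fingerprints`, `validity`).
#' @export
run_pipeline <- function(x, config = pipeline_config(), out_dir = NULL) {
  if (is.list(x) && !inherits(x, "feature_table") &&
      all(c("dataMatrix", "sampleMetadata", "variableMetadata") %in% names(x)))
    x <- read_w4m(x$dataMatrix, x$sampleMetadata, x$variableMetadata)
  stopifnot(inherits(x, "feature_table"), inherits(config, "pipeline_config"))

  run <- list(tables = list(), log = NULL, config = config)
  logrow <- function(stage, tab) {
    rbind(run$log, data.frame(stage = stage, n_features = nrow(tab$matrix),
                              n_samples = ncol(tab$matrix),
                              stringsAsFactors = FALSE))
  }
  flush <- function() {
    if (!is.null(out_dir) && !is.null(run$log)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      utils::write.table(run$log, file.path(out_dir, "pipeline_log.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  stage <- function(name, enabled, fun) {
    if (!enabled) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) {
      flush()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  current <- x
  run$log <- logrow("input", current)
  run$tables$input <- current

  if (config$roi_filter) {
    current <- stage("roi_filter", TRUE, function()
      roi_filter(current, config$rt_min, config$rt_max))
    run$tables$roi <- current
    run$log <- logrow("roi_filter", current)
  }

  if (config$impute) {
    ip <- config$imputation
    ip$seed <- config$seed
    current <- stage("impute", TRUE, function() impute_noise(current, ip))
    run$tables$imputed <- current
    run$log <- logrow("impute", current)
  }

  if (config$batch_correct) {
    current <- stage("batch_correct", TRUE, function() {
      k <- config$k
      if (is.null(k)) {
        run$scree <<- scree_select_k(current, k_max = config$k_max,
                                     tol = config$scree_tol)
        k <- run$scree$chosen_k
      }
      run$model <<- fit_batch_correction(current, k = k)
      pre <- batch_distances(current, roles = "qc_pool")
      corrected <- predict(run$model, current)
      post <- batch_distances(corrected, roles = "qc_pool")
      run$batch_distances <<- data.frame(
        group = "qc_pool", stage = c("pre", "post"),
        inter_batch_distance = c(pre$inter_batch_distance,
                                 post$inter_batch_distance))
      corrected
    })
    run$tables$batch_corrected <- current
    run$log <- logrow("batch_correct", current)
    ## QC injections have served their purpose; drop them
    keep <- setdiff(colnames(current$matrix),
                    samples_by_role(current, c("qc_pool", "solvent")))
    current <- ft_subset(current, samples = keep)
    run$tables$qc_dropped <- current
    run$log <- logrow("drop_qc", current)
  }

  if (config$blank_filter) {
    bf <- stage("blank_filter", TRUE, function()
      blank_filter(current, config$min_blank_detections))
    current <- bf$table
    run$removed_features <- bf$removed
    run$tables$blank_filtered <- current
    run$log <- logrow("blank_filter", current)
  }

  if (config$fingerprints) {
    run$fingerprints <- stage("fingerprints", TRUE, function()
      build_fingerprints(current, config$min_fraction, config$min_count))
    run$log <- logrow("fingerprints", current)
  }

  if (config$validate) {
    if (is.null(run$fingerprints))
      run$fingerprints <- build_fingerprints(current, config$min_fraction,
                                             config$min_count)
    vr <- stage("validate_samples", TRUE, function()
      validate_samples(current, run$fingerprints, config$validity))
    run$validity <- vr
    current <- vr$table
    run$tables$validated <- current
    run$log <- logrow("validate_samples", current)
  }

  run$final <- current
  run$variants <- list()
  for (v in config$output_variants) {
    run$variants[[v]] <-
      if (v != "imputed" && current$missing_convention == "imputed")
        restore_missing(current,
                        convention = if (v == "zeros") "zero" else "NA")
      else current
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    i <- 0L
    for (nm in names(run$tables)) {
      i <- i + 1L
      write_w4m(run$tables[[nm]], out_dir, prefix = sprintf("%02d_%s_", i, nm))
    }
    for (v in names(run$variants))
      write_w4m(run$variants[[v]], out_dir, prefix = sprintf("final_%s_", v))
    flush()
  }
  class(run) <- "pipeline_run"
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run:\n")
  print(x$log, row.names = FALSE)
  if (!is.null(x$model))
    cat(sprintf("  batch correction with k = %d component(s)\n", x$model$k))
  if (!is.null(x$batch_distances)) {
    d <- x$batch_distances
    cat(sprintf("  QC inter-batch distance: %.3f -> %.3f\n",
                d$inter_batch_distance[d$stage == "pre"],
                d$inter_batch_distance[d$stage == "post"]))
  }
  if (!is.null(x$validity))
    cat(sprintf("  validity: %d of %d samples failed\n",
                sum(x$validity$report$decision != "pass"),
                nrow(x$validity$report)))
  invisible(x)
}
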