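#' End-to-end calibration pipeline on synthetic data
#'
#' Runs the full workflow for one analyte: simulate reference trajectories
#' and triplicate spectra, average replicates, preprocess, split one-in-three
#' (samples ordered by power density then time), run the exhaustive Si-PLS
#' interval search, then fit the PCA-compressed BP-ANN on the selected
#' channels with its input PC count chosen by RMSECV, and compare the two
#' models on the untouched prediction set. All randomness derives from
#' `seed`; a repeated call with the same arguments returns an identical
#' result.
#'
#' @param seed Integer master seed (simulation, network initialization).
#' @param target `"SH"` or `"SS"`.
#' @param design An [experiment_design()].
#' @param instrument An [instrument_model()].
#' @param params A [trajectory_params()].
#' @param preprocess A [preprocess_spec()]; for MSC the reference spectrum is
#'   fitted on the calibration set only.
#' @param k_range,combo_sizes,max_pc,cv Si-PLS search settings (see
#'   [sipls_search()]).
#' @param ann_max_pc Largest BP-ANN input PC count considered.
#' @param ann_config A [bpann_config()].
#' @param ann_cv A [cv_scheme()] for the PC-count selection.
#' @return A `pipeline_result` with the simulated data, split, `sipls`
#'   search result, `ann` fit and both models' [metrics_record()]s plus the
#'   [compare_models()] verdict.
#' @export
run_pipeline <- function(seed, target = c("SH", "SS"),
                         design = experiment_design(),
                         instrument = instrument_model(),
                         params = trajectory_params(),
                         preprocess = preprocess_spec("snv"),
                         k_range = 15:30, combo_sizes = 2:4, max_pc = 10,
                         cv = cv_scheme("kfold", 5),
                         ann_max_pc = 10, ann_config = bpann_config(),
                         ann_cv = cv_scheme("kfold", 5)) {
  target <- match.arg(target)
  seed <- as.integer(seed)
  refs <- simulate_reference_trajectories(design, params, seed = seed)
  spectra <- simulate_spectra(refs, instrument,
                              replicates = design$replicates_per_sample,
                              seed = seed + 1L)
  dataset <- build_dataset(spectra, refs, average_replicates = TRUE)
  split <- split_one_in_three(dataset$meta$sample_id)
  y <- if (target == "SH") dataset$y_SH else dataset$y_SS
  if (preprocess$method == "msc") {
    ref_spec <- colMeans(dataset$X[split$cal_idx, , drop = FALSE])
    Xp <- msc(dataset$X, reference = ref_spec)
  } else {
    Xp <- apply_preprocess(dataset$X, preprocess)
  }
  x_cal <- Xp[split$cal_idx, , drop = FALSE]
  x_pred <- Xp[split$pred_idx, , drop = FALSE]
  y_cal <- y[split$cal_idx]
  y_pred <- y[split$pred_idx]
  sipls <- sipls_search(x_cal, y_cal, x_pred, y_pred, dataset$wavelengths,
                        k_range = k_range, combo_sizes = combo_sizes,
                        max_pc = max_pc, cv = cv)
  ch <- sipls$best$channels
  xs_cal <- x_cal[, ch, drop = FALSE]
  xs_pred <- x_pred[, ch, drop = FALSE]
  pc_sel <- select_pc_count(xs_cal, y_cal, max_pc = ann_max_pc,
                            config = ann_config, cv = ann_cv,
                            seed = seed + 2L)
  ann <- fit_bpann(xs_cal, y_cal, pc_sel$n_components, config = ann_config,
                   seed = seed + 3L)
  ann_pred <- predict_ann(ann, xs_pred)
  sipls_metrics <- metrics_record(y_cal, sipls$best$model$fitted,
                                  y_pred, predict(sipls$best$model, xs_pred),
                                  rmsecv = sipls$best$rmsecv)
  ann_metrics <- metrics_record(y_cal, ann$fitted, y_pred, ann_pred,
                                rmsecv = pc_sel$rmsecv[pc_sel$n_components])
  comparison <- compare_models(
    list(name = "Si-PLS", metrics = sipls_metrics, split = split$prediction),
    list(name = "BP-ANN", metrics = ann_metrics, split = split$prediction)
  )
  structure(
    list(seed = seed, target = target,
         refs = refs, dataset = dataset, split = split,
         sipls = sipls, sipls_metrics = sipls_metrics,
         ann = list(model = ann, n_pc = pc_sel$n_components,
                    rmsecv_curve = pc_sel$rmsecv),
         ann_metrics = ann_metrics,
         comparison = comparison),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: target %s, seed %d, %d samples (%d cal / %d pred)\n",
              x$target, x$seed, nrow(x$dataset$X),
              length(x$split$calibration), length(x$split$prediction)))
  b <- x$sipls$best
  cat(sprintf("Si-PLS: k = %d, intervals [%s], %d PCs\n  ",
              b$k, paste(b$intervals, collapse = ", "), b$n_components))
  print(x$sipls_metrics)
  cat(sprintf("BP-ANN: %d input PCs, %d hidden units\n  ",
              x$ann$n_pc, x$ann$model$config$hidden_size))
  print(x$ann_metrics)
  cat(sprintf("winner by Rp: %s\n", x$comparison$winner))
  invisible(x)
}

#' Write the JSON run manifest for a pipeline result
#' @param result A `pipeline_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  b <- result$sipls$best
  jsonlite::write_json(
    list(seed = result$seed, target = result$target,
         n_samples = nrow(result$dataset$X),
         n_cal = length(result$split$calibration),
         n_pred = length(result$split$prediction),
         sipls = list(k = b$k, intervals = b$intervals,
                      n_components = b$n_components,
                      metrics = unclass(result$sipls_metrics)),
         bpann = list(n_pc = result$ann$n_pc,
                      metrics = unclass(result$ann_metrics)),
         winner = result$comparison$winner,
         package_version = as.character(utils::packageVersion("thionir"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
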