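#' One-in-three calibration/prediction split
#'
#' Every third sample (positions 3, 6, 9, ... in the supplied order) goes to
#' the prediction set; the remainder form the calibration set. The input
#' order is part of the contract: order samples by power density, then time,
#' before splitting. 64 samples yield 43 calibration / 21 prediction.
#'
#' @param sample_ids Ordered vector of sample identifiers (>= 3).
#' @return A `split_one_in_three` list with `calibration`/`prediction` ids
#'   and the corresponding `cal_idx`/`pred_idx` positions.
#' @export
split_one_in_three <- function(sample_ids) {
  n <- length(sample_ids)
  if (n < 3) stop("size error: at least 3 samples are required")
  pred_idx <- seq.int(3L, n, by = 3L)
  cal_idx <- setdiff(seq_len(n), pred_idx)
  structure(
    list(calibration = sample_ids[cal_idx], prediction = sample_ids[pred_idx],
         cal_idx = cal_idx, pred_idx = pred_idx),
    class = "split_one_in_three"
  )
}

#' Correlation, RMSE and RPD for one prediction set
#'
#' `R` is the Pearson correlation of predicted vs measured values, `RMSE`
#' the root mean squared error, and `RPD` the residual prediction deviation:
#' the (n-1) sample standard deviation of the prediction-set reference
#' values divided by the RMSEP. An exact prediction gives `RPD = Inf`.
#'
#' @param y_ref Measured reference values.
#' @param y_pred Predicted values (same length, >= 2).
#' @param sd_ref Reference SD used in the RPD; defaults to `sd(y_ref)`. Pass
#'   the prediction-set reference SD explicitly when evaluating subsets.
#' @return List with `R`, `R_squared`, `RMSE`, `RPD`.
#' @export
compute_metrics <- function(y_ref, y_pred, sd_ref = sd(y_ref)) {
  if (length(y_ref) != length(y_pred) || length(y_ref) < 2) {
    stop("y_ref and y_pred must have equal length >= 2")
  }
  if (var(y_ref) == 0) {
    stop("zero-variance reference: correlation undefined")
  }
  r <- cor(y_ref, y_pred)
  rmse_v <- rmse(y_ref, y_pred)
  rpd <- if (rmse_v == 0) Inf else sd_ref / rmse_v
  list(R = r, R_squared = r^2, RMSE = rmse_v, RPD = rpd)
}

#' Assemble the full metrics record for one fitted model
#'
#' @param y_cal,yhat_cal Calibration reference and fitted values.
#' @param y_pred,yhat_pred Prediction-set reference and predicted values.
#' @param rmsecv Cross-validation RMSE of the calibration (optional).
#' @return A `metrics_record` with `Rc`, `RMSEC`, `RMSECV`, `Rp`,
#'   `Rp_squared`, `RMSEP`, `RPD`, `n_cal`, `n_pred`.
#' @export
metrics_record <- function(y_cal, yhat_cal, y_pred, yhat_pred,
                           rmsecv = NA_real_) {
  cal <- compute_metrics(y_cal, yhat_cal)
  pred <- compute_metrics(y_pred, yhat_pred)
  structure(
    list(Rc = cal$R, RMSEC = cal$RMSE, RMSECV = rmsecv,
         Rp = pred$R, Rp_squared = pred$R_squared, RMSEP = pred$RMSE,
         RPD = pred$RPD, n_cal = length(y_cal), n_pred = length(y_pred)),
    class = "metrics_record"
  )
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf(
    "Rc %.4f  RMSEC %.4g  RMSECV %.4g | Rp %.4f  Rp^2 %.4f  RMSEP %.4g  RPD %.3g (n %d/%d)\n",
    x$Rc, x$RMSEC, x$RMSECV, x$Rp, x$Rp_squared, x$RMSEP, x$RPD,
    x$n_cal, x$n_pred))
  invisible(x)
}

#' Compare two calibration models fitted on the same split
#'
#' Declares the winner by the higher prediction-set correlation `Rp`; at a
#' tie the lower `RMSEP` wins.
#'
#' @param a,b Lists with elements `name`, `metrics` (a [metrics_record()])
#'   and `split` (the prediction ids the metrics were computed on).
#' @return A `model_comparison`: side-by-side table and `winner`.
#' @export
compare_models <- function(a, b) {
  for (m in list(a, b)) {
    if (!all(c("name", "metrics", "split") %in% names(m))) {
      stop("each model needs name, metrics and split")
    }
  }
  if (!identical(a$split, b$split)) {
    stop("comparability error: models were evaluated on different splits")
  }
  fields <- c("Rc", "RMSEC", "RMSECV", "Rp", "Rp_squared", "RMSEP", "RPD")
  tab <- data.frame(
    metric = fields,
    a = vapply(fields, function(f) a$metrics[[f]], numeric(1)),
    b = vapply(fields, function(f) b$metrics[[f]], numeric(1))
  )
  names(tab)[2:3] <- c(a$name, b$name)
  winner <- if (a$metrics$Rp > b$metrics$Rp) {
    a$name
  } else if (b$metrics$Rp > a$metrics$Rp) {
    b$name
  } else if (a$metrics$RMSEP <= b$metrics$RMSEP) {
    a$name
  } else {
    b$name
  }
  structure(list(table = tab, winner = winner), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("winner: %s\n", x$winner))
  invisible(x)
}

#' Write a metrics record (or several) as TSV
#' @param records Named list of `metrics_record` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(records, path) {
  rows <- lapply(names(records), function(nm) {
    r <- records[[nm]]
    data.frame(model = nm, Rc = r$Rc, RMSEC = r$RMSEC, RMSECV = r$RMSECV,
               Rp = r$Rp, Rp_squared = r$Rp_squared, RMSEP = r$RMSEP,
               RPD = r$RPD, n_cal = r$n_cal, n_pred = r$n_pred)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
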