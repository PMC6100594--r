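#' Partition the channel axis into contiguous intervals
#'
#' Splits `n_channels` channels into `k` contiguous intervals whose sizes
#' differ by at most one: the first `n_channels %% k` intervals get the extra
#' channel. Intervals are reported 1-based.
#'
#' @param n_channels Number of spectral channels.
#' @param k Number of intervals, `1 <= k <= n_channels`.
#' @param wavelengths Optional wavelength grid (length `n_channels`) enabling
#'   [interval_to_wavelengths()].
#' @return An `interval_scheme`: list with `n_channels`, `k`, a data frame
#'   `intervals` (`index`, `start`, `end`, inclusive channel bounds) and
#'   `wavelengths`.
#' @examples
#' partition_intervals(7, 3)$intervals$end - partition_intervals(7, 3)$intervals$start + 1
#' @export
partition_intervals <- function(n_channels, k, wavelengths = NULL) {
  if (k < 1 || k > n_channels) {
    stop(sprintf("bounds error: k must be in 1..%d", n_channels))
  }
  if (!is.null(wavelengths) && length(wavelengths) != n_channels) {
    stop("shape error: wavelengths length must equal n_channels")
  }
  base <- n_channels %/% k
  extra <- n_channels %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  end <- cumsum(sizes)
  start <- end - sizes + 1L
  structure(
    list(n_channels = as.integer(n_channels), k = as.integer(k),
         intervals = data.frame(index = seq_len(k), start = start, end = end),
         wavelengths = wavelengths),
    class = "interval_scheme"
  )
}

#' Wavelength range covered by one interval
#' @param scheme An `interval_scheme` built with wavelengths.
#' @param index 1-based interval index.
#' @return Numeric `c(lambda_lo, lambda_hi)` in nm (first and last channel of
#'   the interval on the instrument grid).
#' @export
interval_to_wavelengths <- function(scheme, index) {
  stopifnot(inherits(scheme, "interval_scheme"))
  if (is.null(scheme$wavelengths)) {
    stop("scheme was built without a wavelength grid")
  }
  if (index < 1 || index > scheme$k) {
    stop(sprintf("bounds error: index must be in 1..%d", scheme$k))
  }
  iv <- scheme$intervals[index, ]
  c(scheme$wavelengths[iv$start], scheme$wavelengths[iv$end])
}

#' Channels covered by a set of intervals
#' @param scheme An `interval_scheme`.
#' @param indices 1-based interval indices.
#' @return Integer vector of channel indices, ascending.
#' @export
interval_channels <- function(scheme, indices) {
  stopifnot(inherits(scheme, "interval_scheme"))
  if (any(indices < 1 | indices > scheme$k)) {
    stop(sprintf("bounds error: interval indices must be in 1..%d", scheme$k))
  }
  unlist(lapply(sort(indices), function(i) {
    seq.int(scheme$intervals$start[i], scheme$intervals$end[i])
  }), use.names = FALSE)
}

# Strict comparison implementing the Si-PLS tie-break cascade: lower RMSECV,
# then fewer components, then fewer intervals, then lexicographically
# smallest interval set, then smaller k. Deterministic regardless of the
# order candidates are examined in.
sipls_better <- function(cand, best) {
  if (is.null(best)) return(TRUE)
  if (cand$rmsecv != best$rmsecv) return(cand$rmsecv < best$rmsecv)
  if (cand$n_components != best$n_components) {
    return(cand$n_components < best$n_components)
  }
  if (length(cand$intervals) != length(best$intervals)) {
    return(length(cand$intervals) < length(best$intervals))
  }
  for (i in seq_along(cand$intervals)) {
    if (cand$intervals[i] != best$intervals[i]) {
      return(cand$intervals[i] < best$intervals[i])
    }
  }
  cand$k < best$k
}

#' Exhaustive synergy-interval PLS (Si-PLS) search
#'
#' For each interval count `k` the calibration spectra are partitioned into
#' `k` contiguous intervals and every combination of `combo_sizes` intervals
#' is evaluated: the combination's channels are concatenated, the PLS
#' component count is chosen by minimum RMSECV on the calibration set, and
#' the combination with the lowest RMSECV wins. Prediction-set metrics are
#' computed once per winner and are never used for selection. The global
#' winner is the per-k winner with the lowest RMSECV.
#'
#' @param x_cal,y_cal Calibration spectra matrix and reference values.
#' @param x_pred,y_pred Prediction-set spectra and reference values.
#' @param wavelengths Wavelength grid (nm) of the spectra columns.
#' @param k_range Interval counts to scan (default 15-30).
#' @param combo_sizes Interval combination sizes (default 2-4).
#' @param max_pc Largest PLS component count considered (default 10).
#' @param cv A [cv_scheme()] for the RMSECV selection.
#' @param keep_all Keep every combination's RMSECV per k (for auditing the
#'   exhaustive search).
#' @return A `sipls_result`: `table` (one row per k: selected subintervals,
#'   PCs, Rc, RMSEC, RMSECV, Rp, RMSEP) and `best` (global winner with
#'   channels, wavelength ranges, fitted `pls_model` and metrics).
#' @export
sipls_search <- function(x_cal, y_cal, x_pred, y_pred, wavelengths,
                         k_range = 15:30, combo_sizes = 2:4, max_pc = 10,
                         cv = cv_scheme("loo"), keep_all = FALSE) {
  x_cal <- check_xy(x_cal, y_cal)
  x_pred <- check_xy(x_pred, y_pred)
  if (ncol(x_pred) != ncol(x_cal)) stop("shape error: channel count mismatch")
  if (length(wavelengths) != ncol(x_cal)) {
    stop("shape error: wavelengths length must equal channel count")
  }
  if (length(combo_sizes) < 1 || any(combo_sizes < 1)) {
    stop("configuration error: empty or invalid combination sizes")
  }
  if (any(combo_sizes > min(k_range))) {
    stop("configuration error: combination size exceeds interval count")
  }
  fold <- fold_ids(cv, nrow(x_cal))
  check_cv_folds(y_cal, fold)
  rows <- list()
  all_evals <- list()
  best_global <- NULL
  for (k in k_range) {
    scheme <- partition_intervals(ncol(x_cal), k, wavelengths)
    combos <- unlist(lapply(combo_sizes, function(s) {
      combn(k, s, simplify = FALSE)
    }), recursive = FALSE)
    ev <- cpp_sipls_eval(x_cal, y_cal,
                         as.integer(scheme$intervals$start),
                         as.integer(scheme$intervals$end),
                         combos, as.integer(max_pc), as.integer(fold))
    best_k <- NULL
    for (i in seq_along(combos)) {
      cand <- list(k = k, intervals = combos[[i]],
                   rmsecv = ev$rmsecv[i], n_components = ev$n_components[i])
      if (sipls_better(cand, best_k)) best_k <- cand
    }
    win <- evaluate_combination(best_k, scheme, x_cal, y_cal, x_pred, y_pred)
    rows[[as.character(k)]] <- data.frame(
      k = k,
      subintervals = paste0("[", paste(best_k$intervals, collapse = ", "), "]"),
      n_components = best_k$n_components,
      rmsecv = best_k$rmsecv,
      Rc = win$Rc, RMSEC = win$RMSEC, Rp = win$Rp, RMSEP = win$RMSEP,
      stringsAsFactors = FALSE
    )
    if (keep_all) {
      all_evals[[as.character(k)]] <- data.frame(
        k = k,
        combo = vapply(combos, paste, character(1), collapse = ","),
        rmsecv = ev$rmsecv, n_components = ev$n_components,
        stringsAsFactors = FALSE
      )
    }
    if (sipls_better(best_k, best_global)) {
      best_global <- c(best_k, win[c("Rc", "RMSEC", "Rp", "RMSEP")])
      best_global$channels <- win$channels
      best_global$model <- win$model
      best_global$wavelength_ranges <- win$wavelength_ranges
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(
    list(table = table, best = best_global,
         all = if (keep_all) do.call(rbind, all_evals) else NULL,
         k_range = k_range, combo_sizes = combo_sizes, max_pc = max_pc),
    class = "sipls_result"
  )
}

evaluate_combination <- function(cand, scheme, x_cal, y_cal, x_pred, y_pred) {
  ch <- interval_channels(scheme, cand$intervals)
  model <- fit_pls(x_cal[, ch, drop = FALSE], y_cal, cand$n_components)
  yhat_cal <- model$fitted
  yhat_pred <- predict(model, x_pred[, ch, drop = FALSE])
  list(
    channels = ch,
    model = model,
    wavelength_ranges = t(vapply(cand$intervals, function(i) {
      interval_to_wavelengths(scheme, i)
    }, numeric(2))),
    Rc = cor(yhat_cal, y_cal), RMSEC = rmse(y_cal, yhat_cal),
    Rp = cor(yhat_pred, y_pred), RMSEP = rmse(y_pred, yhat_pred),
    yhat_cal = yhat_cal, yhat_pred = yhat_pred
  )
}

#' @export
print.sipls_result <- function(x, ...) {
  cat("Synergy-interval PLS search\n")
  cat(sprintf("  k range %d-%d, combinations of {%s} intervals, max %d PCs\n",
              min(x$k_range), max(x$k_range),
              paste(x$combo_sizes, collapse = ","), x$max_pc))
  b <- x$best
  cat(sprintf("  winner: k = %d, intervals [%s], %d PCs, RMSECV %.4g\n",
              b$k, paste(b$intervals, collapse = ", "), b$n_components,
              b$rmsecv))
  cat(sprintf("  Rc %.4f  RMSEC %.4g  Rp %.4f  RMSEP %.4g\n",
              b$Rc, b$RMSEC, b$Rp, b$RMSEP))
  invisible(x)
}

#' Write a Si-PLS search report
#'
#' Writes the per-k winner table as TSV (one row per interval count:
#' subintervals, PCs, Rc, RMSEC, Rp, RMSEP) and, optionally, the global
#' winner with its wavelength ranges as JSON.
#'
#' @param result A `sipls_result`.
#' @param tsv_path Output TSV path.
#' @param json_path Optional output JSON path for the global winner.
#' @return `tsv_path`, invisibly.
#' @export
write_sipls_report <- function(result, tsv_path, json_path = NULL) {
  stopifnot(inherits(result, "sipls_result"))
  utils::write.table(result$table, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    b <- result$best
    jsonlite::write_json(
      list(k = b$k, intervals = b$intervals, n_components = b$n_components,
           rmsecv = b$rmsecv, Rc = b$Rc, RMSEC = b$RMSEC, Rp = b$Rp,
           RMSEP = b$RMSEP,
           wavelength_ranges_nm = apply(b$wavelength_ranges, 1, function(r) {
             list(lo = r[1], hi = r[2])
           })),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
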