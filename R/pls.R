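#' Cross-validation scheme
#'
#' Leave-one-out (default; deterministic and cheap at the sample sizes used
#' here) or contiguous k-fold, where fold blocks follow the sample order and
#' their sizes differ by at most one.
#'
#' @param kind `"loo"` or `"kfold"`.
#' @param k Number of folds when `kind = "kfold"`.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("loo", "kfold"), k = 5) {
  kind <- match.arg(kind)
  if (kind == "kfold" && k < 2) stop("cv error: k must be >= 2")
  structure(list(kind = kind, k = as.integer(k)), class = "cv_scheme")
}

#' Fold assignment for a cross-validation scheme
#' @param scheme A [cv_scheme()].
#' @param n Number of samples.
#' @return Integer vector of 1-based fold ids, one per sample.
#' @export
fold_ids <- function(scheme, n) {
  stopifnot(inherits(scheme, "cv_scheme"))
  if (scheme$kind == "loo") return(seq_len(n))
  if (scheme$k > n) stop("cv error: more folds than samples")
  base <- n %/% scheme$k
  extra <- n %% scheme$k
  sizes <- rep(base, scheme$k) + c(rep(1L, extra), rep(0L, scheme$k - extra))
  rep(seq_len(scheme$k), times = sizes)
}

check_xy <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (nrow(X) != length(y)) stop("shape error: nrow(X) must equal length(y)")
  X
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' NIPALS partial least squares with a single response: X is deflated after
#' each component, X and y are mean-centered, and no variance scaling is
#' applied (SNV-preprocessed spectra are already normalized per spectrum).
#'
#' @param X Predictor matrix (n x p), e.g. preprocessed absorbances.
#' @param y Response vector (umol/g).
#' @param n_components Number of latent variables, in
#'   `1..min(n - 1, p)`.
#' @return An object of class `pls_model` with the regression vector for the
#'   centered data (`coef`, one column per component count up to
#'   `n_components`), `x_mean`, `y_mean`, NIPALS `weights`/`loadings`/
#'   `scores`, and training `fitted` values.
#' @export
fit_pls <- function(X, y, n_components) {
  X <- check_xy(X, y)
  if (var(y) == 0) stop("degenerate-target error: y has zero variance")
  amax <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1 || n_components > amax) {
    stop(sprintf("bounds error: n_components must be in 1..%d", amax))
  }
  fit <- cpp_pls_fit(X, y, as.integer(n_components))
  model <- structure(
    list(n_components = as.integer(n_components),
         coef = fit$coef,
         weights = fit$weights, loadings = fit$loadings,
         scores = fit$scores, q = as.numeric(fit$q),
         x_mean = as.numeric(fit$x_mean), y_mean = fit$y_mean,
         n_used = fit$n_used),
    class = "pls_model"
  )
  model$fitted <- predict(model, X)
  model
}

#' Predict from a PLS model
#' @param object A `pls_model`.
#' @param newdata Matrix with the same channel count the model was fitted on.
#' @param n_components Component count to predict with (defaults to the
#'   fitted count).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_components = object$n_components,
                              ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$x_mean)) {
    stop(sprintf("shape error: model expects %d channels, got %d",
                 length(object$x_mean), ncol(newdata)))
  }
  if (n_components < 1 || n_components > object$n_components) {
    stop("bounds error: n_components outside the fitted range")
  }
  b <- object$coef[, n_components]
  as.numeric(sweep(newdata, 2, object$x_mean) %*% b + object$y_mean)
}

check_cv_folds <- function(y, fold) {
  for (k in unique(fold)) {
    if (var(y[fold != k]) == 0) {
      stop(sprintf("degenerate-fold error: training fold %d has zero-variance y", k))
    }
  }
  invisible(TRUE)
}

#' RMSECV curve over component counts
#'
#' Root mean square error of cross-validation for 1..`max_pc` latent
#' variables: the model is refitted on each training fold and errors are
#' pooled over all held-out samples.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param max_pc Largest component count evaluated.
#' @param cv A [cv_scheme()].
#' @return Numeric vector of RMSECV values (umol/g), one per component count.
#' @export
rmsecv_curve <- function(X, y, max_pc, cv = cv_scheme("loo")) {
  X <- check_xy(X, y)
  if (max_pc < 1) stop("bounds error: max_pc must be >= 1")
  fold <- fold_ids(cv, nrow(X))
  check_cv_folds(y, fold)
  press <- cpp_pls_cv_press(X, y, as.integer(max_pc), as.integer(fold))
  as.numeric(sqrt(press / nrow(X)))
}

#' RMSECV at one component count
#' @inheritParams rmsecv_curve
#' @param n_components Component count to evaluate.
#' @return RMSECV in umol/g.
#' @export
rmsecv <- function(X, y, n_components, cv = cv_scheme("loo")) {
  rmsecv_curve(X, y, max_pc = n_components, cv = cv)[n_components]
}

#' Select the PLS component count by minimum RMSECV
#'
#' @inheritParams rmsecv_curve
#' @return List with `n_components` (the argmin; ties go to the smallest
#'   count) and the full `rmsecv` curve.
#' @export
select_n_components <- function(X, y, max_pc, cv = cv_scheme("loo")) {
  curve <- rmsecv_curve(X, y, max_pc = max_pc, cv = cv)
  list(n_components = which.min(curve), rmsecv = curve)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Serialize a PLS model to JSON
#' @param model A `pls_model`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_pls <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  jsonlite::write_json(
    list(n_components = model$n_components,
         coef = model$coef[, model$n_components],
         x_mean = model$x_mean, y_mean = model$y_mean),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
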