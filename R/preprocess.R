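#' Preprocessing specification
#'
#' Configuration for the four spectral preprocessing methods compared in this
#' workflow: none, standard normal variate (SNV), multiplicative scatter
#' correction (MSC), and Savitzky-Golay derivatives of order 1 or 2.
#'
#' @param method One of `"none"`, `"snv"`, `"msc"`, `"sg_derivative"`.
#' @param derivative_order 1 or 2 (Savitzky-Golay only).
#' @param window_length Odd filter window in channels, > `poly_order`.
#' @param poly_order Fitting polynomial degree, >= `derivative_order`.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("none", "snv", "msc", "sg_derivative"),
                            derivative_order = 1, window_length = 11,
                            poly_order = 2) {
  method <- match.arg(method)
  if (method == "sg_derivative") {
    if (!derivative_order %in% c(1, 2)) {
      stop("spec error: derivative_order must be 1 or 2")
    }
    if (window_length %% 2 != 1) stop("spec error: window_length must be odd")
    if (window_length <= poly_order) {
      stop("spec error: window_length must exceed poly_order")
    }
    if (poly_order < derivative_order) {
      stop("spec error: poly_order must be >= derivative_order")
    }
  }
  structure(list(method = method,
                 derivative_order = as.integer(derivative_order),
                 window_length = as.integer(window_length),
                 poly_order = as.integer(poly_order)),
            class = "preprocess_spec")
}

#' Standard normal variate (SNV)
#'
#' Centers and scales each spectrum to mean 0 and unit sample standard
#' deviation (n-1 denominator), removing per-spectrum multiplicative gain and
#' additive offset.
#'
#' @param x Numeric vector (one spectrum) or matrix (spectra in rows) with
#'   >= 2 channels.
#' @return Transformed vector or matrix of the same shape.
#' @examples
#' snv(c(1, 2, 3)) # -1 0 1
#' @export
snv <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, snv)))
  if (length(x) < 2) stop("snv requires >= 2 channels")
  s <- sd(x)
  if (s == 0) stop("zero-variance error: constant spectrum has no SNV transform")
  (x - mean(x)) / s
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum (least squares slope `a`
#' and intercept `b`) and corrects it to `(x - b) / a`. The reference
#' defaults to the mean spectrum of `x`; for prediction data pass the
#' calibration-set reference to avoid leakage.
#'
#' @param x Matrix of spectra (rows), or a single spectrum if `reference` is
#'   given.
#' @param reference Optional reference spectrum.
#' @return Corrected matrix (or vector) of the same shape.
#' @export
msc <- function(x, reference = NULL) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (is.null(reference)) {
    if (nrow(x) < 2) {
      stop("msc requires >= 2 spectra when no reference is supplied")
    }
    reference <- colMeans(x)
  }
  if (length(reference) != ncol(x)) stop("shape error: reference length mismatch")
  vr <- sum((reference - mean(reference))^2)
  if (vr == 0) stop("degenerate-reference error: reference spectrum has zero variance")
  rc <- reference - mean(reference)
  out <- t(apply(x, 1, function(r) {
    a <- sum(rc * (r - mean(r))) / vr
    b <- mean(r) - a * mean(reference)
    if (abs(a) < 1e-12) stop("degenerate slope in MSC fit")
    (r - b) / a
  }))
  if (vec) out[1, ] else out
}

#' Savitzky-Golay derivative
#'
#' Smoothed spectral derivative of order 1 or 2 with respect to channel
#' index. Output length equals input length; edge channels are handled by the
#' polynomial fit over the first/last window.
#'
#' @param x Spectrum vector or matrix of spectra (rows).
#' @param spec A [preprocess_spec()] with `method = "sg_derivative"`.
#' @return Derivative spectra, same shape as `x`.
#' @export
sg_derivative <- function(x, spec = preprocess_spec("sg_derivative")) {
  stopifnot(inherits(spec, "preprocess_spec"))
  if (spec$method != "sg_derivative") {
    stop("spec error: sg_derivative requires a sg_derivative spec")
  }
  if (is.matrix(x)) return(t(apply(x, 1, sg_derivative, spec = spec)))
  if (spec$window_length > length(x)) {
    stop("spec error: window does not fit within the channel count")
  }
  as.numeric(signal::sgolayfilt(x, p = spec$poly_order,
                                n = spec$window_length,
                                m = spec$derivative_order, ts = 1))
}

#' Apply a preprocessing specification to a spectra matrix
#'
#' @param X Matrix of spectra (rows).
#' @param spec A [preprocess_spec()].
#' @param reference Optional MSC reference spectrum (e.g. the calibration-set
#'   mean when transforming prediction spectra).
#' @return Transformed matrix.
#' @export
apply_preprocess <- function(X, spec, reference = NULL) {
  stopifnot(inherits(spec, "preprocess_spec"), is.matrix(X))
  switch(spec$method,
         none = X,
         snv = snv(X),
         msc = msc(X, reference = reference),
         sg_derivative = sg_derivative(X, spec))
}

#' Compare preprocessing methods by full-spectrum PLS cross-validation
#'
#' Applies each candidate method, fits a full-spectrum PLS with
#' cross-validated component selection, and ranks methods by their minimum
#' RMSECV (ascending; ties keep input order).
#'
#' @param X Calibration spectra matrix.
#' @param y Calibration reference values.
#' @param methods Named list of [preprocess_spec()] objects.
#' @param max_pc Maximum latent-variable count to consider.
#' @param cv A [cv_scheme()].
#' @return Data frame with columns `method`, `n_components`, `rmsecv`,
#'   `rank`, sorted by RMSECV.
#' @export
compare_preprocessing <- function(X, y, methods, max_pc = 10,
                                  cv = cv_scheme("loo")) {
  if (length(methods) < 1) stop("at least one method is required")
  if (is.null(names(methods)) || any(names(methods) == "")) {
    names(methods) <- vapply(methods, function(m) m$method, character(1))
  }
  res <- lapply(methods, function(m) {
    Xp <- apply_preprocess(X, m)
    sel <- select_n_components(Xp, y, max_pc = max_pc, cv = cv)
    data.frame(n_components = sel$n_components,
               rmsecv = min(sel$rmsecv))
  })
  tab <- do.call(rbind, res)
  tab <- cbind(method = names(methods), tab)
  ord <- order(tab$rmsecv)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
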