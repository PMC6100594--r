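#' Mean-centered principal component basis
#'
#' PCA of the (Si-PLS-selected) channels used to compress the spectra before
#' they enter the neural network. Scores are the centered data projected on
#' the orthonormal loadings.
#'
#' @param X Matrix (n x p) of selected-channel spectra.
#' @param n_pc Number of components, `1..min(n - 1, p)`.
#' @return A `pca_basis`: `loadings` (p x n_pc, orthonormal), `x_mean`,
#'   `scores` (n x n_pc), `explained_variance` shares of total variance.
#' @export
pca_fit <- function(X, n_pc) {
  stopifnot(is.matrix(X))
  amax <- min(nrow(X) - 1L, ncol(X))
  if (n_pc < 1 || n_pc > amax) {
    stop(sprintf("bounds error: n_pc must be in 1..%d", amax))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  structure(
    list(loadings = pc$rotation[, seq_len(n_pc), drop = FALSE],
         x_mean = as.numeric(pc$center),
         scores = pc$x[, seq_len(n_pc), drop = FALSE],
         explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pc)],
         n_pc = as.integer(n_pc)),
    class = "pca_basis"
  )
}

#' Project spectra on a PCA basis
#' @param basis A `pca_basis`.
#' @param X Matrix with the channel count the basis was fitted on.
#' @return Score matrix (n x n_pc).
#' @export
pca_project <- function(basis, X) {
  stopifnot(inherits(basis, "pca_basis"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(basis$x_mean)) {
    stop(sprintf("shape error: basis expects %d channels, got %d",
                 length(basis$x_mean), ncol(X)))
  }
  sweep(X, 2, basis$x_mean) %*% basis$loadings
}

#' Backpropagation network hyperparameters
#'
#' @param hidden_size Hidden-layer width (sigmoid units).
#' @param learning_rate Gradient step size.
#' @param momentum Momentum coefficient.
#' @param epochs Maximum full-batch epochs (>= 0).
#' @param tol Early-stop threshold on the epoch-to-epoch loss change.
#' @return An object of class `bpann_config`.
#' @export
bpann_config <- function(hidden_size = 5, learning_rate = 0.05,
                         momentum = 0.9, epochs = 2000, tol = 1e-8) {
  if (hidden_size < 1) stop("parameter error: hidden_size must be >= 1")
  if (epochs < 0) stop("parameter error: epochs must be >= 0")
  if (learning_rate <= 0) stop("parameter error: learning_rate must be > 0")
  if (momentum < 0 || momentum >= 1) {
    stop("parameter error: momentum must be in [0, 1)")
  }
  structure(list(hidden_size = as.integer(hidden_size),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), tol = tol),
            class = "bpann_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

net_forward <- function(net, Z) {
  H <- sigmoid(sweep(Z %*% net$W1, 2, net$b1, `+`))
  as.numeric(H %*% net$W2 + net$b2)
}

#' Train a three-layer backpropagation network on PCA scores
#'
#' Single hidden layer of sigmoid units and a linear output unit, trained by
#' full-batch gradient descent with momentum on the squared-error loss.
#' Inputs are standardized with training means/SDs; the target is scaled to
#' `[0.1, 0.9]` internally and unscaled on prediction. Weights are
#' initialized uniformly in `[-0.5, 0.5]` from `seed`, so identical seeds
#' give identical networks.
#'
#' @param scores PCA score matrix (n x n_pc).
#' @param y Response vector (umol/g).
#' @param config A [bpann_config()].
#' @param seed Integer seed for the weight initialization.
#' @return A `bpann_net` holding weights, scaling parameters, the loss trace
#'   and the number of epochs actually run.
#' @export
train_bpann <- function(scores, y, config = bpann_config(), seed) {
  stopifnot(inherits(config, "bpann_config"))
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite")
  }
  if (missing(seed)) stop("seed is required")
  if (nrow(scores) != length(y)) stop("shape error: nrow(scores) != length(y)")
  ymin <- min(y); ymax <- max(y)
  if (ymax == ymin) stop("degenerate-target error: y has zero range")
  z_mean <- colMeans(scores)
  z_sd <- apply(scores, 2, sd)
  z_sd[z_sd == 0] <- 1
  Z <- sweep(sweep(scores, 2, z_mean), 2, z_sd, `/`)
  ys <- 0.1 + 0.8 * (y - ymin) / (ymax - ymin)
  k <- ncol(Z); h <- config$hidden_size; n <- nrow(Z)
  net <- withr::with_seed(as.integer(seed), list(
    W1 = matrix(runif(k * h, -0.5, 0.5), k, h),
    b1 = runif(h, -0.5, 0.5),
    W2 = matrix(runif(h, -0.5, 0.5), h, 1),
    b2 = runif(1, -0.5, 0.5)
  ))
  vel <- list(W1 = net$W1 * 0, b1 = net$b1 * 0, W2 = net$W2 * 0, b2 = 0)
  lr <- config$learning_rate; mo <- config$momentum
  loss_trace <- numeric(0)
  prev_loss <- Inf
  epochs_run <- 0L
  if (config$epochs > 0) {
    for (e in seq_len(config$epochs)) {
      H <- sigmoid(sweep(Z %*% net$W1, 2, net$b1, `+`))
      o <- as.numeric(H %*% net$W2 + net$b2)
      err <- o - ys
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop(sprintf(
          "divergence error: non-finite loss at epoch %d (learning rate %g)",
          e, lr))
      }
      d_o <- matrix(2 * err / n, ncol = 1)
      g_W2 <- t(H) %*% d_o
      g_b2 <- sum(d_o)
      d_H <- (d_o %*% t(net$W2)) * H * (1 - H)
      g_W1 <- t(Z) %*% d_H
      g_b1 <- colSums(d_H)
      vel$W1 <- mo * vel$W1 - lr * g_W1
      vel$b1 <- mo * vel$b1 - lr * g_b1
      vel$W2 <- mo * vel$W2 - lr * g_W2
      vel$b2 <- mo * vel$b2 - lr * g_b2
      net$W1 <- net$W1 + vel$W1
      net$b1 <- net$b1 + vel$b1
      net$W2 <- net$W2 + vel$W2
      net$b2 <- net$b2 + vel$b2
      loss_trace <- c(loss_trace, loss)
      epochs_run <- e
      if (abs(prev_loss - loss) < config$tol) break
      prev_loss <- loss
    }
  }
  structure(
    list(W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
         z_mean = z_mean, z_sd = z_sd, y_min = ymin, y_max = ymax,
         config = config, seed = as.integer(seed),
         loss_trace = loss_trace, epochs_run = epochs_run),
    class = "bpann_net"
  )
}

#' Predict from a trained network on PCA scores
#' @param net A `bpann_net`.
#' @param scores Score matrix with the width the net was trained on.
#' @return Predictions on the original response scale (umol/g).
#' @export
predict_net <- function(net, scores) {
  stopifnot(inherits(net, "bpann_net"))
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  if (ncol(scores) != nrow(net$W1)) {
    stop(sprintf("shape error: network expects %d inputs, got %d",
                 nrow(net$W1), ncol(scores)))
  }
  Z <- sweep(sweep(scores, 2, net$z_mean), 2, net$z_sd, `/`)
  o <- net_forward(net, Z)
  (o - 0.1) / 0.8 * (net$y_max - net$y_min) + net$y_min
}

#' Fit the PCA-compressed BP-ANN calibration model
#'
#' Fits a PCA basis on the selected channels and trains the backpropagation
#' network on its scores.
#'
#' @param X_selected Calibration spectra restricted to the selected channels.
#' @param y Reference values (umol/g).
#' @param n_pc Number of input principal components.
#' @param config A [bpann_config()].
#' @param seed Integer seed.
#' @return A `bpann_model`: `pca`, `net`, `n_pc`, training `fitted` values.
#' @export
fit_bpann <- function(X_selected, y, n_pc, config = bpann_config(), seed) {
  pca <- pca_fit(X_selected, n_pc)
  net <- train_bpann(pca$scores, y, config = config, seed = seed)
  model <- structure(list(pca = pca, net = net, n_pc = as.integer(n_pc),
                          config = config, seed = as.integer(seed)),
                     class = "bpann_model")
  model$fitted <- predict_ann(model, X_selected)
  model
}

#' Predict SH/SS from selected-channel spectra with a BP-ANN model
#' @param model A `bpann_model`.
#' @param X_selected Spectra restricted to the channels the PCA basis was
#'   fitted on.
#' @return Predictions in umol/g.
#' @export
predict_ann <- function(model, X_selected) {
  stopifnot(inherits(model, "bpann_model"))
  predict_net(model$net, pca_project(model$pca, X_selected))
}

#' @export
predict.bpann_model <- function(object, newdata, ...) {
  predict_ann(object, newdata)
}

#' Select the number of input principal components by RMSECV
#'
#' Trains one network per candidate PC count under cross-validation (PCA and
#' network both refitted on each training fold) and returns the count with
#' the minimum RMSECV.
#'
#' @param X_selected Calibration spectra on the selected channels.
#' @param y Reference values.
#' @param max_pc Largest PC count considered.
#' @param config A [bpann_config()].
#' @param cv A [cv_scheme()].
#' @param seed Integer seed; per-fold network seeds are derived from it.
#' @return List with `n_components` (argmin; ties to the smallest count) and
#'   the `rmsecv` curve.
#' @export
select_pc_count <- function(X_selected, y, max_pc, config = bpann_config(),
                            cv = cv_scheme("kfold", 5), seed) {
  stopifnot(is.matrix(X_selected))
  if (max_pc < 1) stop("bounds error: max_pc must be >= 1")
  if (missing(seed)) stop("seed is required")
  fold <- fold_ids(cv, nrow(X_selected))
  check_cv_folds(y, fold)
  pc_cap <- min(max_pc, min(nrow(X_selected) - max(table(fold)) - 1L,
                            ncol(X_selected)))
  curve <- rep(NA_real_, max_pc)
  for (pc in seq_len(pc_cap)) {
    sq <- 0
    for (k in unique(fold)) {
      tr <- fold != k
      pca <- pca_fit(X_selected[tr, , drop = FALSE], pc)
      net <- train_bpann(pca$scores, y[tr], config = config,
                         seed = as.integer(seed) + 1009L * pc + k)
      pred <- predict_net(net, pca_project(pca, X_selected[!tr, , drop = FALSE]))
      sq <- sq + sum((pred - y[!tr])^2)
    }
    curve[pc] <- sqrt(sq / nrow(X_selected))
  }
  list(n_components = which.min(curve[seq_len(pc_cap)]),
       rmsecv = curve[seq_len(pc_cap)])
}

#' Serialize a BP-ANN model to JSON for exact reload
#' @param model A `bpann_model`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_bpann <- function(model, path) {
  stopifnot(inherits(model, "bpann_model"))
  jsonlite::write_json(
    list(n_pc = model$n_pc, seed = model$seed,
         config = unclass(model$config),
         pca = list(loadings = model$pca$loadings, x_mean = model$pca$x_mean,
                    explained_variance = model$pca$explained_variance),
         net = list(W1 = model$net$W1, b1 = model$net$b1,
                    W2 = model$net$W2, b2 = model$net$b2,
                    z_mean = model$net$z_mean, z_sd = model$net$z_sd,
                    y_min = model$net$y_min, y_max = model$net$y_max)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a BP-ANN model written by [write_bpann()]
#' @param path JSON file.
#' @return A `bpann_model` (without training history).
#' @export
read_bpann <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pca <- structure(
    list(loadings = as.matrix(j$pca$loadings), x_mean = j$pca$x_mean,
         scores = NULL, explained_variance = j$pca$explained_variance,
         n_pc = as.integer(j$n_pc)),
    class = "pca_basis")
  net <- structure(
    list(W1 = as.matrix(j$net$W1), b1 = j$net$b1,
         W2 = as.matrix(j$net$W2), b2 = j$net$b2,
         z_mean = j$net$z_mean, z_sd = j$net$z_sd,
         y_min = j$net$y_min, y_max = j$net$y_max,
         config = do.call(bpann_config, j$config), seed = as.integer(j$seed),
         loss_trace = numeric(0), epochs_run = NA_integer_),
    class = "bpann_net")
  structure(list(pca = pca, net = net, n_pc = as.integer(j$n_pc),
                 config = net$config, seed = net$seed),
            class = "bpann_model")
}
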