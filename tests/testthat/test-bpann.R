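test_that("pca is lossless at full rank and on planted subspaces", {
  withr::with_seed(101, {
    X <- matrix(rnorm(12 * 5), 12, 5)
  })
  b <- pca_fit(X, 5)
  recon <- sweep(b$scores %*% t(b$loadings), 2, -b$x_mean)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_lt(max(abs(crossprod(b$loadings) - diag(5))), 1e-8)
  # data confined to a 2-D plane in 5-D
  withr::with_seed(102, {
    S <- matrix(rnorm(20 * 2), 20, 2)
    L <- matrix(rnorm(2 * 5), 2, 5)
    Xp <- S %*% L
  })
  b2 <- pca_fit(Xp, 2)
  recon2 <- sweep(b2$scores %*% t(b2$loadings), 2, -b2$x_mean)
  expect_lt(max(abs(recon2 - Xp)), 1e-8)
})

test_that("explained-variance shares match an eigendecomposition oracle", {
  withr::with_seed(103, {
    X <- matrix(rnorm(6 * 4), 6, 4)
  })
  b <- pca_fit(X, 4)
  ev <- eigen(cov(X))$values
  expect_equal(b$explained_variance, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(b$explained_variance) <= 1e-12))
  expect_lte(sum(b$explained_variance), 1 + 1e-12)
  expect_error(pca_fit(X, 6), "bounds error")
})

test_that("zero training epochs leave the seeded initial network untouched", {
  withr::with_seed(104, {
    Z <- matrix(rnorm(20 * 3), 20, 3)
    y <- rnorm(20, 5, 2)
  })
  cfg <- bpann_config(hidden_size = 4, epochs = 0)
  net <- train_bpann(Z, y, cfg, seed = 7)
  init <- withr::with_seed(7L, list(
    W1 = matrix(runif(3 * 4, -0.5, 0.5), 3, 4),
    b1 = runif(4, -0.5, 0.5),
    W2 = matrix(runif(4, -0.5, 0.5), 4, 1),
    b2 = runif(1, -0.5, 0.5)
  ))
  expect_identical(net$W1, init$W1)
  expect_identical(net$W2, init$W2)
  # predictions equal the manual forward pass through the initial weights
  Zs <- scale(Z, center = net$z_mean, scale = net$z_sd)
  H <- 1 / (1 + exp(-(Zs %*% init$W1 + rep(init$b1, each = 20))))
  o <- as.numeric(H %*% init$W2 + init$b2)
  manual <- (o - 0.1) / 0.8 * (net$y_max - net$y_min) + net$y_min
  expect_equal(predict_net(net, Z), manual, tolerance = 1e-12)
})

test_that("training is bitwise deterministic under a fixed seed", {
  withr::with_seed(105, {
    Z <- matrix(rnorm(30 * 4), 30, 4)
    y <- rnorm(30, 3, 1)
  })
  n1 <- train_bpann(Z, y, bpann_config(epochs = 300), seed = 11)
  n2 <- train_bpann(Z, y, bpann_config(epochs = 300), seed = 11)
  expect_identical(n1$W1, n2$W1)
  expect_identical(n1$W2, n2$W2)
  expect_identical(n1$b1, n2$b1)
  n3 <- train_bpann(Z, y, bpann_config(epochs = 300), seed = 12)
  expect_false(identical(n1$W1, n3$W1))
})

test_that("the network fits a noiseless linear target", {
  withr::with_seed(106, {
    Z <- matrix(rnorm(40 * 3), 40, 3)
    y <- as.numeric(Z %*% c(2, -1, 0.5)) + 10
  })
  net <- train_bpann(Z, y, bpann_config(), seed = 21)
  expect_lt(sqrt(mean((predict_net(net, Z) - y)^2)), 0.05 * sd(y))
})

test_that("an all-zero network predicts the unscaled output bias", {
  withr::with_seed(107, {
    Z <- matrix(rnorm(10 * 2), 10, 2)
    y <- rnorm(10, 4, 1)
  })
  net <- train_bpann(Z, y, bpann_config(hidden_size = 3, epochs = 0), seed = 5)
  net$W1[] <- 0; net$b1[] <- 0; net$W2[] <- 0; net$b2 <- 0.4
  expected <- (0.4 - 0.1) / 0.8 * (net$y_max - net$y_min) + net$y_min
  expect_equal(predict_net(net, Z), rep(expected, 10), tolerance = 1e-12)
})

test_that("a 2-PC, 2-hidden-unit forward pass matches pencil-and-paper arithmetic", {
  net <- structure(
    list(W1 = matrix(c(1, 0, 0, 1), 2, 2), b1 = c(0, 0),
         W2 = matrix(c(0.5, -0.5), 2, 1), b2 = 0.5,
         z_mean = c(0, 0), z_sd = c(1, 1), y_min = 0, y_max = 8,
         config = bpann_config(hidden_size = 2), seed = 1L,
         loss_trace = numeric(0), epochs_run = 0L),
    class = "bpann_net")
  # input (0, 0): H = (0.5, 0.5), o = 0.5, unscaled = (0.5-0.1)/0.8*8 = 4
  expect_equal(predict_net(net, matrix(c(0, 0), 1)), 4, tolerance = 1e-12)
  # input (log(3), -log(3)): H = (0.75, 0.25), o = 0.75, unscaled = 6.5
  expect_equal(predict_net(net, matrix(c(log(3), -log(3)), 1)), 6.5,
               tolerance = 1e-12)
})

test_that("PC-count selection returns single candidates and planted dimensions", {
  dat <- make_latent_data(n = 36, p = 10, dim = 3, noise_sd = 0.05, seed = 108)
  one <- select_pc_count(dat$X, dat$y, max_pc = 1, seed = 1)
  expect_equal(one$n_components, 1)
  sel <- select_pc_count(dat$X, dat$y, max_pc = 6, seed = 2)
  expect_true(abs(sel$n_components - 3) <= 1)
})

test_that("serialized models reload with identical predictions", {
  dat <- make_latent_data(n = 30, p = 8, dim = 2, noise_sd = 0.1, seed = 109)
  m <- fit_bpann(dat$X, dat$y, 3, bpann_config(epochs = 500), seed = 31)
  path <- withr::local_tempfile(fileext = ".json")
  write_bpann(m, path)
  m2 <- read_bpann(path)
  Xnew <- make_latent_data(n = 5, p = 8, dim = 2, noise_sd = 0.1, seed = 110)$X
  expect_equal(predict_ann(m2, Xnew), predict_ann(m, Xnew), tolerance = 1e-12)
})

test_that("ANN and PLS agree on noiseless linear data", {
  dat <- make_latent_data(n = 45, p = 10, dim = 2, noise_sd = 0, seed = 111)
  new <- make_latent_data(n = 15, p = 10, dim = 2, noise_sd = 0, seed = 112)
  pls <- fit_pls(dat$X, dat$y, 2)
  ann <- fit_bpann(dat$X, dat$y, 2, seed = 41)
  rmse_pls <- sqrt(mean((predict(pls, new$X) - new$y)^2))
  rmse_ann <- sqrt(mean((predict_ann(ann, new$X) - new$y)^2))
  expect_lt(abs(rmse_ann - rmse_pls), 0.1 * sd(dat$y))
})

test_that("divergent or ill-posed training inputs raise errors", {
  Z <- matrix(rnorm(10 * 2), 10, 2)
  expect_error(train_bpann(Z, rep(1, 10), seed = 1), "degenerate-target")
  Zbad <- Z; Zbad[1, 1] <- Inf
  expect_error(train_bpann(Zbad, rnorm(10), seed = 1), "finite")
})
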