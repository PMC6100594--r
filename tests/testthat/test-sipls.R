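test_that("interval partitions have balanced, contiguous, covering ranges", {
  s <- partition_intervals(10, 5)
  expect_equal(s$intervals$end - s$intervals$start + 1, rep(2L, 5))
  s <- partition_intervals(7, 3)
  expect_equal(s$intervals$end - s$intervals$start + 1, c(3L, 2L, 2L))
  s <- partition_intervals(256, 20)
  sizes <- s$intervals$end - s$intervals$start + 1
  expect_equal(sizes, c(rep(13L, 16), rep(12L, 4)))
  expect_equal(s$intervals$start[1], 1L)
  expect_equal(s$intervals$end[20], 256L)
  expect_true(all(s$intervals$start[-1] == s$intervals$end[-20] + 1))
  expect_error(partition_intervals(10, 0), "bounds error")
  expect_error(partition_intervals(10, 11), "bounds error")
})

test_that("intervals map to wavelength ranges on the instrument grid", {
  wl <- seq(850, 2500, length.out = 256)
  s1 <- partition_intervals(256, 1, wl)
  expect_equal(interval_to_wavelengths(s1, 1), c(850, 2500))
  s20 <- partition_intervals(256, 20, wl)
  r <- interval_to_wavelengths(s20, 1)
  expect_equal(r[1], 850)
  expect_equal(r[2], 850 + 12 * (1650 / 255), tolerance = 1e-12)
  expect_error(interval_to_wavelengths(s20, 21), "bounds error")
  expect_error(interval_to_wavelengths(partition_intervals(256, 20), 1),
               "without a wavelength grid")
})

test_that("k=2 with both intervals selected reduces to full-spectrum PLS", {
  dat <- make_latent_data(n = 30, p = 16, dim = 3, noise_sd = 0.2, seed = 71)
  pred <- make_latent_data(n = 9, p = 16, dim = 3, noise_sd = 0.2, seed = 72)
  res <- sipls_search(dat$X, dat$y, pred$X, pred$y,
                      wavelengths = seq_len(16), k_range = 2,
                      combo_sizes = 2, max_pc = 4)
  full <- rmsecv_curve(dat$X, dat$y, max_pc = 4)
  expect_equal(res$best$rmsecv, min(full), tolerance = 1e-10)
  expect_equal(res$best$intervals, c(1L, 2L))
})

test_that("the search enumerates exactly C(k,2)+C(k,3)+C(k,4) combinations", {
  dat <- make_latent_data(n = 25, p = 24, dim = 2, noise_sd = 0.2, seed = 73)
  pred <- make_latent_data(n = 8, p = 24, dim = 2, noise_sd = 0.2, seed = 74)
  res <- sipls_search(dat$X, dat$y, pred$X, pred$y,
                      wavelengths = seq_len(24), k_range = 8,
                      combo_sizes = 2:4, max_pc = 3,
                      cv = cv_scheme("kfold", 5), keep_all = TRUE)
  expect_equal(nrow(res$all), choose(8, 2) + choose(8, 3) + choose(8, 4))
})

test_that("the winner attains the minimum over an independent re-enumeration", {
  dat <- make_latent_data(n = 24, p = 18, dim = 2, noise_sd = 0.3, seed = 75)
  pred <- make_latent_data(n = 8, p = 18, dim = 2, noise_sd = 0.3, seed = 76)
  cvs <- cv_scheme("kfold", 4)
  res <- sipls_search(dat$X, dat$y, pred$X, pred$y,
                      wavelengths = seq_len(18), k_range = 6,
                      combo_sizes = 2:3, max_pc = 3, cv = cvs,
                      keep_all = TRUE)
  # independent oracle: re-enumerate every combination with rmsecv_curve
  scheme <- partition_intervals(18, 6)
  combos <- c(combn(6, 2, simplify = FALSE), combn(6, 3, simplify = FALSE))
  oracle <- vapply(combos, function(iv) {
    ch <- interval_channels(scheme, iv)
    min(rmsecv_curve(dat$X[, ch, drop = FALSE], dat$y, max_pc = 3, cv = cvs))
  }, numeric(1))
  expect_equal(min(oracle), res$best$rmsecv, tolerance = 1e-10)
  expect_true(all(res$best$rmsecv <= oracle + 1e-12))
  expect_equal(res$all$rmsecv, oracle, tolerance = 1e-10)
  # winner equals the tie-break-ordered head of the audit table
  ord <- order(res$all$rmsecv, res$all$n_components, nchar(res$all$combo),
               res$all$combo)
  expect_equal(res$all$combo[ord[1]],
               paste(res$best$intervals, collapse = ","))
})

test_that("planted analyte intervals are recovered and beat the full spectrum", {
  sim <- simulate_cal_pred(planted_instrument(), seed = 81,
                           preprocess = "none")
  res <- sipls_search(sim$x_cal, sim$y_cal, sim$x_pred, sim$y_pred,
                      sim$wavelengths, k_range = 10, combo_sizes = 2,
                      max_pc = 6, cv = cv_scheme("kfold", 5))
  expect_true(all(c(2L, 7L) %in% res$best$intervals))
  full <- fit_pls(sim$x_cal, sim$y_cal,
                  select_n_components(sim$x_cal, sim$y_cal, 6,
                                      cv = cv_scheme("kfold", 5))$n_components)
  rmsep_full <- sqrt(mean((predict(full, sim$x_pred) - sim$y_pred)^2))
  expect_lt(res$best$RMSEP, rmsep_full)
})

test_that("invalid configurations are rejected", {
  dat <- make_latent_data(n = 12, p = 10, dim = 2, noise_sd = 0.2, seed = 77)
  expect_error(sipls_search(dat$X, dat$y, dat$X, dat$y, seq_len(10),
                            k_range = 4, combo_sizes = integer(0)),
               "configuration error")
  expect_error(sipls_search(dat$X, dat$y, dat$X, dat$y, seq_len(10),
                            k_range = 3, combo_sizes = 4),
               "configuration error")
})

test_that("search reports round trip to TSV and JSON", {
  dat <- make_latent_data(n = 20, p = 12, dim = 2, noise_sd = 0.2, seed = 78)
  pred <- make_latent_data(n = 6, p = 12, dim = 2, noise_sd = 0.2, seed = 79)
  res <- sipls_search(dat$X, dat$y, pred$X, pred$y, seq_len(12),
                      k_range = 4:5, combo_sizes = 2, max_pc = 3,
                      cv = cv_scheme("kfold", 4))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_sipls_report(res, tsv, js)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$k, 4:5)
  win <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(win$rmsecv, res$best$rmsecv)
})
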