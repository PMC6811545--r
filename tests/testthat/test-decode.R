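mk_raster <- function(trains, duration = 200) {
  spikes <- do.call(rbind, lapply(seq_along(trains), function(i) {
    if (!length(trains[[i]])) return(NULL)
    data.frame(neuron = i, population = "Ex", t_ms = trains[[i]])
  }))
  if (is.null(spikes)) {
    spikes <- data.frame(neuron = integer(0), population = character(0),
                         t_ms = numeric(0))
  }
  structure(list(spikes = spikes, n_ex = length(trains), n_in = 0,
                 duration = duration), class = "spike_raster")
}

test_that("feature matrices bin counts conservatively", {
  r <- mk_raster(list(c(25), c(5, 95)), duration = 100)
  X <- featurize(list(r), ensemble = 1:2, bin_ms = 10)
  expect_equal(dim(X), c(1, 20))
  expect_equal(X[1, 3], 1)           # spike at 25 ms -> bin 3 of neuron 1
  expect_equal(sum(X), 3)            # conservation of spike counts
  X20 <- featurize(list(r), ensemble = 1:2, bin_ms = 20)
  expect_equal(ncol(X20), 10)        # doubling bin width halves columns
  expect_equal(sum(X20), 3)
  expect_error(featurize(list(r), integer(0)), "ensemble")
})

test_that("the decoder separates separated clouds and respects its limits", {
  set.seed(1)
  X <- rbind(matrix(rnorm(100, 0), 10), matrix(rnorm(100, 5), 10))
  y <- rep(c("a", "b"), each = 10)
  dec <- train_linear_decoder(X, y)
  expect_equal(predict(dec, X), y)   # zero training error
  expect_error(train_linear_decoder(X, rep("a", 20)), "two classes")

  # lambda = 1 (shrinkage): nearest-class-mean geometry, w parallel to
  # the mean difference
  dec1 <- train_linear_decoder(X, y, lambda = 1)
  mu_diff <- colMeans(X[11:20, ]) - colMeans(X[1:10, ])
  cosang <- sum(dec1$w * mu_diff) /
    sqrt(sum(dec1$w^2) * sum(mu_diff^2))
  expect_equal(cosang, 1, tolerance = 1e-8)

  # wide problems (features >> trials) solve exactly via Woodbury:
  # compare against a direct dense solve on a small instance
  set.seed(2)
  Xw <- rbind(matrix(rnorm(8 * 30), 8), matrix(rnorm(8 * 30, 1), 8))
  yw <- rep(c("a", "b"), each = 8)
  dw <- train_linear_decoder(Xw, yw, lambda = 0.05)
  mu0 <- colMeans(Xw[1:8, ]); mu1 <- colMeans(Xw[9:16, ])
  Xc <- rbind(sweep(Xw[1:8, ], 2, mu0), sweep(Xw[9:16, ], 2, mu1))
  S <- crossprod(Xc) / 14
  Sreg <- (1 - 0.05) * S + 0.05 * mean(diag(S)) * diag(30)
  w_direct <- solve(Sreg, mu1 - mu0)
  expect_equal(dw$w, w_direct, tolerance = 1e-8)
})

test_that("LOOCV error is 0 on separable data and chance under permutation", {
  set.seed(3)
  X <- rbind(matrix(rnorm(60, 0, 0.5), 10), matrix(rnorm(60, 4, 0.5), 10))
  y <- rep(c("regular", "oddball"), each = 10)
  res <- loo_cv(X, y)
  expect_equal(res$error, 0)
  expect_equal(res$n_folds, 20)

  # label-permutation null centred at 0.5
  res_p <- loo_cv(X, y, n_perm = 100, seed = 5)
  se <- sd(res_p$null_errors) / sqrt(length(res_p$null_errors))
  expect_lt(abs(mean(res_p$null_errors) - 0.5), 3 * se + 0.02)

  # identical class distributions: error indistinguishable from chance
  set.seed(4)
  errs <- vapply(1:30, function(i) {
    Xn <- matrix(rnorm(20 * 6), 20)
    loo_cv(Xn, y)$error
  }, numeric(1))
  se0 <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs) - 0.5), 3 * se0 + 0.02)
  expect_true(all(errs >= 0 & errs <= 1))
})

test_that("pure-noise feature columns do not rescue the decoder", {
  set.seed(6)
  y <- rep(c("a", "b"), each = 8)
  diffs <- vapply(1:20, function(i) {
    X <- rbind(matrix(rnorm(8 * 4, 0, 1), 8), matrix(rnorm(8 * 4, 1.2, 1), 8))
    e1 <- loo_cv(X, y)$error
    e2 <- loo_cv(cbind(X, matrix(rnorm(16 * 40), 16)), y)$error
    e2 - e1
  }, numeric(1))
  # adding 40 noise dimensions never helps beyond sampling noise (on
  # average)
  expect_gt(mean(diffs), -0.05)
})

test_that("ensemble decoding separates structured from identical responses", {
  # trials where neurons fire around different latencies per condition are
  # decodable; identical response distributions are not
  gen_raster <- function(shift, seed) {
    set.seed(seed)
    mk_raster(lapply(1:30, function(i)
      sort(runif(3, 50 + shift, 100 + shift))), duration = 200)
  }
  reg <- lapply(1:8, function(s) gen_raster(0, s))
  odd <- lapply(1:8, function(s) gen_raster(60, 100 + s))
  X <- featurize(c(reg, odd), ensemble = 1:30, bin_ms = 10)
  y <- rep(c("regular", "oddball"), each = 8)
  expect_equal(loo_cv(X, y)$error, 0)

  same <- lapply(1:16, function(s) gen_raster(0, 200 + s))
  Xs <- featurize(same, ensemble = 1:30, bin_ms = 10)
  expect_gt(loo_cv(Xs, y)$error, 0.2)
})

test_that("single-cell oddball summaries match their direct recomputation", {
  reg <- lapply(1:3, function(i) mk_raster(list(c(50, 100), c(20))))
  odd <- lapply(1:3, function(i) mk_raster(list(c(50, 100, 150), c(20))))
  res <- oddball_single_cell(reg, odd, neurons = 1:2)
  expect_equal(res$delta_rate, c(1, 0))
  expect_equal(res$delta_first_ms, c(0, 0))
  expect_equal(res$dissimilarity[2], 0)
  # oracle: the per-neuron mean of all pairwise van Rossum distances
  d_expect <- van_rossum(c(50, 100), c(50, 100, 150))
  expect_equal(res$dissimilarity[1], d_expect, tolerance = 1e-12)
})
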