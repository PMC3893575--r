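test_that("single-component EM recovers the sample moments", {
  set.seed(1)
  X <- matrix(rnorm(500 * 3), 500, 3) %*% chol(diag(c(1, 2, 0.5))) +
    rep(c(1, -1, 2), each = 500)
  g <- gmm_fit_em(X, 1)
  expect_equal(g$means[1, ], colMeans(X), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(g$covariances[, , 1], cov(X) * 499 / 500, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(g$weights, 1)
})

test_that("EM separates well-separated clusters", {
  set.seed(2)
  n <- 1000
  X <- rbind(matrix(rnorm(n * 2, mean = 0), n, 2),
             matrix(rnorm(n * 2, mean = 6), n, 2))
  g <- gmm_fit_em(X, 2, seed = 1)
  mu <- g$means[order(g$means[, 1]), ]
  se <- 1 / sqrt(n)
  expect_lt(max(abs(mu[1, ] - 0)), 3 * se)
  expect_lt(max(abs(mu[2, ] - 6)), 3 * se)
  expect_equal(sort(g$weights), c(0.5, 0.5), tolerance = 0.05)
})

test_that("EM requires at least k observations and survives degenerate data", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(gmm_fit_em(X, 6), "at least")
  # rank-deficient data: constant column handled by the eigenvalue floor
  Xd <- cbind(rnorm(50), 1)
  g <- gmm_fit_em(Xd, 2, seed = 1)
  for (j in 1:2)
    expect_gte(min(eigen(g$covariances[, , j])$values), 1e-6 - 1e-12)
})

test_that("incremental updates interpolate between old model and batch", {
  set.seed(3)
  g0 <- gmm_fit_em(matrix(rnorm(200), 100, 2), 1)
  batch <- matrix(rnorm(100, mean = 5), 50, 2)
  expect_identical(gmm_incremental_update(g0, batch, 0), g0)
  g1 <- gmm_incremental_update(g0, batch, 1, sweeps = 1L)
  expect_equal(g1$means[1, ], colMeans(batch), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(g1$covariances[, , 1], cov(batch) * 49 / 50,
               tolerance = 1e-6, ignore_attr = TRUE)
  g5 <- gmm_incremental_update(g0, batch, 0.5, sweeps = 1L)
  expect_equal(g5$means[1, ],
               0.5 * g0$means[1, ] + 0.5 * colMeans(batch),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("streaming incremental EM tracks a pooled classical fit", {
  set.seed(4)
  truth <- vd_gmm(c(0.3, 0.4, 0.3), rbind(c(-4, 0), c(0, 3), c(4, -2)),
                  array(c(diag(2) * 0.5, diag(2) * 0.8, diag(2) * 0.6),
                        c(2, 2, 3)))
  batches <- lapply(1:60, function(i) gmm_sample(truth, 100))
  pooled <- do.call(rbind, batches)
  g <- gmm_fit_em(batches[[1]], 3, seed = 1)
  for (i in 2:60)
    g <- gmm_incremental_update(g, batches[[i]],
                                alpha = learning_rate(i - 2, 58))
  heldout <- gmm_sample(truth, 2000)
  ll_inc <- gmm_loglik(g, heldout) / 2000
  ll_pool <- gmm_loglik(gmm_fit_em(pooled, 3, seed = 1), heldout) / 2000
  expect_lt(abs(ll_inc - ll_pool) / abs(ll_pool), 0.05)
})

test_that("the learning-rate schedule hits its endpoints and decreases", {
  expect_equal(learning_rate(0, 600), 0.1)
  expect_equal(learning_rate(600, 600), 0.01)
  a <- vapply(0:150, learning_rate, 0, total_updates = 150)
  expect_true(all(diff(a) < 0))
  expect_error(learning_rate(10, 5))
})

test_that("conditioning matches the closed form for a single Gaussian", {
  mu <- c(1, -2)
  S <- matrix(c(2, 0.8, 0.8, 1.5), 2)
  g <- vd_gmm(1, matrix(mu, 1), array(S, c(2, 2, 1)))
  v <- 0.7
  cond <- gmm_condition(g, 2, v)
  expect_equal(cond$means[1, 1], mu[1] + S[1, 2] / S[2, 2] * (v - mu[2]),
               tolerance = 1e-12)
  expect_equal(cond$covariances[1, 1, 1],
               S[1, 1] - S[1, 2]^2 / S[2, 2], tolerance = 1e-12)
  # independent case: conditional mean equals the marginal mean
  g0 <- vd_gmm(1, matrix(mu, 1), array(diag(c(2, 1.5)), c(2, 2, 1)))
  expect_equal(gmm_condition(g0, 2, 5)$means[1, 1], mu[1],
               tolerance = 1e-12)
})

test_that("mixture conditionals match brute-force joint-density slicing", {
  g <- toy_mixture_2d()
  for (v in c(-1.5, 0.4, 2.2)) {
    cond <- gmm_condition(g, 2, v)
    x <- seq(-8, 8, length.out = 400)
    f_cond <- gmm_density(cond, matrix(x, ncol = 1))
    f_joint <- gmm_density(g, cbind(x, v))
    f_slice <- f_joint / (sum(f_joint) * diff(x)[1])
    f_ref <- f_cond / (sum(f_cond) * diff(x)[1])
    expect_lt(max(abs(f_ref - f_slice)), 1e-6)
    expect_equal(sum(cond$weights), 1, tolerance = 1e-12)
  }
})

test_that("conditioning far in the tails never yields NaN weights", {
  g <- toy_mixture_2d()
  cond <- gmm_condition(g, 2, 1e4)
  expect_false(anyNA(cond$weights))
  expect_equal(sum(cond$weights), 1, tolerance = 1e-9)
})

test_that("sampling respects weights, means and near-degenerate spreads", {
  g <- toy_mixture_2d()
  set.seed(6)
  X <- gmm_sample(g, 10000)
  mix_mean <- colSums(g$weights * g$means)
  expect_lt(max(abs(colMeans(X) - mix_mean)), 3 * 3 / sqrt(10000))
  # point-mass-like component
  gp <- vd_gmm(1, matrix(c(2, -1), 1), array(diag(2) * 1e-8, c(2, 2, 1)))
  Xp <- gmm_sample(gp, 100)
  expect_lt(max(abs(t(Xp) - c(2, -1))), 1e-3)
  # zero-weight component is never drawn
  gz <- vd_gmm(c(1, 0), rbind(c(0, 0), c(100, 100)),
               array(rep(diag(2), 2), c(2, 2, 2)))
  Xz <- gmm_sample(gz, 500)
  expect_lt(max(abs(Xz)), 10)
})

test_that("classical EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(9)
  X <- rbind(matrix(rnorm(400, -3), 200, 2), matrix(rnorm(400, 3), 200, 2))
  g <- gmm_fit_em(X, 2, seed = 1)
  mc <- Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  ll_ours <- gmm_loglik(g, X)
  expect_lt(abs(ll_ours - mc$loglik) / abs(mc$loglik), 0.01)
})

test_that("mixtures survive a JSON round trip", {
  g <- toy_mixture_2d()
  path <- tempfile(fileext = ".json")
  gmm_to_json(g, path)
  g2 <- gmm_from_json(path)
  expect_equal(g$weights, g2$weights)
  expect_equal(g$means, g2$means)
  expect_equal(g$covariances, g2$covariances)
})
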