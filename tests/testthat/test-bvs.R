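test_that("residualization centers, scales, and orthogonalizes", {
  set.seed(1)
  Y <- matrix(rnorm(60), 30, 2)
  X <- matrix(rnorm(90), 30, 3)
  rz <- residualize(Y, X)           # intercept only
  expect_equal(colMeans(rz$X), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(rz$X, 2, sd), rep(1, 3), tolerance = 1e-12)
  C <- cbind(rnorm(30), rbinom(30, 1, 0.5))
  rz2 <- residualize(Y, X, C)
  Cfull <- cbind(1, C)
  expect_lt(max(abs(cor(rz2$X, Cfull[, -1]))), 1e-8)
  expect_lt(max(abs(crossprod(Cfull, rz2$Y))), 1e-8)
  # collinear predictor is rejected by name
  Xc <- cbind(X, bad = C[, 1])
  expect_error(residualize(Y, Xc, C), "bad")
})

test_that("the size prior is moment-matched, truncated and normalized", {
  pr <- size_prior(5, 4, 7, 33)
  expect_equal(pr$T, 33)
  k <- 0:33
  pmf <- exp(pr$log_size_pmf)
  expect_equal(sum(k * pmf), 5, tolerance = 0.01 / 5)
  expect_equal(sqrt(sum(k^2 * pmf) - sum(k * pmf)^2), 4, tolerance = 0.01 / 4)
  # per-model prior sums to one over sizes 0..T
  expect_equal(sum(choose(33, k) * exp(log_size_prior(k, pr))), 1,
               tolerance = 1e-10)
  # truncation: a small F cuts the support
  pr2 <- size_prior(2, 1.5, 2, 20)
  expect_equal(pr2$T, 5)
  expect_true(all(is.infinite(log_size_prior(6:20, pr2))))
  expect_equal(sum(choose(20, 0:20) * exp(log_size_prior(0:20, pr2))), 1,
               tolerance = 1e-10)
  # infeasible moment matching falls back to a binomial prior
  expect_warning(pr3 <- size_prior(5, 4, 7, 6), "binomial")
  expect_equal(sum(exp(pr3$log_size_pmf)), 1, tolerance = 1e-10)
})

test_that("the log marginal likelihood matches an independent QR oracle", {
  toy <- make_toy_regression()
  g <- toy$n
  nu <- toy$n - 1
  # empty model: projector term vanishes
  expect_equal(log_marginal(toy$Y, toy$X, integer(0), g, nu),
               -0.5 * nu * determinant(crossprod(toy$Y))$modulus[1],
               ignore_attr = TRUE)
  # permutation invariance of the included set
  expect_equal(log_marginal(toy$Y, toy$X, c(1, 3, 5), g, nu),
               log_marginal(toy$Y, toy$X, c(5, 1, 3), g, nu))
  # every one of the 64 models agrees with the oracle to 1e-8 relative
  for (msk in 0:63) {
    idx <- which(bitwAnd(msk, 2^(0:5)) > 0)
    a <- log_marginal(toy$Y, toy$X, idx, g, nu)
    b <- oracle_log_marginal(toy$Y, toy$X, idx, g, nu)
    expect_equal(a, b, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("exact enumeration normalizes and handles the trivial case", {
  toy <- make_toy_regression()
  pr <- size_prior(2, 1.5, 7, toy$p)
  en <- enumerate_posterior(toy$Y, toy$X, pr)
  expect_equal(sum(en$models$prob), 1, tolerance = 1e-12)
  expect_equal(sum(en$size_posterior), 1, tolerance = 1e-12)
  # p = 1: two models (moment matching degenerates; binomial fallback)
  pr1 <- suppressWarnings(size_prior(0.5, 0.6, 7, 1))
  en1 <- enumerate_posterior(toy$Y, toy$X[, 1, drop = FALSE], pr1)
  expect_equal(nrow(en1$models), 2)
  expect_error(enumerate_posterior(toy$Y, matrix(rnorm(50 * 16), 50, 16),
                                   size_prior(2, 1.5, 7, 16)),
               "p <= 15")
})

test_that("the sampler is deterministic and converges to the enumerated posterior", {
  toy <- make_toy_regression()
  pr <- size_prior(2, 1.5, 7, toy$p)
  cfg <- sampler_config(12000, 4000, 3, seed = 7)
  fit <- run_guess(toy$Y, toy$X, pr, cfg, nu = toy$n - 1)
  fit2 <- run_guess(toy$Y, toy$X, pr, cfg, nu = toy$n - 1)
  expect_identical(fit$models, fit2$models)
  expect_identical(fit$trace, fit2$trace)
  en <- enumerate_posterior(toy$Y, toy$X, pr)
  freq <- setNames(fit$models$count / fit$n_kept, fit$models$model)
  exact <- setNames(en$models$prob, en$models$model)
  expect_lt(tv_distance(freq, exact), 0.05)
  # visited-model log conservation
  expect_equal(sum(fit$models$count), fit$n_kept)
  expect_equal(nrow(fit$trace), cfg$n_sweeps)
})

test_that("sampler agreement with enumeration improves with sweep count", {
  toy <- make_toy_regression(seed = 5)
  pr <- size_prior(2, 1.5, 7, toy$p)
  en <- enumerate_posterior(toy$Y, toy$X, pr)
  exact <- setNames(en$models$prob, en$models$model)
  tv <- vapply(c(800, 20000), function(ns) {
    fit <- run_guess(toy$Y, toy$X, pr,
                     sampler_config(ns, ns / 4, 3, seed = 11),
                     nu = toy$n - 1)
    tv_distance(setNames(fit$models$count / fit$n_kept, fit$models$model),
                exact)
  }, 0)
  expect_lt(tv[2], tv[1])
})

test_that("a dominant shared predictor reaches MPPI near one", {
  set.seed(13)
  n <- 200; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", 1:p)
  # R^2 ~ 0.9 on both traits
  Y <- cbind(3 * X[, 4] + rnorm(n), 3 * X[, 4] + rnorm(n))
  rz <- residualize(Y, X)
  pr <- size_prior(2, 1.5, 7, p)
  fit <- run_guess(rz$Y, rz$X, pr, sampler_config(6000, 2000, 3, seed = 3),
                   nu = n - 1)
  mppi <- compute_mppi(fit)
  expect_gt(mppi["x4"], 0.99)
  expect_true(fit$exchange_rate >= 0.2 && fit$exchange_rate <= 0.8)
})

test_that("null data drive the sampler to the enumerated null posterior", {
  set.seed(17)
  n <- 120; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", 1:p)
  Y <- matrix(rnorm(n * 2), n, 2)
  rz <- residualize(Y, X)
  pr <- size_prior(2, 1.5, 7, p)
  en <- enumerate_posterior(rz$Y, rz$X, pr)
  fit <- run_guess(rz$Y, rz$X, pr, sampler_config(15000, 5000, 3, seed = 19),
                   nu = n - 1)
  expect_lt(tv_distance(
    setNames(fit$models$count / fit$n_kept, fit$models$model),
    setNames(en$models$prob, en$models$model)), 0.05)
  expect_lt(max(abs(compute_mppi(fit) - en$mppi)), 0.05)
})

test_that("oversized proposals are rejected, never raised", {
  toy <- make_toy_regression()
  # T = 1; S below the binomial floor, so the binomial fallback applies
  pr <- suppressWarnings(size_prior(1, 0.9, 1, toy$p))
  fit <- run_guess(toy$Y, toy$X, pr, sampler_config(2000, 500, 2, seed = 1),
                   nu = toy$n - 1)
  expect_true(all(fit$models$size <= pr$T))
})
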