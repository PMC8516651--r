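test_that("sum-to-one projection behaves as documented", {
  expect_equal(constrain_weights(c(0.5, 0.3, 0.2)), c(0.5, 0.3, 0.2))
  b <- constrain_weights(c(2, -1, 0.4))
  expect_lt(abs(sum(b) - 1), 1e-10)
  b2 <- constrain_weights(rnorm(3))
  expect_lt(abs(sum(b2) - 1), 1e-10)
})

test_that("all learners collapse to the empirical logit on constant signal", {
  set.seed(31)
  n <- 120
  obs <- data.table::data.table(
    cluster_id = 1:n, lon = runif(n), lat = runif(n),
    year = 2013, country = 1, weight = 1,
    N = 200L, C = rbinom(n, 200, 0.3))
  obs[, `:=`(mild = 0L, moderate = C, severe = 0L)]
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  Xg <- list(x1 = matrix(0, 4, 1), x2 = matrix(0, 4, 1))
  st <- fit_stackers(obs, X, Xg, stage = 1, seed = 1)
  for (l in colnames(st$pred_obs)) {
    p_hat <- invlogit(st$pred_obs[, l])
    expect_lt(abs(mean(p_hat) - 0.3), 0.02)
    expect_lt(sd(p_hat), 0.05)     # near-constant predictions
  }
})

test_that("lasso recovers a noiseless linear signal out of sample", {
  set.seed(32)
  n <- 150
  x <- runif(n, -2, 2)
  eta <- -0.5 + 0.8 * x
  obs <- data.table::data.table(
    cluster_id = 1:n, lon = runif(n), lat = runif(n), year = 2013,
    country = 1, weight = 1, N = 500L,
    C = round(500 * invlogit(eta)))
  obs[, `:=`(mild = 0L, moderate = C, severe = 0L)]
  X <- cbind(x1 = x, x2 = rnorm(n))
  Xg <- list(x1 = matrix(0, 4, 1), x2 = matrix(0, 4, 1))
  st <- fit_stackers(obs, X, Xg, stage = 1, seed = 2)
  expect_gt(cor(st$pred_obs[, "lasso"], eta), 0.99)
  expect_equal(nrow(st$pred_obs), n)        # one OOS prediction per obs
  expect_equal(ncol(st$pred_obs), 3L)
})

test_that("degenerate response falls back to the pooled logit", {
  n <- 30
  obs <- data.table::data.table(
    cluster_id = 1:n, lon = runif(n), lat = runif(n), year = 2013,
    country = 1, weight = 1, N = 50L, C = 0L, mild = 0L, moderate = 0L,
    severe = 0L)
  X <- cbind(x1 = rnorm(n))
  Xg <- list(x1 = matrix(0, 4, 1))
  expect_warning(st <- fit_stackers(obs, X, Xg, stage = 1, seed = 3),
                 "degenerate")
  expect_equal(length(unique(as.vector(st$pred_obs))), 1L)
})

test_that("stage predictions are strictly out of sample per fold", {
  sc <- default_scenario()
  obs <- default_observations()
  st <- fit_stackers(obs, default_X_raw(), sc$covariates, stage = 1,
                     seed = 44)
  # every observation got a prediction, and folds partition the clusters
  expect_false(anyNA(st$pred_obs))
  expect_equal(length(st$folds), nrow(obs))
  expect_true(all(table(st$folds) > 0))
  one_cluster_folds <- tapply(st$folds, obs$cluster_id, function(f)
    length(unique(f)))
  expect_true(all(one_cluster_folds == 1))  # cluster-stratified
})

test_that("a perfect learner takes the full constrained weight", {
  # learner 1 carries the exact truth; 2 and 3 are noise. The constrained
  # parent weight on learner 1 must converge to 1.
  set.seed(33)
  n <- 400
  eta <- rnorm(n, 0, 1)
  obs <- data.table::data.table(
    cluster_id = 1:n, lon = runif(n), lat = runif(n), year = 2013,
    country = 1, weight = 1, N = 400L,
    C = rbinom(n, 400, invlogit(eta)))
  obs[, `:=`(mild = 0L, moderate = C, severe = 0L)]
  Xst <- cbind(perfect = eta, noise1 = rnorm(n), noise2 = rnorm(n))
  cfg <- model_config(variant = "stackers", draws = 200, theta_draws = 1)
  grid1 <- grid_spec(0, 0, 0.25, 4, 4, 2013)
  fit <- fit_stage(obs, Xst, 1, grid1, cfg, seed = 6)
  B <- anemomap:::stage_beta_draws(fit)
  expect_lt(abs(sum(colMeans(t(B[-1, ]))) - 1), 1e-10)  # exact constraint
  ci <- quantile(B["beta1", ], c(0.025, 0.975))
  expect_gt(mean(B["beta1", ]), 0.9)
  expect_true(ci[1] <= 1 && 1 <= ci[2] + 0.05)
  # noise weights near zero
  expect_lt(abs(mean(B["beta2", ])), 0.1)
})

test_that("ensemble deviance is no worse than the worst single learner", {
  sc <- default_scenario()
  obs <- default_observations()
  st <- fit_stackers(obs, default_X_raw(), sc$covariates, stage = 1,
                     seed = 44)
  dev <- function(eta) {
    p <- invlogit(eta)
    -2 * sum(obs$C * log(p) + (obs$N - obs$C) * log(1 - p))
  }
  single <- apply(st$pred_obs, 2, dev)
  cfg <- model_config(variant = "stackers", draws = 50, theta_draws = 1)
  fit <- fit_stage(obs, st$pred_obs, 1, sc$grid, cfg, seed = 7)
  B <- rowMeans(anemomap:::stage_beta_draws(fit))
  eta_ens <- B["intercept"] + st$pred_obs %*% B[-1]
  expect_lte(dev(eta_ens), max(single))
})
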