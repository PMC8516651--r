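test_that("joint log-posterior matches a dense brute-force oracle", {
  sc <- default_scenario()
  obs <- default_observations()[1:80]
  cfg <- model_config(variant = "raw_gp", knots_x = 4, knots_y = 4,
                      draws = 10, theta_draws = 1)
  X <- default_X_raw()[1:80, ]
  design <- build_stage_design(obs, X, 1, sc$grid, cfg)
  params <- gp_params(omega2 = 0.4, delta = 1.5, rho = 0.6,
                      gamma2_country = 0.08, sigma2_nugget = 0.04)
  set.seed(17)
  f <- c(-0.5, 0.3, -0.2)
  z <- rnorm(16 * 6, 0, 0.3)
  cc <- rnorm(3, 0, 0.2)
  u <- rnorm(design$n_obs, 0, 0.1)
  got <- stage_joint_logpost(design, params, f, z, cc, u)

  # oracle: dense multivariate normal densities + direct binomial loglik
  dmvn <- function(x, Sig) {
    L <- chol(Sig)
    q <- sum(backsolve(L, x, transpose = TRUE)^2)
    -0.5 * q - sum(log(diag(L))) - length(x) / 2 * log(2 * pi)
  }
  eta <- design$offset +
    as.vector(design$V %*% c(f, z, cc)) + u
  p <- plogis(eta)
  ll <- sum(design$w * (design$y * log(p) + (design$n - design$y) * log1p(-p)))
  Sig_z <- dense_spacetime_covariance(design$knots, sc$grid$years, params)
  oracle <- ll +
    dmvn(f, diag(cfg$fixed_sd^2, 3)) +
    dmvn(z, Sig_z) +
    dmvn(cc, diag(params$gamma2_country, 3)) +
    dmvn(u, diag(params$sigma2_nugget, design$n_obs))
  expect_lt(abs(got - oracle), 1e-6)
})

test_that("fixed-effect-only limit recovers a known intercept", {
  set.seed(19)
  n <- 200
  p0 <- 0.3
  obs <- data.table::data.table(
    cluster_id = 1:n, lon = runif(n), lat = runif(n), year = 2013,
    country = 1, weight = 1, N = 300L, C = rbinom(n, 300, p0))
  obs[, `:=`(mild = 0L, moderate = C, severe = 0L)]
  cfg <- model_config(variant = "raw", draws = 400, theta_draws = 1)
  g1 <- grid_spec(0, 0, 0.25, 4, 4, 2013)
  fit <- fit_stage(obs, matrix(numeric(0), n, 0), 1, g1, cfg, seed = 20)
  b0 <- mean(fit$draws_v[1, ])
  expect_lt(abs(b0 - logit(p0)), 0.05)
})

test_that("marginal composition is exact, draw-wise, and sums correctly", {
  out <- compose_marginals(0.4, 0.5, 0.1)
  expect_equal(out$mild, 0.20)
  expect_equal(out$moderate, 0.18)
  expect_equal(out$severe, 0.02)
  expect_equal(compose_marginals(0, 0.7, 0.9),
               list(mild = 0, moderate = 0, severe = 0))
  set.seed(23)
  p1 <- array(runif(60), c(5, 4, 3))
  p2 <- array(runif(60), c(5, 4, 3))
  p3 <- array(runif(60), c(5, 4, 3))
  m <- compose_marginals(p1, p2, p3)
  expect_equal(m$mild + m$moderate + m$severe, p1, tolerance = 1e-12)
  expect_true(all(m$moderate >= -1e-15))
})

test_that("continuation-ratio fit composes stage draws consistently", {
  sc <- default_scenario()
  obs <- default_observations()
  X <- default_X_raw()
  cfg <- model_config(variant = "raw_gp", knots_x = 5, knots_y = 5,
                      draws = 60, theta_draws = 3)
  fit <- fit_continuation_ratio(
    obs, list(X, X, X), sc$grid, cfg, seed = 24,
    stage_grid_X = list(sc$covariates, sc$covariates, sc$covariates),
    country_map = sc$country_map$values)
  expect_length(fit$stages, 3)
  for (s in fit$stages) expect_equal(ncol(s$draws_v), 60)
  d <- fit$draws
  expect_equal(d$mild + d$moderate + d$severe, d$overall, tolerance = 1e-12)
  expect_true(all(d$overall >= 0 & d$overall <= 1))
  expect_true(all(d$severe >= 0))
})

test_that("zero-anemia data yields a flagged stage-1-only fit", {
  set.seed(25)
  n <- 60
  obs <- data.table::data.table(
    cluster_id = 1:n, lon = runif(n), lat = runif(n), year = 2013,
    country = 1, weight = 1, N = 40L, C = 0L, mild = 0L, moderate = 0L,
    severe = 0L)
  g1 <- grid_spec(0, 0, 0.25, 4, 4, 2013)
  cfg <- model_config(variant = "raw", draws = 30, theta_draws = 1)
  w <- capture_warnings(
    fit <- fit_continuation_ratio(obs, rep(list(matrix(rnorm(n))), 3),
                                  g1, cfg, seed = 26))
  expect_match(w, "stage", all = FALSE)
  expect_null(fit$stages[[2]])
  expect_null(fit$stages[[3]])
  expect_false(is.null(fit$stages[[1]]))
})

test_that("hyperparameter intervals are finite and ordered", {
  fit <- default_stage1_fit()
  iv <- stage_hyper_intervals(fit)
  expect_true(all(is.finite(iv$lower) & is.finite(iv$upper)))
  expect_true(all(iv$lower < iv$estimate & iv$estimate < iv$upper))
  expect_true(all(iv$lower > 0 | iv$parameter == "rho"))
})

test_that("grid draws from the standard model track the truth surface", {
  sc <- default_scenario()
  fit <- default_stage1_fit()
  pm <- apply(fit$grid_draws, c(1, 2), mean)
  expect_gt(cor(as.vector(pm), as.vector(sc$stage_truths$overall)), 0.8)
  qs <- apply(fit$grid_draws, c(1, 2), quantile, c(0.025, 0.975))
  cover <- mean(sc$stage_truths$overall >= qs[1, , ] &
                  sc$stage_truths$overall <= qs[2, , ])
  expect_gte(cover, 0.85)   # cell-level truth coverage of the 95% bands
})

test_that("model variants switch the design as configured", {
  sc <- default_scenario()
  obs <- default_observations()[1:50]
  X <- default_X_raw()[1:50, ]
  for (v in c("raw", "raw_gp", "stackers", "stackers_gp")) {
    cfg <- model_config(variant = v, knots_x = 4, knots_y = 4, draws = 5,
                        theta_draws = 1)
    Xv <- if (cfg$constrained) cbind(X, x3 = rowMeans(X)) else X
    des <- build_stage_design(obs, Xv, 1, sc$grid, cfg)
    expect_identical(is.null(des$blocks$z), !cfg$use_gp)
    if (cfg$constrained) expect_equal(des$p_f, ncol(Xv))  # offset absorbed
  }
})
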