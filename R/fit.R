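#' Model configuration for a stage fit
#'
#' Collects the tunable settings of the geostatistical stage model. The
#' `variant` switch selects the sensitivity-analysis model families:
#' `"stackers_gp"` (stacked covariates + GP; the standard model),
#' `"stackers"`, `"raw_gp"`, `"raw"`. Stacker variants impose the sum-to-one
#' constraint on the submodel weights; `*_gp` variants include the
#' Matern x AR1 knot field.
#'
#' Priors on the transformed hyperparameters are weakly informative
#' normals; the range prior defaults to centring log(delta) at 40% of the
#' data extent (set at fit time when `ldelta_mean` is `NA`).
#'
#' @param variant model family (see above).
#' @param knots_x,knots_y knot-lattice dimensions for the low-rank GP.
#' @param draws posterior draws D.
#' @param theta_draws hyperparameter values sampled from the Gaussian
#'   approximation of the hyperparameter posterior among which the D draws
#'   are allocated; 1 conditions everything on the MAP.
#' @param use_country include iid country intercepts.
#' @param fixed_sd prior sd of intercept/coefficients (logit units).
#' @param prior named list of `c(mean, sd)` for `lomega2`, `ldelta`, `arho`,
#'   `lgamma2`, `lsigma2` (log-variance / atanh-correlation scale).
#' @param control optimizer control (`maxit`, `reltol`).
#' @return list of class `model_config`.
#' @export
model_config <- function(variant = c("stackers_gp", "stackers", "raw_gp", "raw"),
                         knots_x = 9, knots_y = 9, draws = 1000,
                         theta_draws = 20, use_country = TRUE, fixed_sd = 5,
                         prior = list(), control = list()) {
  variant <- match.arg(variant)
  def_prior <- list(lomega2 = c(log(0.25), 1.5), ldelta = c(NA, 1),
                    arho = c(1, 1), lgamma2 = c(log(0.05), 1.5),
                    lsigma2 = c(log(0.05), 1.5))
  def_prior[names(prior)] <- prior
  def_control <- list(maxit = 300, reltol = 1e-7, newton_max = 30,
                      newton_tol = 1e-8)
  def_control[names(control)] <- control
  structure(list(variant = variant, knots_x = knots_x, knots_y = knots_y,
                 draws = draws, theta_draws = theta_draws,
                 use_country = use_country, fixed_sd = fixed_sd,
                 prior = def_prior, control = def_control,
                 use_gp = variant %in% c("stackers_gp", "raw_gp"),
                 constrained = variant %in% c("stackers_gp", "stackers")),
            class = "model_config")
}

log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# symmetric central-difference Hessian with fixed absolute steps
fd_hessian <- function(fn, par, h = 0.05) {
  k <- length(par)
  H <- matrix(0, k, k)
  f0 <- fn(par)
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    fp[i] <- fn(par + ei); fm[i] <- fn(par - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ei <- replace(numeric(k), i, h); ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (fn(par + ei + ej) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] +
           fn(par - ei - ej)) / (2 * h^2)
    }
  }
  H
}

# Cholesky with escalating ridge repair; the smooth Matern prior precision is
# ill-conditioned by nature, so a tiny ridge is occasionally needed
safe_chol <- function(M) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  ridge <- 1e-10 * mean(diag(M))
  while (is.null(out) && ridge < 1e2 * mean(diag(M))) {
    out <- tryCatch(chol(M + ridge * diag(nrow(M))), error = function(e) NULL)
    ridge <- ridge * 100
  }
  if (is.null(out)) stop("Cholesky factorization failed beyond ridge repair")
  out
}

#' Assemble the latent design of one continuation-ratio stage
#'
#' Builds the response, weights and sparse latent design for a stage fit:
#' fixed-effect columns (with the sum-to-one stacker reparameterization when
#' `config$constrained`), bilinear knot-field projection columns, and country
#' indicator columns. Rows with a zero denominator are dropped with a
#' message (conditional stages lose clusters with no anemic women).
#'
#' @param obs cluster observations (columns `lon`, `lat`, `year`, `weight`,
#'   `country`, and the count columns `N`, `C`, `mild`, `moderate`, `severe`).
#' @param X_obs covariate matrix (one column per stacker / raw covariate),
#'   rows aligned with `obs`; stacker columns on the logit scale.
#' @param stage 1 (anemic of sampled), 2 (mild of anemic) or
#'   3 (severe of moderate-or-severe).
#' @param grid the [grid_spec()] defining the prediction years.
#' @param config a [model_config()].
#' @return list of design pieces used by [fit_stage()] and the tests.
#' @export
build_stage_design <- function(obs, X_obs, stage, grid, config) {
  stopifnot(stage %in% 1:3, nrow(obs) == nrow(X_obs))
  y <- switch(stage, obs$C, obs$mild, obs$severe)
  n <- switch(stage, obs$N, obs$C, obs$moderate + obs$severe)
  keep <- n > 0
  if (!all(keep))
    message(sprintf("stage %d: dropped %d observation(s) with empty denominator",
                    stage, sum(!keep)))
  if (!any(keep)) stop(sprintf("stage %d has no informative observations", stage))
  obs <- obs[keep, ]; X <- as.matrix(X_obs)[keep, , drop = FALSE]
  y <- y[keep]; n <- n[keep]
  n_obs <- nrow(obs)
  year_idx <- match(obs$year, grid$years)
  if (anyNA(year_idx)) stop("observation year outside grid years")

  if (config$constrained) {
    if (ncol(X) < 2) stop("constrained weights need >= 2 stacker columns")
    offset <- X[, ncol(X)]
    Ffix <- cbind(intercept = 1, X[, -ncol(X), drop = FALSE] - offset)
  } else {
    offset <- rep(0, n_obs)
    Ffix <- cbind(intercept = 1, X)
  }
  p_f <- ncol(Ffix)

  blocks <- list(fixed = seq_len(p_f))
  Vparts <- list(Matrix::Matrix(Ffix, sparse = TRUE))
  knots <- NULL
  if (config$use_gp) {
    knots <- make_knots(grid, config$knots_x, config$knots_y)
    K <- nrow(knots); Tn <- length(grid$years)
    Asp <- bilinear_projector(knots, obs$lon, obs$lat)   # n_obs x K
    trip <- Matrix::summary(Asp)
    Az <- Matrix::sparseMatrix(
      i = trip$i, j = (trip$j - 1L) * Tn + year_idx[trip$i], x = trip$x,
      dims = c(n_obs, K * Tn))
    blocks$z <- p_f + seq_len(K * Tn)
    Vparts <- c(Vparts, list(Az))
  }
  countries <- sort(unique(obs$country))
  if (config$use_country && length(countries) >= 2) {
    Mc <- Matrix::sparseMatrix(i = seq_len(n_obs),
                               j = match(obs$country, countries),
                               x = 1, dims = c(n_obs, length(countries)))
    blocks$country <- max(unlist(blocks)) + seq_along(countries)
    Vparts <- c(Vparts, list(Mc))
  } else {
    countries <- integer()
  }
  V <- do.call(cbind, Vparts)

  if (all(y == 0) || all(y == n))
    warning(sprintf(
      "stage %d response is degenerate (separation); prior regularization engages",
      stage))

  list(stage = stage, y = y, n = n, w = obs$weight, lon = obs$lon,
       lat = obs$lat, year_idx = year_idx, country = obs$country,
       n_obs = n_obs, V = V, offset = offset, blocks = blocks, p_f = p_f,
       knots = knots, countries = countries, grid = grid, config = config,
       extent = max(diff(range(obs$lon)), diff(range(obs$lat)), 1e-6))
}

# active transformed-hyperparameter names for a design
active_theta <- function(design) {
  c(if (design$config$use_gp) c("lomega2", "ldelta", "arho"),
    if (length(design$countries)) "lgamma2", "lsigma2")
}

theta_to_params <- function(theta) {
  gp_params(
    omega2 = if ("lomega2" %in% names(theta)) exp(theta[["lomega2"]]) else 0,
    delta = if ("ldelta" %in% names(theta)) exp(theta[["ldelta"]]) else 1,
    rho = if ("arho" %in% names(theta)) tanh(theta[["arho"]]) else 0,
    gamma2_country = if ("lgamma2" %in% names(theta)) exp(theta[["lgamma2"]]) else 0,
    sigma2_nugget = exp(theta[["lsigma2"]]))
}

# prior mean/sd vectors for the active theta, resolving the data-driven
# default centre of the range prior
theta_prior <- function(design) {
  pr <- design$config$prior
  if (is.na(pr$ldelta[1])) pr$ldelta[1] <- log(0.4 * design$extent)
  act <- active_theta(design)
  list(mean = vapply(act, function(a) pr[[a]][1], 0),
       sd = vapply(act, function(a) pr[[a]][2], 0))
}

# prior precision blocks as a dense matrix plus its log-determinant
build_Qv <- function(design, params) {
  m <- max(unlist(design$blocks))
  Q <- matrix(0, m, m)
  bf <- design$blocks$fixed
  Q[cbind(bf, bf)] <- 1 / design$config$fixed_sd^2
  logdetQ <- -2 * length(bf) * log(design$config$fixed_sd)
  stcov <- NULL
  if (!is.null(design$blocks$z)) {
    stcov <- build_spacetime_covariance(design$knots, design$grid$years, params)
    Q[design$blocks$z, design$blocks$z] <- st_precision(stcov)
    logdetQ <- logdetQ - st_logdet(stcov)
  }
  if (!is.null(design$blocks$country)) {
    bc <- design$blocks$country
    Q[cbind(bc, bc)] <- 1 / params$gamma2_country
    logdetQ <- logdetQ - length(bc) * log(params$gamma2_country)
  }
  logdetQ <- logdetQ - design$n_obs * log(params$sigma2_nugget)
  list(Q = Q, logdetQ = logdetQ, stcov = stcov)
}

# joint log density of data and latent state (up to no constant): binomial
# log-likelihood plus Gaussian log-priors, all constants included
joint_logpost_core <- function(design, params, Qv, v, u) {
  eta <- design$offset + as.vector(design$V %*% v) + u
  ll <- sum(design$w * (design$y * eta - design$n * log1pexp(eta)))
  m <- length(v)
  quad <- as.numeric(crossprod(v, Qv$Q %*% v)) +
    sum(u^2) / params$sigma2_nugget
  ll - 0.5 * quad + 0.5 * Qv$logdetQ -
    0.5 * (m + design$n_obs) * log(2 * pi)
}

#' Joint log-posterior density of one stage at a given latent state
#'
#' Evaluates the full joint log density (binomial likelihood plus all
#' Gaussian priors, constants included) of a stage design at the supplied
#' hyperparameters and latent state, using the Kronecker-structured
#' covariance algebra. Tests compare this against a dense brute-force
#' evaluation.
#'
#' @param design a [build_stage_design()].
#' @param params a [gp_params()].
#' @param f fixed-effect vector, `z` knot-field vector (or NULL), `c_country`
#'   country effects (or NULL), `u` per-observation nuggets.
#' @param z,c_country,u see above.
#' @return scalar log density (excluding the hyperparameter prior).
#' @export
stage_joint_logpost <- function(design, params, f, z = NULL, c_country = NULL,
                                u = rep(0, design$n_obs)) {
  v <- numeric(max(unlist(design$blocks)))
  v[design$blocks$fixed] <- f
  if (!is.null(design$blocks$z)) v[design$blocks$z] <- z
  if (!is.null(design$blocks$country)) v[design$blocks$country] <- c_country
  Qv <- build_Qv(design, params)
  joint_logpost_core(design, params, Qv, v, u)
}

# inner Newton optimization of the latent state given hyperparameters;
# nugget handled by block elimination so the factored system is only
# (fixed + knots + countries) square
newton_mode <- function(design, params, Qv, v0, u0) {
  ctrl <- design$config$control
  V <- design$V; y <- design$y; n <- design$n; w <- design$w
  s2 <- params$sigma2_nugget
  v <- v0; u <- u0
  obj <- function(v, u) {
    eta <- design$offset + as.vector(V %*% v) + u
    sum(w * (y * eta - n * log1pexp(eta))) -
      0.5 * as.numeric(crossprod(v, Qv$Q %*% v)) - 0.5 * sum(u^2) / s2
  }
  f_cur <- obj(v, u)
  cholHs <- NULL; Dvec <- NULL
  for (it in seq_len(ctrl$newton_max)) {
    eta <- design$offset + as.vector(V %*% v) + u
    p <- plogis(eta)
    W <- pmax(w * n * p * (1 - p), 1e-10)
    r <- w * (y - n * p)
    D <- W + 1 / s2
    Wt <- W / (1 + s2 * W)
    grad_v <- as.vector(Matrix::crossprod(V, r)) - as.vector(Qv$Q %*% v)
    grad_u <- r - u / s2
    Hs <- as.matrix(Matrix::crossprod(V * sqrt(Wt))) + Qv$Q
    cholHs <- safe_chol(Hs)
    Dvec <- D
    rhs <- grad_v - as.vector(Matrix::crossprod(V, (W / D) * grad_u))
    dv <- backsolve(cholHs, forwardsolve(t(cholHs), rhs))
    du <- (grad_u - W * as.vector(V %*% dv)) / D
    step <- 1
    repeat {
      f_new <- obj(v + step * dv, u + step * du)
      if (is.finite(f_new) && f_new >= f_cur - 1e-12) break
      step <- step / 2
      if (step < 1e-6) break
    }
    v <- v + step * dv; u <- u + step * du
    improved <- f_new - f_cur
    f_cur <- f_new
    if (abs(improved) < ctrl$newton_tol * (abs(f_cur) + 1)) break
  }
  list(v = v, u = u, cholHs = cholHs, D = Dvec, logpost = f_cur,
       iterations = it)
}

# negative Laplace-approximate log marginal posterior of theta
stage_nlml <- function(theta_vec, design, state) {
  act <- active_theta(design)
  theta <- setNames(theta_vec, act)
  params <- theta_to_params(theta)
  Qv <- build_Qv(design, params)
  mode <- newton_mode(design, params, Qv, state$v, state$u)
  state$v <- mode$v; state$u <- mode$u   # warm start across evaluations
  logdetH <- sum(log(mode$D)) + 2 * sum(log(diag(mode$cholHs)))
  pr <- theta_prior(design)
  lp_theta <- sum(stats::dnorm(theta_vec, pr$mean, pr$sd, log = TRUE))
  m <- length(mode$v)
  lml <- mode$logpost + 0.5 * Qv$logdetQ - 0.5 * logdetH +
    0.5 * (m + design$n_obs) * log(2 * pi) -
    0.5 * (m + design$n_obs) * log(2 * pi)  # latent dims cancel Q vs H
  -(lml + lp_theta)
}

#' Fit one continuation-ratio stage
#'
#' Empirical-Bayes fit of the binomial logit mixed model of one stage:
#' maximum a posteriori estimation of the (transformed) hyperparameters
#' under a Laplace approximation to the latent field, followed by Gaussian
#' posterior draws of all latent quantities. Hyperparameter uncertainty is
#' propagated by allocating the D draws among `theta_draws` hyperparameter
#' values sampled from the Gaussian approximation at the MAP.
#'
#' @inheritParams build_stage_design
#' @param seed integer seed controlling the draw stage.
#' @param grid_data optional list with `X_grid` (list of cell x year
#'   covariate matrices aligned with `X_obs` columns) and `country_map`
#'   (integer vector per cell); when supplied, draws of the prevalence
#'   surface are computed on the full grid.
#' @return object of class `stage_fit`: hyperparameter MAP and intervals,
#'   latent mode, draw matrices, and (optionally) `grid_draws`, an array
#'   `cells x years x D` of prevalence draws.
#' @export
fit_stage <- function(obs, X_obs, stage, grid, config = model_config(),
                      seed = 1, grid_data = NULL) {
  design <- build_stage_design(obs, X_obs, stage, grid, config)
  act <- active_theta(design)
  pr <- theta_prior(design)
  state <- new.env()
  m <- max(unlist(design$blocks))
  state$v <- numeric(m); state$u <- numeric(design$n_obs)
  state$v[design$blocks$fixed[1]] <- logit(
    min(max(sum(design$w * design$y) / sum(design$w * design$n), 1e-3), 1 - 1e-3))

  opt <- if (length(act) == 1) {
    stats::optim(pr$mean, stage_nlml, design = design, state = state,
                 method = "Brent", lower = pr$mean - 12, upper = pr$mean + 12,
                 control = list(maxit = design$config$control$maxit))
  } else {
    stats::optim(pr$mean, stage_nlml, design = design, state = state,
                 method = "Nelder-Mead",
                 control = list(maxit = design$config$control$maxit,
                                reltol = design$config$control$reltol))
  }
  if (opt$convergence != 0 && opt$convergence != 1)
    stop(sprintf("stage %d hyperparameter optimization failed (code %d)",
                 stage, opt$convergence))
  converged <- opt$convergence == 0
  if (!converged)
    warning(sprintf("stage %d: optimizer hit maxit; using best value found", stage))

  # deterministic re-evaluation (fresh Newton from the current mode each
  # call) for the quasi-Newton polish and the finite-difference Hessian;
  # the warm-started objective above is history-dependent by design
  ref_v <- state$v; ref_u <- state$u
  clean_nlml <- function(th) {
    st <- new.env(); st$v <- ref_v; st$u <- ref_u
    stage_nlml(th, design, st)
  }
  opt2 <- tryCatch(
    stats::optim(opt$par, clean_nlml, method = "BFGS",
                 control = list(maxit = 40, reltol = 1e-10, ndeps = rep(1e-4,
                                length(act)))),
    error = function(e) NULL)
  if (!is.null(opt2) && is.finite(opt2$value) && opt2$value <= opt$value) {
    opt <- opt2
    st <- new.env(); st$v <- ref_v; st$u <- ref_u
    stage_nlml(opt$par, design, st)
    ref_v <- st$v; ref_u <- st$u
    state$v <- st$v; state$u <- st$u
  }
  theta_map <- setNames(opt$par, act)

  Htheta <- fd_hessian(clean_nlml, opt$par, h = 0.05)
  # curvature floored at 0.1 (transformed scale): caps the dispersion of the
  # hyperparameter draws in directions the data leave unidentified
  eh <- eigen((Htheta + t(Htheta)) / 2, symmetric = TRUE)
  vals <- pmax(eh$values, 0.1)
  vcov_theta <- eh$vectors %*% ((1 / vals) * t(eh$vectors))
  dimnames(vcov_theta) <- list(act, act)

  params_map <- theta_to_params(theta_map)
  Qv <- build_Qv(design, params_map)
  mode <- newton_mode(design, params_map, Qv, state$v, state$u)

  # ---- posterior draws ----------------------------------------------------
  D <- config$draws
  n_theta <- max(1L, min(config$theta_draws, D))
  set.seed(child_seed(seed, paste0("draws-stage", stage)))
  Ltheta <- tryCatch(chol(vcov_theta), error = function(e) NULL)
  theta_js <- matrix(rep(opt$par, n_theta), ncol = n_theta)
  if (n_theta > 1 && !is.null(Ltheta))
    theta_js <- theta_js + t(Ltheta) %*%
      matrix(rnorm(length(act) * n_theta), length(act))
  alloc <- rep(floor(D / n_theta), n_theta)
  alloc[seq_len(D - sum(alloc))] <- alloc[seq_len(max(D - sum(alloc), 0))] + 1

  draws_v <- matrix(0, m, D)
  draws_u_sd <- numeric(D)       # nugget sd per draw (for predictive checks)
  draws_theta <- matrix(0, length(act), D, dimnames = list(act, NULL))
  col0 <- 0L
  for (j in seq_len(n_theta)) {
    nd <- alloc[j]
    if (nd == 0) next
    th <- setNames(theta_js[, j], act)
    pj <- theta_to_params(th)
    Qj <- build_Qv(design, pj)
    mj <- newton_mode(design, pj, Qj, mode$v, mode$u)
    Zs <- matrix(rnorm(m * nd), m, nd)
    dv <- backsolve(mj$cholHs, Zs)
    draws_v[, col0 + seq_len(nd)] <- mj$v + dv
    draws_theta[, col0 + seq_len(nd)] <- th
    draws_u_sd[col0 + seq_len(nd)] <- sqrt(pj$sigma2_nugget)
    col0 <- col0 + nd
  }

  fit <- structure(list(
    stage = stage, config = config, design = design,
    theta_map = theta_map, params_map = params_map,
    vcov_theta = vcov_theta, converged = converged,
    logml = -opt$value, mode = mode,
    draws_v = draws_v, draws_theta = draws_theta, draws_u_sd = draws_u_sd,
    seed = seed), class = "stage_fit")
  if (!is.null(grid_data))
    fit$grid_draws <- predict_stage_grid(fit, grid_data$X_grid,
                                         grid_data$country_map)
  fit
}

#' @export
print.stage_fit <- function(x, ...) {
  p <- x$params_map
  cat(sprintf("stage_fit (stage %d, %s): %d obs, %d draws\n", x$stage,
              x$config$variant, x$design$n_obs, ncol(x$draws_v)))
  cat(sprintf("  MAP: omega2=%.3g delta=%.3g rho=%.3g gamma2=%.3g sigma2=%.3g\n",
              p$omega2, p$delta, p$rho, p$gamma2_country, p$sigma2_nugget))
  invisible(x)
}

#' Central posterior intervals of the natural-scale hyperparameters
#'
#' Gaussian intervals on the transformed scale (log variance / log range /
#' atanh correlation), mapped back to the natural scale.
#'
#' @param fit a [fit_stage()] result.
#' @param level central interval mass.
#' @return data.frame with `parameter`, `estimate`, `lower`, `upper`.
#' @export
stage_hyper_intervals <- function(fit, level = 0.95) {
  act <- names(fit$theta_map)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit$vcov_theta))
  lo <- fit$theta_map - zq * se
  hi <- fit$theta_map + zq * se
  back <- function(nm, v) {
    if (nm == "arho") tanh(v) else exp(v)
  }
  nat_name <- c(lomega2 = "omega2", ldelta = "delta", arho = "rho",
                lgamma2 = "gamma2_country", lsigma2 = "sigma2_nugget")
  data.frame(parameter = unname(nat_name[act]),
             estimate = mapply(back, act, fit$theta_map),
             lower = mapply(back, act, lo),
             upper = mapply(back, act, hi), row.names = NULL)
}

# fixed-effect rows of the draw matrix, as stacker weights when constrained
# (deriving the last weight from the sum-to-one constraint)
stage_beta_draws <- function(fit) {
  B <- fit$draws_v[fit$design$blocks$fixed, , drop = FALSE]
  rownames(B) <- c("intercept", paste0("beta", seq_len(nrow(B) - 1)))
  if (fit$config$constrained && nrow(B) >= 2) {
    free <- B[-1, , drop = FALSE]
    B <- rbind(B, beta_last = 1 - colSums(free))
    rownames(B)[nrow(B)] <- paste0("beta", nrow(B) - 1)
  }
  B
}

#' Prevalence draws on the full grid
#'
#' @param fit a [fit_stage()] result.
#' @param X_grid list of cell x year covariate matrices (same columns as the
#'   fit's `X_obs`).
#' @param country_map integer country id per cell (or NULL).
#' @return array `cells x years x D` of stage probabilities.
#' @export
predict_stage_grid <- function(fit, X_grid, country_map = NULL) {
  design <- fit$design; grid <- design$grid
  nc <- n_cells(grid); Tn <- length(grid$years); D <- ncol(fit$draws_v)
  fdr <- fit$draws_v[design$blocks$fixed, , drop = FALSE]
  zdr <- if (!is.null(design$blocks$z))
    fit$draws_v[design$blocks$z, , drop = FALSE]
  cdr <- if (!is.null(design$blocks$country))
    fit$draws_v[design$blocks$country, , drop = FALSE]
  Acell <- if (!is.null(design$knots)) {
    cc <- cell_centers(grid)
    bilinear_projector(design$knots, cc$lon, cc$lat)
  }
  out <- array(NA_real_, c(nc, Tn, D))
  for (t in seq_len(Tn)) {
    Xt <- vapply(X_grid, function(M) M[, t], numeric(nc))
    if (design$config$constrained) {
      off <- Xt[, ncol(Xt)]
      Ft <- cbind(1, Xt[, -ncol(Xt), drop = FALSE] - off)
    } else {
      off <- rep(0, nc)
      Ft <- cbind(1, Xt)
    }
    eta <- off + Ft %*% fdr
    if (!is.null(zdr)) {
      idx_t <- (seq_len(nrow(design$knots)) - 1L) * Tn + t
      eta <- eta + as.matrix(Acell %*% zdr[idx_t, , drop = FALSE])
    }
    if (!is.null(cdr)) {
      ci <- match(country_map, design$countries)
      known <- !is.na(ci)
      add <- matrix(0, nc, D)
      add[known, ] <- cdr[ci[known], , drop = FALSE]
      eta <- eta + add
    }
    out[, t, ] <- plogis(eta)
  }
  out
}

#' Posterior predictive draws at point observations
#'
#' Evaluates the fitted linear predictor at arbitrary points (bilinear in
#' space, exact in year), optionally adding a fresh nugget draw per draw —
#' the correct predictive distribution for observed cluster proportions.
#'
#' @param fit a [fit_stage()] result.
#' @param lon,lat,year point coordinates.
#' @param X_new covariate matrix aligned with the fit's `X_obs` columns.
#' @param country integer country ids (or NULL).
#' @param include_nugget add nugget noise (default TRUE).
#' @param seed integer seed for the nugget draws.
#' @return matrix `length(lon) x D` of probability draws.
#' @export
predict_stage_points <- function(fit, lon, lat, year, X_new, country = NULL,
                                 include_nugget = TRUE, seed = 1) {
  design <- fit$design; grid <- design$grid
  np <- length(lon); D <- ncol(fit$draws_v)
  X_new <- as.matrix(X_new)
  year_idx <- match(year, grid$years)
  if (anyNA(year_idx)) stop("prediction year outside grid years")
  if (design$config$constrained) {
    off <- X_new[, ncol(X_new)]
    Fn <- cbind(1, X_new[, -ncol(X_new), drop = FALSE] - off)
  } else {
    off <- rep(0, np)
    Fn <- cbind(1, X_new)
  }
  eta <- off + Fn %*% fit$draws_v[design$blocks$fixed, , drop = FALSE]
  if (!is.null(design$blocks$z)) {
    Tn <- length(grid$years)
    Asp <- bilinear_projector(design$knots, lon, lat)
    trip <- Matrix::summary(Asp)
    Az <- Matrix::sparseMatrix(
      i = trip$i, j = (trip$j - 1L) * Tn + year_idx[trip$i], x = trip$x,
      dims = c(np, nrow(design$knots) * Tn))
    eta <- eta + as.matrix(Az %*% fit$draws_v[design$blocks$z, , drop = FALSE])
  }
  if (!is.null(design$blocks$country) && !is.null(country)) {
    ci <- match(country, design$countries)
    known <- !is.na(ci)
    add <- matrix(0, np, D)
    add[known, ] <- fit$draws_v[design$blocks$country, , drop = FALSE][
      ci[known], , drop = FALSE]
    eta <- eta + add
  }
  if (include_nugget) {
    set.seed(child_seed(seed, "prednugget"))
    eta <- eta + matrix(rnorm(np * D), np, D) *
      matrix(fit$draws_u_sd, np, D, byrow = TRUE)
  }
  plogis(eta)
}

#' Compose conditional stage probabilities into marginal severities
#'
#' Applies the continuation-ratio composition, draw-wise:
#' mild = overall x mild|anemic; severe = overall x (1 - mild|anemic) x
#' severe|mod-or-sev; moderate is the residual, so the three marginals sum
#' to the overall prevalence exactly.
#'
#' @param p_anemic,p_mild_given,p_severe_given numeric arrays of identical
#'   shape, values in \[0, 1\].
#' @return list with `mild`, `moderate`, `severe` of the same shape.
#' @export
compose_marginals <- function(p_anemic, p_mild_given, p_severe_given) {
  stopifnot(all(p_anemic >= 0 & p_anemic <= 1, na.rm = TRUE),
            all(p_mild_given >= 0 & p_mild_given <= 1, na.rm = TRUE),
            all(p_severe_given >= 0 & p_severe_given <= 1, na.rm = TRUE))
  mild <- p_anemic * p_mild_given
  severe <- p_anemic * (1 - p_mild_given) * p_severe_given
  list(mild = mild, moderate = p_anemic - mild - severe, severe = severe)
}

#' Fit the full continuation-ratio model
#'
#' Fits the three sequential stages — overall anemia (`C/N`), mild given
#' anemic (`mild/C`), severe given moderate-or-severe
#' (`severe/(moderate+severe)`) — independently, then composes marginal
#' mild/moderate/severe draws. Draws are paired across stages by draw index.
#'
#' @param obs cluster observations (see [build_stage_design()]); counts must
#'   satisfy mild + moderate + severe = C <= N.
#' @param stage_X list of three covariate matrices (rows aligned with
#'   `obs`), one per stage — typically stacker predictions per stage.
#' @param grid the [grid_spec()].
#' @param config a [model_config()].
#' @param seed integer seed.
#' @param stage_grid_X optional list of three `X_grid` lists for grid draws.
#' @param country_map integer country id per cell (with `stage_grid_X`).
#' @return object of class `cr_fit`: `stages` (three `stage_fit`s) and, when
#'   grid covariates were supplied, `draws`, a list of `cells x years x D`
#'   arrays `overall`, `mild`, `moderate`, `severe`.
#' @export
fit_continuation_ratio <- function(obs, stage_X, grid, config = model_config(),
                                   seed = 1, stage_grid_X = NULL,
                                   country_map = NULL) {
  stopifnot(all(obs$mild + obs$moderate + obs$severe == obs$C),
            all(obs$C <= obs$N))
  stages <- vector("list", 3)
  for (s in 1:3) {
    gd <- if (!is.null(stage_grid_X))
      list(X_grid = stage_grid_X[[s]], country_map = country_map)
    res <- tryCatch(
      fit_stage(obs, stage_X[[s]], s, grid, config,
                seed = child_seed(seed, paste0("stage", s)), grid_data = gd),
      error = function(e) {
        if (s == 1) stop("stage 1 failed: ", conditionMessage(e))
        warning(sprintf("stage %d not fit (%s); stage-1-only output", s,
                        conditionMessage(e)))
        NULL
      })
    stages[s] <- list(res)   # keep NULL placeholders
  }
  out <- structure(list(stages = stages, grid = grid, config = config,
                        seed = seed), class = "cr_fit")
  if (!is.null(stage_grid_X) && !is.null(stages[[1]]$grid_draws)) {
    if (!is.null(stages[[2]]) && !is.null(stages[[3]])) {
      marg <- compose_marginals(stages[[1]]$grid_draws,
                                stages[[2]]$grid_draws,
                                stages[[3]]$grid_draws)
      out$draws <- c(list(overall = stages[[1]]$grid_draws), marg)
    } else {
      out$draws <- list(overall = stages[[1]]$grid_draws)
    }
  }
  out
}

#' @export
print.cr_fit <- function(x, ...) {
  cat("cr_fit: continuation-ratio model,",
      sum(!vapply(x$stages, is.null, TRUE)), "of 3 stages fit\n")
  for (s in x$stages) if (!is.null(s)) print(s)
  invisible(x)
}
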