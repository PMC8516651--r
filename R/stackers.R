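#' Project coefficients onto the sum-to-one plane
#'
#' The parent model combines the three submodel predictions with weights
#' constrained to sum to one. This helper orthogonally projects an
#' unconstrained coefficient vector onto that plane; already-feasible
#' vectors pass through unchanged. Inside [fit_stage()] the constraint is
#' enforced exactly by reparameterization (the last weight is one minus the
#' others), so this function is mainly useful for reporting and tests.
#'
#' @param beta numeric coefficient vector.
#' @return vector with `sum(beta) == 1` to machine tolerance.
#' @export
constrain_weights <- function(beta) {
  beta + (1 - sum(beta)) / length(beta)
}

# empirical logit of a pooled binomial response
pooled_logit <- function(y, n, w) {
  p <- sum(w * y) / sum(w * n)
  logit(min(max(p, 1e-4), 1 - 1e-4))
}

# ---- child learners -------------------------------------------------------
# each learner returns list(predict = function(X) logit-scale predictions)

fit_learner_gam <- function(X, y, n, w) {
  df <- data.frame(X)
  k <- max(3, min(10, nrow(unique(df)) - 1))
  terms <- vapply(names(df), function(v) {
    if (length(unique(df[[v]])) > 10) sprintf("s(%s, k = %d)", v, k) else v
  }, "")
  form <- stats::as.formula(paste("cbind(y, n - y) ~", paste(terms, collapse = "+")))
  df$y <- y; df$n <- n
  fit <- mgcv::gam(form, family = stats::binomial(), data = df, weights = w,
                   method = "REML")
  list(predict = function(Xn)
    as.numeric(stats::predict(fit, newdata = data.frame(Xn), type = "link")))
}

fit_learner_brt <- function(X, y, n, w, seed, nrounds = 150, eta = 0.1,
                            max_depth = 3) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y / n, weight = w * n)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = eta,
                  max_depth = max_depth, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  list(predict = function(Xn)
    as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(Xn)),
                              outputmargin = TRUE)))
}

# lasso on an expanded basis (squares + pairwise products) so the linear
# learner can express mild curvature; glmnet picks lambda by internal CV
fit_learner_lasso <- function(X, y, n, w, seed) {
  expand <- function(M) {
    M <- as.matrix(M)
    out <- cbind(M, M^2)
    if (ncol(M) >= 2) {
      pairs <- utils::combn(ncol(M), 2)
      out <- cbind(out, apply(pairs, 2, function(ij) M[, ij[1]] * M[, ij[2]]))
    }
    out
  }
  Xe <- expand(X)
  set.seed(seed)
  foldid <- sample(rep_len(1:5, nrow(Xe)))
  fit <- glmnet::cv.glmnet(Xe, cbind(n - y, y), family = "binomial",
                           weights = w * n / mean(n), foldid = foldid,
                           alpha = 1, nlambda = 50)
  list(predict = function(Xn)
    as.numeric(stats::predict(fit, expand(Xn), s = "lambda.min",
                              type = "link")))
}

#' Fit the three child learners of the stacked ensemble
#'
#' Trains the submodels — a penalized additive smooth model, gradient
#' boosted regression trees, and lasso-penalized logistic regression — on
#' the stage-specific binomial response, and produces (a) strictly
#' out-of-sample per-observation predictions from `cv_folds`-fold
#' cross-validation stratified by cluster, and (b) full-grid predictions
#' from an all-data refit. All predictions are on the logit scale, ready to
#' enter the parent geostatistical model as covariates.
#'
#' A degenerate response (all zeros or all successes) cannot support any
#' learner; all three then return the (clamped) pooled empirical logit, with
#' a warning.
#'
#' @param obs cluster observations (see [build_stage_design()]).
#' @param X_obs raw covariate matrix, rows aligned with `obs`.
#' @param X_grid list of cell x year matrices of the same covariates.
#' @param stage continuation-ratio stage 1, 2 or 3 (defines the response).
#' @param cv_folds number of stacking folds (default 5).
#' @param seed integer seed (fold assignment, learner randomness).
#' @return list of class `stacker_predictions`: `pred_obs` (matrix
#'   n_obs x 3, out-of-sample logit predictions, NA rows for observations
#'   with empty stage denominator), `pred_grid` (list of three cell x year
#'   matrices), `learners` (all-data fits), `folds` (per-obs fold id).
#' @export
fit_stackers <- function(obs, X_obs, X_grid, stage, cv_folds = 5, seed = 1) {
  stopifnot(stage %in% 1:3, nrow(obs) == nrow(X_obs))
  y_all <- switch(stage, obs$C, obs$mild, obs$severe)
  n_all <- switch(stage, obs$N, obs$C, obs$moderate + obs$severe)
  use <- n_all > 0
  X <- as.matrix(X_obs)
  colnames(X) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  y <- y_all[use]; n <- n_all[use]; w <- obs$weight[use]
  Xu <- X[use, , drop = FALSE]
  if (sum(use) < cv_folds) stop("fewer informative clusters than folds")

  nm <- c("gam", "brt", "lasso")
  grid_X <- function(f) {
    nc <- nrow(X_grid[[1]]); Tn <- ncol(X_grid[[1]])
    Xg <- vapply(X_grid, as.vector, numeric(nc * Tn))
    colnames(Xg) <- colnames(X)
    matrix(f(Xg), nc, Tn)
  }

  degenerate <- all(y == 0) || all(y == n)
  if (degenerate) {
    warning(sprintf("stage %d stacker response is degenerate; %s", stage,
                    "all learners return the pooled empirical logit"))
    const <- pooled_logit(y, n, w)
    pred_obs <- matrix(NA_real_, nrow(obs), 3, dimnames = list(NULL, nm))
    pred_obs[use, ] <- const
    pred_grid <- lapply(1:3, function(i)
      matrix(const, nrow(X_grid[[1]]), ncol(X_grid[[1]])))
    names(pred_grid) <- nm
    return(structure(list(pred_obs = pred_obs, pred_grid = pred_grid,
                          learners = NULL, folds = NULL, stage = stage),
                     class = "stacker_predictions"))
  }

  # cluster-stratified fold assignment
  set.seed(child_seed(seed, paste0("stackfolds", stage)))
  clusters <- unique(obs$cluster_id[use])
  fold_of_cluster <- setNames(sample(rep_len(seq_len(cv_folds),
                                             length(clusters))), clusters)
  folds <- fold_of_cluster[as.character(obs$cluster_id[use])]

  fit_all <- function(Xtr, ytr, ntr, wtr, sd) {
    list(gam = fit_learner_gam(Xtr, ytr, ntr, wtr),
         brt = fit_learner_brt(Xtr, ytr, ntr, wtr, seed = sd),
         lasso = fit_learner_lasso(Xtr, ytr, ntr, wtr, seed = sd))
  }

  pred_use <- matrix(NA_real_, sum(use), 3, dimnames = list(NULL, nm))
  for (f in seq_len(cv_folds)) {
    hold <- folds == f
    if (!any(hold)) next
    tr <- !hold
    lf <- tryCatch(
      fit_all(Xu[tr, , drop = FALSE], y[tr], n[tr], w[tr],
              sd = child_seed(seed, paste0("fold", stage, f))),
      error = function(e) NULL)
    if (is.null(lf)) {
      pred_use[hold, ] <- pooled_logit(y[tr], n[tr], w[tr])
      next
    }
    for (i in seq_along(nm))
      pred_use[hold, i] <- lf[[i]]$predict(Xu[hold, , drop = FALSE])
  }

  learners <- fit_all(Xu, y, n, w, sd = child_seed(seed, paste0("full", stage)))
  pred_grid <- lapply(learners, function(l) grid_X(l$predict))

  pred_obs <- matrix(NA_real_, nrow(obs), 3, dimnames = list(NULL, nm))
  pred_obs[use, ] <- pred_use
  clamp <- function(M) pmin(pmax(M, -8), 8)
  structure(list(pred_obs = clamp(pred_obs),
                 pred_grid = lapply(pred_grid, clamp),
                 learners = learners, folds = folds, stage = stage),
            class = "stacker_predictions")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
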