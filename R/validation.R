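#' Bi-tree spatial partition of weighted points
#'
#' Recursively partitions the points by alternating axis splits at the
#' weighted (lower) median — longitude first, then latitude, and so on —
#' where the weights are the per-point sample sizes. A node is split only
#' while its total sample size exceeds `target_size` and both children
#' would retain at least `min_size`; points exactly at the median go to the
#' lower side. The result is invariant to the input order of the points.
#'
#' @param lon,lat point coordinates.
#' @param size per-point sample sizes (weights).
#' @param target_size stop splitting once a leaf is at or below this total.
#' @param min_size minimum total sample size of any leaf (default 500).
#' @return list of class `spatial_partition`: `leaf` (integer leaf id per
#'   point) and `tree` (nested split description).
#' @export
bitree_partition <- function(lon, lat, size, target_size = 2000,
                             min_size = 500) {
  n <- length(lon)
  stopifnot(length(lat) == n, length(size) == n, all(size >= 0))
  if (sum(size) < min_size)
    stop("total sample size below the minimum leaf size")
  leaf <- integer(n)
  counter <- new.env(); counter$next_id <- 1L
  recurse <- function(idx, depth) {
    tot <- sum(size[idx])
    coord <- if (depth %% 2 == 0) lon[idx] else lat[idx]
    axis <- if (depth %% 2 == 0) "lon" else "lat"
    make_leaf <- function() {
      id <- counter$next_id; counter$next_id <- id + 1L
      leaf[idx] <<- id
      list(leaf = id, n = length(idx), size = tot)
    }
    if (tot <= target_size || tot < 2 * min_size) return(make_leaf())
    if (all(coord == coord[1])) {
      # degenerate along this axis; try the other, else give up
      other <- if (axis == "lon") lat[idx] else lon[idx]
      if (all(other == other[1])) {
        warning("co-located points exceed target size; kept as one leaf")
        return(make_leaf())
      }
      coord <- other
      axis <- if (axis == "lon") "lat" else "lon"
    }
    split_at <- weighted_median(coord, size[idx])
    lower <- coord <= split_at
    if (!any(lower) || all(lower) ||
        sum(size[idx][lower]) < min_size || sum(size[idx][!lower]) < min_size)
      return(make_leaf())
    list(axis = axis, split = split_at,
         lower = recurse(idx[lower], depth + 1),
         upper = recurse(idx[!lower], depth + 1))
  }
  tree <- recurse(seq_len(n), 0)
  structure(list(leaf = leaf, tree = tree,
                 leaf_sizes = tapply(size, leaf, sum)),
            class = "spatial_partition")
}

#' Allocate partition leaves to cross-validation folds
#'
#' Greedy balancing: leaves are sorted by total sample size (largest
#' first, ties broken deterministically under the seed) and each is
#' assigned to the currently lightest fold, so fold totals stay close.
#'
#' @param partition a [bitree_partition()].
#' @param k number of folds (default 5).
#' @param seed integer seed (tie shuffling).
#' @return integer fold id per point.
#' @export
assign_folds <- function(partition, k = 5, seed = 1) {
  sizes <- partition$leaf_sizes
  if (length(sizes) < k)
    stop(sprintf("only %d leaves for %d folds", length(sizes), k))
  set.seed(child_seed(seed, "folds"))
  ord <- sample(seq_along(sizes))            # random tie-break ...
  ord <- ord[order(-sizes[ord])]             # ... then largest first
  fold_of_leaf <- integer(length(sizes))
  totals <- numeric(k)
  for (l in ord) {
    f <- which.min(totals)
    fold_of_leaf[l] <- f
    totals[f] <- totals[f] + sizes[l]
  }
  fold_of_leaf[partition$leaf]
}

#' Predictive-validity metrics at an admin level
#'
#' Aggregates observed cluster proportions and their predictive draws to
#' admin unit-years (weights = effective sample size x survey weight), then
#' scores: mean error (bias), RMSE, coefficient of variation of the
#' predictions (100 x sd / mean), 95% interval coverage of the observed
#' values, and Pearson correlation. Each unit-year with data is one scoring
#' point.
#'
#' @param obs cluster observations with the stage counts.
#' @param pred_draws matrix `nrow(obs) x D` of predictive probability
#'   draws for the same stage (from [predict_stage_points()]).
#' @param unit integer admin unit id per observation.
#' @param stage continuation-ratio stage (defines observed proportion).
#' @param by_year score unit-years (default) rather than pooled units.
#' @param sampling include binomial sampling noise in the predictive draws
#'   (posterior predictive of the observed proportions, the right reference
#'   for coverage of observed data); disable to score the latent prevalence
#'   draws directly.
#' @param seed integer seed for the sampling noise.
#' @return one-row data.frame: `n_units`, `me`, `rmse`, `cov_pct`,
#'   `coverage95`, `correlation`.
#' @export
validation_metrics <- function(obs, pred_draws, unit, stage = 1,
                               by_year = TRUE, sampling = TRUE, seed = 1) {
  y <- switch(stage, obs$C, obs$mild, obs$severe)
  n <- switch(stage, obs$N, obs$C, obs$moderate + obs$severe)
  keep <- n > 0
  if (by_year) unit <- paste(unit, obs$year, sep = ":")
  y <- y[keep]; n <- n[keep]; u <- unit[keep]
  w <- (obs$weight * n)[keep]
  P <- pred_draws[keep, , drop = FALSE]
  if (sampling) {
    set.seed(child_seed(seed, "valsampling"))
    P <- matrix(stats::rbinom(length(P), rep(n, ncol(P)), as.vector(P)),
                nrow(P), ncol(P)) / rep(n, ncol(P))
  }
  units <- sort(unique(u))
  if (length(units) < 2)
    return(data.frame(n_units = length(units), me = NA_real_,
                      rmse = NA_real_, cov_pct = NA_real_,
                      coverage95 = NA_real_, correlation = NA_real_))
  obs_u <- pred_mean <- lo <- hi <- cov_u <- numeric(length(units))
  for (i in seq_along(units)) {
    idx <- u == units[i]
    ww <- w[idx] / sum(w[idx])
    obs_u[i] <- sum(ww * y[idx] / n[idx])
    du <- as.vector(crossprod(P[idx, , drop = FALSE], ww))
    pred_mean[i] <- mean(du)
    qs <- stats::quantile(du, c(0.025, 0.975), names = FALSE)
    lo[i] <- qs[1]; hi[i] <- qs[2]
    cov_u[i] <- 100 * stats::sd(du) / mean(du)
  }
  data.frame(
    n_units = length(units),
    me = mean(obs_u - pred_mean),
    rmse = sqrt(mean((obs_u - pred_mean)^2)),
    cov_pct = mean(cov_u),
    coverage95 = mean(obs_u >= lo & obs_u <= hi),
    correlation = stats::cor(obs_u, pred_mean))
}

#' Spatially stratified cross-validation of a stage model
#'
#' Runs the stage fit `k` times, holding out one spatial fold at a time,
#' and collects strictly out-of-sample predictive draws covering every
#' observation exactly once. Stackers are refit inside every training set
#' so no information leaks from the held-out fold.
#'
#' @param obs cluster observations.
#' @param X_raw raw covariate matrix aligned with `obs`.
#' @param X_grid list of raw covariate cell x year matrices.
#' @param grid the [grid_spec()].
#' @param config a [model_config()].
#' @param folds integer fold id per observation (see [assign_folds()]).
#' @param stage continuation-ratio stage.
#' @param seed integer seed.
#' @return list: `pred_draws` (matrix `nrow(obs) x D`, out-of-sample),
#'   `in_sample_draws` (same shape, from an all-data fit), `folds`,
#'   `fit_all` (the all-data fit).
#' @export
cross_validate <- function(obs, X_raw, X_grid, grid, config, folds,
                           stage = 1, seed = 1) {
  k <- length(unique(folds))
  D <- config$draws
  pred <- matrix(NA_real_, nrow(obs), D)
  use_stack <- config$constrained
  for (f in sort(unique(folds))) {
    hold <- folds == f
    train <- obs[!hold, ]
    Xt <- X_raw[!hold, , drop = FALSE]
    fit_f <- tryCatch({
      if (use_stack) {
        st <- fit_stackers(train, Xt, X_grid, stage,
                           seed = child_seed(seed, paste0("cvstack", f)))
        Xobs_f <- st$pred_obs
        # held-out covariates: all-train learner predictions
        Xho <- vapply(st$learners, function(l)
          pmin(pmax(l$predict(X_raw[hold, , drop = FALSE]), -8), 8),
          numeric(sum(hold)))
        fit <- fit_stage(train, Xobs_f, stage, grid, config,
                         seed = child_seed(seed, paste0("cvfit", f)))
        list(fit = fit, Xho = Xho)
      } else {
        fit <- fit_stage(train, Xt, stage, grid, config,
                         seed = child_seed(seed, paste0("cvfit", f)))
        list(fit = fit, Xho = X_raw[hold, , drop = FALSE])
      }
    }, error = function(e)
      stop(sprintf("fold %d fit failed: %s", f, conditionMessage(e))))
    pred[hold, ] <- predict_stage_points(
      fit_f$fit, obs$lon[hold], obs$lat[hold], obs$year[hold], fit_f$Xho,
      obs$country[hold], include_nugget = TRUE,
      seed = child_seed(seed, paste0("cvpred", f)))
  }
  # in-sample reference fit on everything
  if (use_stack) {
    st_all <- fit_stackers(obs, X_raw, X_grid, stage,
                           seed = child_seed(seed, "allstack"))
    fit_all <- fit_stage(obs, st_all$pred_obs, stage, grid, config,
                         seed = child_seed(seed, "allfit"))
    Xin <- st_all$pred_obs
  } else {
    fit_all <- fit_stage(obs, X_raw, stage, grid, config,
                         seed = child_seed(seed, "allfit"))
    Xin <- X_raw
  }
  insample <- predict_stage_points(fit_all, obs$lon, obs$lat, obs$year, Xin,
                                   obs$country, include_nugget = TRUE,
                                   seed = child_seed(seed, "inpred"))
  list(pred_draws = pred, in_sample_draws = insample, folds = folds,
       fit_all = fit_all)
}
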