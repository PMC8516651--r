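#' Pairwise annualized rates of change on the logit scale
#'
#' The AROC between adjacent years is the difference of logits,
#' `logit(p_t) - logit(p_{t-1})` (negative when prevalence declines), the
#' form consistent with logit-space projection. A literal transcription of
#' the ratio form `logit(p_t / p_{t-1})` is available via
#' `formula = "printed"` for audit; it is not used by any pipeline stage.
#'
#' @param p prevalence series in (0, 1) (boundary values are nudged by
#'   [logit()]'s `eps`); a vector ordered by year, or a matrix
#'   `years x draws`.
#' @param years the (consecutive) years of the series.
#' @param formula `"logit_diff"` (default) or `"printed"`.
#' @return matrix `(length(years) - 1) x draws` of AROCs, rownames the
#'   ending year of each pair.
#' @export
pairwise_aroc <- function(p, years, formula = c("logit_diff", "printed")) {
  formula <- match.arg(formula)
  if (!is.matrix(p)) p <- matrix(p, ncol = 1)
  stopifnot(nrow(p) == length(years))
  if (length(years) > 1 && !all(diff(years) == 1))
    stop("series has missing years")
  lp <- matrix(logit(p), nrow(p), ncol(p))
  out <- switch(formula,
    logit_diff = lp[-1, , drop = FALSE] - lp[-nrow(lp), , drop = FALSE],
    # audit-only transcription; NaN where the prevalence ratio exceeds 1
    printed = matrix(stats::qlogis(p[-1, , drop = FALSE] /
                                     p[-nrow(p), , drop = FALSE]),
                     nrow(p) - 1, ncol(p)))
  rownames(out) <- years[-1]
  out
}

#' Year weights for the weighted AROC
#'
#' \deqn{W_t = (t - t_0)^\gamma / \sum_{t_0+1}^{T} (t - t_0)^\gamma}
#' with `t0` the year before the first pairwise AROC. `aroc_gamma = 0`
#' gives uniform weights; larger values emphasize recent change.
#'
#' @param years the AROC ending years (`t0 + 1 ... T`).
#' @param aroc_gamma weight exponent (>= 0).
#' @param t0 origin year (default `min(years) - 1`).
#' @return weights summing to 1.
#' @export
aroc_weights <- function(years, aroc_gamma = 1, t0 = min(years) - 1) {
  stopifnot(aroc_gamma >= 0, all(years > t0))
  w <- (years - t0)^aroc_gamma
  w / sum(w)
}

#' Weighted average AROC
#'
#' @param pairwise matrix `(n_years - 1) x draws` from [pairwise_aroc()].
#' @param weights vector from [aroc_weights()], aligned with the rows.
#' @return vector of weighted AROCs, one per draw (logit units / year).
#' @export
weighted_aroc <- function(pairwise, weights) {
  stopifnot(nrow(pairwise) == length(weights))
  as.vector(crossprod(pairwise, weights))
}

#' Logit-space projection of prevalence
#'
#' \deqn{Proj = logit^{-1}(logit(p_{last}) + AROC \times k)} — guaranteed
#' to stay in (0, 1).
#'
#' @param p_last prevalence at the last estimation year (vector of draws).
#' @param aroc weighted AROC per draw.
#' @param horizon years ahead `k` (e.g. 7 for 2018 to 2025).
#' @return projected prevalence per draw.
#' @export
project_prevalence <- function(p_last, aroc, horizon) {
  stopifnot(horizon >= 0, length(p_last) == length(aroc) ||
              length(aroc) == 1 || length(p_last) == 1)
  invlogit(logit(p_last) + aroc * horizon)
}

#' Probability of meeting the WHO Global Nutrition Target
#'
#' Fraction of draw pairs in which the projected prevalence achieves the
#' relative reduction target against the baseline-year draw (default: 50%
#' reduction from 2012). Results above 0.95 are conventionally described as
#' high probability of attainment; below 0.05 as low.
#'
#' @param projected draws of projected prevalence.
#' @param baseline draws of baseline-year prevalence (paired by index).
#' @param reduction target relative reduction (default 0.5).
#' @return list with `probability` and `class`
#'   (`low` < 0.05, `high` > 0.95, else `intermediate`).
#' @export
gnt_probability <- function(projected, baseline, reduction = 0.5) {
  stopifnot(length(projected) == length(baseline), reduction >= 0,
            reduction <= 1)
  prob <- mean(projected <= (1 - reduction) * baseline)
  cls <- if (prob > 0.95) "high" else if (prob < 0.05) "low" else "intermediate"
  list(probability = prob, class = cls)
}

#' Trend analysis of admin-level prevalence draws
#'
#' Full trend pipeline for one set of admin units: pairwise AROCs, the
#' weighted average AROC, logit-space projection to each target year, and
#' GNT attainment probabilities against the baseline year — all at the
#' draw level.
#'
#' @param agg draw-level aggregates (data.table with `unit`, `year`,
#'   `draw`, `value`).
#' @param baseline_year GNT baseline (the year the targets were set).
#' @param target_years projection targets.
#' @param aroc_gamma weight exponent of [aroc_weights()].
#' @param reduction target relative reduction.
#' @return data.table with one row per unit: mean AROC, projections
#'   (posterior means) and attainment probability per target year.
#' @export
trend_analysis <- function(agg, baseline_year, target_years,
                           aroc_gamma = 1, reduction = 0.5) {
  dt <- data.table::as.data.table(agg)
  years <- sort(unique(dt$year))
  last_year <- max(years)
  stopifnot(baseline_year %in% years, all(target_years > last_year))
  rows <- list()
  for (u in sort(unique(dt$unit))) {
    sub <- dt[unit == u]
    P <- data.table::dcast(sub, year ~ draw, value.var = "value")
    pm <- as.matrix(P[, -1])[order(P$year), , drop = FALSE]
    pa <- pairwise_aroc(pm, years)
    w <- aroc_weights(years[-1], aroc_gamma)
    ar <- weighted_aroc(pa, w)
    base <- pm[match(baseline_year, years), ]
    row <- data.table::data.table(unit = u, aroc_mean = mean(ar),
                                  aroc_lower = stats::quantile(ar, 0.025, names = FALSE),
                                  aroc_upper = stats::quantile(ar, 0.975, names = FALSE))
    for (ty in target_years) {
      proj <- project_prevalence(pm[nrow(pm), ], ar, ty - last_year)
      g <- gnt_probability(proj, base, reduction)
      row[[paste0("proj_", ty)]] <- mean(proj)
      row[[paste0("prob_gnt_", ty)]] <- g$probability
      row[[paste0("class_gnt_", ty)]] <- g$class
    }
    rows[[length(rows) + 1]] <- row
  }
  data.table::rbindlist(rows)
}
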