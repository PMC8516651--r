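#' Simulate a zero-mean Matern x AR1 space-time field over grid cells
#'
#' Draws a Gaussian field with covariance
#' \eqn{\omega^2\, Matern(\nu, \kappa) \otimes AR1(\rho)} evaluated at the
#' cell centers of `grid`, using the Kronecker factorization of the two
#' kernels (a matrix normal draw), so the dense space-time covariance is
#' never formed.
#'
#' @param grid a [grid_spec()].
#' @param params a [gp_params()]; only `omega2`, `delta`, `nu`, `rho` are used.
#' @param seed integer seed.
#' @return matrix `n_cells x n_years`.
#' @export
simulate_space_time_field <- function(grid, params, seed = 1) {
  stopifnot(abs(params$rho) < 1, params$delta > 0, params$omega2 >= 0)
  set.seed(seed)
  cc <- cell_centers(grid)
  ny <- length(grid$years)
  if (params$omega2 == 0) return(matrix(0, n_cells(grid), ny))
  D <- as.matrix(stats::dist(cbind(cc$lon, cc$lat)))
  S <- matern_correlation(D, params$kappa, params$nu)
  eS <- eigen(S, symmetric = TRUE)
  if (min(eS$values) < -1e-8 * max(eS$values))
    stop("spatial covariance not positive semi-definite (degenerate grid)")
  Ls <- eS$vectors %*% (sqrt(pmax(eS$values, 0)) * t(eS$vectors))
  Tm <- ar1_correlation(ny, params$rho)
  eT <- eigen(Tm, symmetric = TRUE)
  Lt <- eT$vectors %*% (sqrt(pmax(eT$values, 0)) * t(eT$vectors))
  Z <- matrix(stats::rnorm(n_cells(grid) * ny), n_cells(grid), ny)
  sqrt(params$omega2) * (Ls %*% Z %*% t(Lt))
}

#' Rectilinear administrative hierarchy over a grid
#'
#' Partitions the grid into `n_countries` vertical bands (admin 0), each
#' split into `n_admin1` horizontal bands (admin 1), each split into
#' `n_admin2` vertical sub-blocks (admin 2). Returns id rasters per level, a
#' lookup table, and per-admin2 rectangles usable as survey polygons.
#'
#' @param grid a [grid_spec()].
#' @param n_countries,n_admin1,n_admin2 partition counts per level.
#' @return list with `country_map`, `admin1_map`, `admin2_map`
#'   ([grid_raster()]s of integer ids), `lookup` (data.table admin2 ->
#'   admin1 -> country) and `polygons` (named list of admin2 bounding boxes).
#' @export
make_admin_hierarchy <- function(grid, n_countries = 3, n_admin1 = 2,
                                 n_admin2 = 2) {
  cc <- cell_centers(grid)
  cut_int <- function(idx, n, k) pmin(ceiling(idx / (n / k)), k)
  ctry <- cut_int(cc$col, grid$n_cols, n_countries)
  a1_in <- cut_int(cc$row, grid$n_rows, n_admin1)
  # columns within the country band, re-split for admin2
  col_in <- cc$col - ave(cc$col, ctry, FUN = min) + 1
  width <- ave(cc$col, ctry, FUN = function(z) max(z) - min(z) + 1)
  a2_in <- pmin(ceiling(col_in / (width / n_admin2)), n_admin2)
  admin1 <- (ctry - 1) * n_admin1 + a1_in
  admin2 <- (admin1 - 1) * n_admin2 + a2_in
  lookup <- unique(data.table::data.table(admin2 = admin2, admin1 = admin1,
                                          country = ctry))
  data.table::setkey(lookup, admin2)
  half <- grid$cell_size / 2
  polys <- lapply(split(seq_len(nrow(cc)), admin2), function(ix) {
    list(lon_min = min(cc$lon[ix]) - half, lon_max = max(cc$lon[ix]) + half,
         lat_min = min(cc$lat[ix]) - half, lat_max = max(cc$lat[ix]) + half)
  })
  list(country_map = grid_raster(grid, ctry),
       admin1_map = grid_raster(grid, admin1),
       admin2_map = grid_raster(grid, admin2),
       lookup = lookup, polygons = polys)
}

#' Synthetic ground-truth scenario
#'
#' Builds every input the pipeline consumes, with the statistical structure
#' the analysis assumes and known ground truth: smooth covariate surfaces, a
#' log-normal population raster, an elevation gradient, a rectilinear
#' three-level admin hierarchy, and the three continuation-ratio latent truth
#' surfaces (overall anemia; mild given anemic; severe given
#' moderate-or-severe), each built from an intercept, covariate effects, a
#' Matern x AR1 field and country effects on the logit scale.
#'
#' The default dimensions (20 x 20 cells, 6 years, 3 countries, 2
#' covariates) are the package's standard study conditions; all recovery and
#' calibration properties are assessed against them.
#'
#' @param grid a [grid_spec()] (default 20 x 20, years 2013-2018).
#' @param beta0 stage-1 intercept, logit units.
#' @param covariate_effects stage-1 covariate coefficients, logit units.
#' @param gp_params a [gp_params()] describing the stage-1 field, country
#'   and nugget variances.
#' @param stage2_intercept,stage3_intercept intercepts of the conditional
#'   stages (logit units); their fields reuse the stage-1 kernel at half
#'   amplitude.
#' @param n_countries,n_admin1,n_admin2 admin hierarchy shape.
#' @param barren_frac fraction of cells labeled barren (masking exercise).
#' @param seed integer seed; fully determines the scenario.
#' @return object of class `truth_scenario`.
#' @export
make_scenario <- function(grid = grid_spec(30, -10, 0.25, 20, 20, 2013:2018),
                          beta0 = -0.7,
                          covariate_effects = c(0.4, -0.3),
                          gp_params = anemomap::gp_params(
                            omega2 = 0.3, delta = 2, rho = 0.8,
                            gamma2_country = 0.05, sigma2_nugget = 0.03),
                          stage2_intercept = 0,
                          stage3_intercept = -2.3,
                          n_countries = 3, n_admin1 = 2, n_admin2 = 2,
                          barren_frac = 0.03,
                          seed = 1) {
  set.seed(child_seed(seed, "scenario"))
  cc <- cell_centers(grid)
  nc <- n_cells(grid); ny <- length(grid$years)
  ext_x <- diff(range(cc$lon)) + grid$cell_size
  ext_y <- diff(range(cc$lat)) + grid$cell_size
  sx <- (cc$lon - min(cc$lon)) / ext_x
  sy <- (cc$lat - min(cc$lat)) / ext_y

  # two smooth standardized covariates; the second drifts linearly in time
  cov1_base <- sin(2 * pi * sx) + sy
  cov2_base <- cos(2 * pi * sy) - (sx - 0.5)^2 * 4
  scale01 <- function(v) as.numeric(scale(v))
  covariates <- list(
    cov1 = matrix(scale01(cov1_base), nc, ny),
    cov2 = sapply(seq_len(ny), function(t)
      scale01(cov2_base) + 0.05 * (t - (ny + 1) / 2)))
  covariates <- covariates[seq_len(length(covariate_effects))]

  # log-normal population density (persons/km^2, roughly 5-400) times the
  # flat-earth cell area, so masking thresholds behave like real rasters
  dens <- exp(3 + 2 * sy + 0.8 * as.vector(simulate_space_time_field(
    grid_spec(grid$origin_lon, grid$origin_lat, grid$cell_size,
              grid$n_rows, grid$n_cols, grid$years[1]),
    anemomap::gp_params(omega2 = 1, delta = 4, rho = 0),
    seed = child_seed(seed, "pop"))))
  cell_km2 <- (grid$cell_size * 111.32)^2
  population <- grid_raster(grid, dens * cell_km2)
  elevation <- grid_raster(grid, pmax(0, 3000 * sx^2 + 500 * sy))
  admin <- make_admin_hierarchy(grid, n_countries, n_admin1, n_admin2)
  land_class <- grid_raster(grid, as.numeric(
    stats::runif(nc) < barren_frac))  # 1 = barren or sparsely vegetated

  country_effects <- stats::rnorm(n_countries, 0,
                                  sqrt(gp_params$gamma2_country))
  country_effects <- country_effects - mean(country_effects)

  fld <- function(tag, half = FALSE) {
    p <- gp_params
    if (half) p$omega2 <- p$omega2 / 4
    simulate_space_time_field(grid, p, seed = child_seed(seed, tag))
  }
  xb <- matrix(beta0, nc, ny)
  for (j in seq_along(covariate_effects))
    xb <- xb + covariate_effects[j] * covariates[[j]]
  eta1 <- xb + fld("z1") + country_effects[admin$country_map$values]
  eta2 <- stage2_intercept + fld("z2", half = TRUE)
  eta3 <- stage3_intercept + fld("z3", half = TRUE)

  structure(list(
    grid = grid, beta0 = beta0, covariate_effects = covariate_effects,
    gp_params = gp_params, country_effects = country_effects,
    covariates = covariates,
    stage_truths = list(overall = invlogit(eta1),
                        mild_given = invlogit(eta2),
                        severe_given = invlogit(eta3)),
    population = population, elevation = elevation,
    land_class = land_class,
    country_map = admin$country_map, admin = admin,
    seed = seed), class = "truth_scenario")
}

#' @export
print.truth_scenario <- function(x, ...) {
  cat("truth_scenario over "); print(x$grid)
  cat(sprintf("  mean overall anemia truth %.3f; %d countries; seed %d\n",
              mean(x$stage_truths$overall),
              length(x$country_effects), x$seed))
  invisible(x)
}

#' Marginal severity truth surfaces of a scenario
#'
#' @param scenario a [make_scenario()].
#' @return list of cell x year matrices `mild`, `moderate`, `severe`
#'   (marginal prevalences; they sum to the overall truth).
#' @export
scenario_marginals <- function(scenario) {
  with(scenario$stage_truths, {
    mild <- overall * mild_given
    severe <- overall * (1 - mild_given) * severe_given
    list(mild = mild, moderate = overall - mild - severe, severe = severe)
  })
}

# band of adjusted hemoglobin consistent with a category, given thresholds
category_band <- function(category, pregnant, thresholds, headroom = 4) {
  v <- if (pregnant) thresholds$pregnant else thresholds$nonpregnant
  switch(category,
         "severe"     = c(3, v[["severe"]]),
         "moderate"   = c(v[["severe"]], v[["moderate"]]),
         "mild"       = c(v[["moderate"]], v[["overall"]]),
         "non-anemic" = c(v[["overall"]], v[["overall"]] + headroom))
}

#' Simulate woman-level hemoglobin microdata
#'
#' Clusters are placed at grid cell centers drawn with probability
#' proportional to population and cycled through the scenario years. For each
#' woman a severity category is drawn from the local continuation-ratio truth
#' (anemic with the overall truth; mild given anemic; severe given
#' moderate-or-severe), an adjusted hemoglobin value is drawn uniformly
#' inside that category's WHO band for her pregnancy status, and the raw
#' value is then reconstructed by adding back the configured elevation and
#' smoking decrements — so the adjustment + classification pipeline recovers
#' the generating category exactly.
#'
#' @param scenario a [make_scenario()].
#' @param n_clusters total cluster-year locations (>= 1).
#' @param mean_cluster_size expected women per cluster.
#' @param tables an [adjustment_tables()].
#' @param thresholds a [severity_thresholds()].
#' @param prop_pregnant,prop_smoker marginal flag rates.
#' @param seed integer seed.
#'
#' Each cluster-year also receives an independent nugget deviation on the
#' logit of the overall-anemia probability (variance
#' `scenario$gp_params$sigma2_nugget`), emulating unstructured
#' cluster-level noise on top of the smooth truth surface.
#' @return data.table of woman records: `cluster_id`, `lon`, `lat`, `year`,
#'   `country`, `age`, `pregnant`, `smoker`, `elevation`, `raw_hb`,
#'   `category_true`.
#' @export
simulate_cluster_microdata <- function(scenario, n_clusters = 300,
                                       mean_cluster_size = 35,
                                       tables = adjustment_tables(),
                                       thresholds = severity_thresholds(),
                                       prop_pregnant = 0.1, prop_smoker = 0.15,
                                       seed = 1) {
  stopifnot(n_clusters >= 1)
  set.seed(seed)
  grid <- scenario$grid
  pop <- scenario$population$values
  if (sum(pop) <= 0) stop("empty population raster")
  cells <- sample.int(n_cells(grid), n_clusters, replace = TRUE,
                      prob = pop / sum(pop))
  years_idx <- rep_len(seq_along(grid$years), n_clusters)
  cc <- cell_centers(grid)
  sizes <- 1L + stats::rpois(n_clusters, max(mean_cluster_size - 1, 0))
  nugget <- stats::rnorm(n_clusters, 0,
                         sqrt(scenario$gp_params$sigma2_nugget))
  recs <- vector("list", n_clusters)
  tr <- scenario$stage_truths
  for (d in seq_len(n_clusters)) {
    i <- cells[d]; t <- years_idx[d]; n <- sizes[d]
    p1 <- invlogit(logit(tr$overall[i, t]) + nugget[d])
    p2 <- tr$mild_given[i, t]; p3 <- tr$severe_given[i, t]
    anemic <- stats::runif(n) < p1
    mild <- anemic & stats::runif(n) < p2
    severe <- anemic & !mild & stats::runif(n) < p3
    category <- ifelse(!anemic, "non-anemic",
                ifelse(mild, "mild", ifelse(severe, "severe", "moderate")))
    pregnant <- stats::runif(n) < prop_pregnant
    smoker <- stats::runif(n) < prop_smoker
    adj_hb <- vapply(seq_len(n), function(w) {
      b <- category_band(category[w], pregnant[w], thresholds)
      stats::runif(1, b[1], b[2])
    }, numeric(1))
    elev <- scenario$elevation$values[i]
    raw_hb <- adj_hb + elevation_decrement(elev, tables) +
      ifelse(smoker, tables$smoking_decrement, 0)
    recs[[d]] <- data.table::data.table(
      cluster_id = d, lon = cc$lon[i], lat = cc$lat[i],
      year = grid$years[t], country = scenario$country_map$values[i],
      age = sample(15:49, n, replace = TRUE),
      pregnant = pregnant, smoker = smoker, elevation = elev,
      raw_hb = raw_hb, category_true = category)
  }
  data.table::rbindlist(recs)
}

#' Simulate polygon-referenced (areal) survey observations
#'
#' Draws continuation-ratio binomial counts for each polygon from the
#' population-weighted mean truth over the polygon's cells: overall anemic
#' `C ~ Binomial(N, p1)`, then `mild ~ Binomial(C, p2)` and
#' `severe ~ Binomial(C - mild, p3)`. Polygons with zero population are
#' skipped with a warning.
#'
#' @param scenario a [make_scenario()].
#' @param polygons named list of rectangles (default: the scenario's admin2
#'   polygons).
#' @param n_per_polygon women sampled per polygon.
#' @param seed integer seed.
#' @return data.table of areal observations: `polygon_id`, `year`,
#'   `country`, `N`, `C`, `mild`, `moderate`, `severe`.
#' @export
simulate_areal_observations <- function(scenario,
                                        polygons = scenario$admin$polygons,
                                        n_per_polygon = 1000, seed = 1) {
  set.seed(seed)
  grid <- scenario$grid
  cc <- cell_centers(grid)
  tr <- scenario$stage_truths
  out <- vector("list", length(polygons))
  years_idx <- rep_len(seq_along(grid$years), length(polygons))
  for (j in seq_along(polygons)) {
    pg <- polygons[[j]]
    inside <- cc$lon > pg$lon_min & cc$lon < pg$lon_max &
      cc$lat > pg$lat_min & cc$lat < pg$lat_max
    pop <- scenario$population$values[inside]
    if (sum(pop) <= 0) {
      warning(sprintf("polygon %s has zero population; skipped",
                      names(polygons)[j]))
      next
    }
    w <- pop / sum(pop); t <- years_idx[j]
    p1 <- sum(w * tr$overall[inside, t])
    p2 <- sum(w * tr$mild_given[inside, t])
    p3 <- sum(w * tr$severe_given[inside, t])
    C <- stats::rbinom(1, n_per_polygon, p1)
    mild <- stats::rbinom(1, C, p2)
    severe <- stats::rbinom(1, C - mild, p3)
    out[[j]] <- data.table::data.table(
      polygon_id = names(polygons)[j], year = grid$years[t],
      country = scenario$admin$lookup[
        admin2 == as.integer(names(polygons)[j]), country],
      N = n_per_polygon, C = C, mild = mild,
      severe = severe, moderate = C - mild - severe)
  }
  res <- data.table::rbindlist(out)
  if (nrow(res))
    data.table::setcolorder(res, c("polygon_id", "year", "country", "N", "C",
                                   "mild", "moderate", "severe"))
  res
}

#' Generate a synthetic national calibration series
#'
#' Emulates an external country-year estimate series (the role GBD estimates
#' play for the real analysis): population-weighted national truth per
#' indicator, multiplied by a bias factor. With `bias_factor = 1` the series
#' equals the aggregated truth, which makes raking exactness testable. By
#' default the series stops one year short of the scenario's last year so
#' factor extrapolation is exercised.
#'
#' @param scenario a [make_scenario()].
#' @param bias_factor scalar > 0, or data.frame with `country`, `year`,
#'   `bias` for country-year-specific biases.
#' @param years years covered by the series.
#' @return data.table with `country`, `year`, `indicator`
#'   (overall/mild/moderate/severe) and `value`.
#' @export
generate_national_series <- function(scenario, bias_factor = 1,
                                     years = utils::head(scenario$grid$years, -1)) {
  grid <- scenario$grid
  marg <- scenario_marginals(scenario)
  surfaces <- c(list(overall = scenario$stage_truths$overall), marg)
  pop <- scenario$population$values
  ctry <- scenario$country_map$values
  rows <- list()
  for (cn in sort(unique(ctry))) {
    idx <- ctry == cn
    w <- pop[idx] / sum(pop[idx])
    for (yr in years) {
      t <- match(yr, grid$years)
      for (ind in names(surfaces)) {
        b <- if (is.data.frame(bias_factor)) {
          hit <- bias_factor$country == cn & bias_factor$year == yr
          if (any(hit)) bias_factor$bias[hit][1] else 1
        } else bias_factor
        stopifnot(b > 0)
        rows[[length(rows) + 1]] <- data.table::data.table(
          country = cn, year = yr, indicator = ind,
          value = b * sum(w * surfaces[[ind]][idx, t]))
      }
    }
  }
  data.table::rbindlist(rows)
}
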