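#' Pipeline stages
#'
#' The analysis is organized as a linear pipeline over a workspace
#' directory of named artifacts:
#' `simulate -> preprocess -> stack -> fit -> postest -> rake -> project ->
#' validate`. Each stage reads its prerequisites' artifacts, writes its own
#' (`<stage>.rds` plus plain-text tables), and records a manifest with the
#' config hash, seed and input hashes. Re-running an up-to-date stage is a
#' no-op.
#'
#' @name pipeline
NULL

PIPELINE_STAGES <- c("simulate", "preprocess", "stack", "fit", "postest",
                     "rake", "project", "validate")

stage_prereqs <- list(
  simulate = character(), preprocess = "simulate",
  stack = c("simulate", "preprocess"),
  fit = c("simulate", "preprocess", "stack"),
  postest = c("simulate", "fit"),
  rake = c("simulate", "postest"),
  project = c("simulate", "rake"),
  validate = c("simulate", "preprocess"))

ws_path <- function(ws, ...) file.path(ws, ...)
artifact_path <- function(ws, stage) ws_path(ws, paste0(stage, ".rds"))
manifest_path <- function(ws, stage) ws_path(ws, paste0(stage, "_manifest.json"))

read_artifact <- function(ws, stage) {
  p <- artifact_path(ws, stage)
  if (!file.exists(p))
    stop(sprintf("missing artifact of stage '%s'; run it first", stage))
  readRDS(p)
}

write_manifest <- function(ws, stage, config, inputs) {
  manifest <- list(
    stage = stage,
    config_hash = object_hash(unclass(config)),
    seed = config$seed,
    inputs = inputs,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("anemomap")))
  jsonlite::write_json(manifest, manifest_path(ws, stage), auto_unbox = TRUE)
}

manifest_current <- function(ws, stage, config) {
  mp <- manifest_path(ws, stage)
  if (!file.exists(mp) || !file.exists(artifact_path(ws, stage))) return(FALSE)
  man <- jsonlite::read_json(mp)
  if (!identical(man$config_hash, object_hash(unclass(config)))) return(FALSE)
  for (pre in stage_prereqs[[stage]]) {
    h <- tryCatch(object_hash(read_artifact(ws, pre)), error = function(e) NA)
    if (!identical(man$inputs[[pre]], h)) return(FALSE)
  }
  TRUE
}

input_hashes <- function(ws, stage) {
  pres <- stage_prereqs[[stage]]
  setNames(lapply(pres, function(p) object_hash(read_artifact(ws, p))), pres)
}

#' Run one pipeline stage
#'
#' @param stage one of `simulate`, `preprocess`, `stack`, `fit`, `postest`,
#'   `rake`, `project`, `validate`, or `all`.
#' @param config a [default_config()].
#' @param workspace directory of artifacts (created if needed).
#' @param force re-run even when the manifest is current.
#' @return the stage's artifact (invisibly for `all`).
#' @export
run_stage <- function(stage, config = default_config(), workspace,
                      force = FALSE) {
  if (identical(stage, "all")) {
    for (s in PIPELINE_STAGES) run_stage(s, config, workspace, force)
    return(invisible(NULL))
  }
  stopifnot(stage %in% PIPELINE_STAGES)
  dir.create(workspace, recursive = TRUE, showWarnings = FALSE)
  for (pre in stage_prereqs[[stage]])
    if (!file.exists(artifact_path(workspace, pre)))
      stop(sprintf("stage '%s' requires stage '%s' to be run first",
                   stage, pre))
  if (!force && manifest_current(workspace, stage, config)) {
    message(sprintf("stage '%s' is up to date; skipping", stage))
    return(invisible(read_artifact(workspace, stage)))
  }
  message(sprintf("running stage '%s'", stage))
  fn <- get(paste0("stage_", stage), mode = "function")
  out <- fn(config, workspace)
  saveRDS(out, artifact_path(workspace, stage))
  write_manifest(workspace, stage, config, input_hashes(workspace, stage))
  invisible(out)
}

# ---- stage implementations ------------------------------------------------

scenario_from_config <- function(config) {
  sc <- config$scenario
  make_scenario(
    grid = grid_spec(sc$origin_lon, sc$origin_lat, sc$cell_size,
                     sc$n_rows, sc$n_cols, sc$years),
    beta0 = sc$beta0, covariate_effects = unlist(sc$covariate_effects),
    gp_params = gp_params(omega2 = sc$omega2, delta = sc$delta,
                          rho = sc$rho, gamma2_country = sc$gamma2_country,
                          sigma2_nugget = sc$sigma2_nugget),
    n_countries = sc$n_countries, n_admin1 = sc$n_admin1,
    n_admin2 = sc$n_admin2, barren_frac = sc$barren_frac,
    seed = child_seed(config$seed, "scenario"))
}

stage_simulate <- function(config, ws) {
  sc <- config$scenario
  scenario <- scenario_from_config(config)
  tables <- adjustment_tables(smoking_decrement =
                                config$adjustments$smoking_decrement)
  microdata <- simulate_cluster_microdata(
    scenario, n_clusters = sc$n_clusters,
    mean_cluster_size = sc$mean_cluster_size, tables = tables,
    seed = child_seed(config$seed, "microdata"))
  areal <- simulate_areal_observations(
    scenario, n_per_polygon = sc$n_areal_per_polygon,
    seed = child_seed(config$seed, "areal"))
  national <- generate_national_series(scenario,
                                       bias_factor = sc$national_bias)
  data.table::fwrite(microdata, ws_path(ws, "microdata.csv"))
  data.table::fwrite(areal, ws_path(ws, "areal.csv"))
  data.table::fwrite(national, ws_path(ws, "national_series.csv"))
  write_polygons_geojson(scenario$admin$polygons,
                         ws_path(ws, "admin2_polygons.geojson"))
  write_raster_csv(scenario$population, ws_path(ws, "population.csv"))
  write_raster_csv(scenario$elevation, ws_path(ws, "elevation.csv"))
  list(scenario = scenario, microdata = microdata, areal = areal,
       national = national, tables = tables)
}

stage_preprocess <- function(config, ws) {
  sim <- read_artifact(ws, "simulate")
  md <- sim$microdata
  adj <- adjust_hemoglobin(md$raw_hb, md$elevation, md$smoker, sim$tables)
  md$category <- classify_severity(adj, md$pregnant)
  clusters <- collapse_to_clusters(md)
  pseudo <- data.table::rbindlist(lapply(seq_len(nrow(sim$areal)), function(i) {
    ar <- sim$areal[i]
    resample_polygon(ar, sim$scenario$admin$polygons[[ar$polygon_id]],
                     sim$scenario$population,
                     seed = child_seed(config$seed, paste0("resample", i)))
  }))
  obs <- data.table::rbindlist(list(clusters, pseudo), use.names = TRUE)
  data.table::fwrite(obs, ws_path(ws, "cluster_observations.csv"))
  list(obs = obs, clusters = clusters, pseudo = pseudo)
}

# raw covariate values at observation locations
obs_covariates <- function(scenario, obs) {
  ci <- cbind(cells_at(scenario$grid, obs$lon, obs$lat),
              match(obs$year, scenario$grid$years))
  out <- vapply(scenario$covariates, function(M) M[ci], numeric(nrow(obs)))
  colnames(out) <- names(scenario$covariates)
  out
}

stage_stack <- function(config, ws) {
  sim <- read_artifact(ws, "simulate")
  pre <- read_artifact(ws, "preprocess")
  X_raw <- obs_covariates(sim$scenario, pre$obs)
  stacks <- lapply(1:3, function(s)
    fit_stackers(pre$obs, X_raw, sim$scenario$covariates, s,
                 cv_folds = config$stackers$cv_folds,
                 seed = child_seed(config$seed, paste0("stack", s))))
  for (s in 1:3)
    data.table::fwrite(
      data.table::as.data.table(stacks[[s]]$pred_obs),
      ws_path(ws, sprintf("stacker_obs_stage%d.csv", s)))
  list(stacks = stacks, X_raw = X_raw)
}

model_config_from <- function(config) {
  m <- config$model
  model_config(variant = m$variant, knots_x = m$knots_x,
               knots_y = m$knots_y, draws = m$draws,
               theta_draws = m$theta_draws)
}

stage_fit <- function(config, ws) {
  sim <- read_artifact(ws, "simulate")
  pre <- read_artifact(ws, "preprocess")
  stk <- read_artifact(ws, "stack")
  cfg <- model_config_from(config)
  if (cfg$constrained) {
    stage_X <- lapply(stk$stacks, `[[`, "pred_obs")
    stage_grid_X <- lapply(stk$stacks, `[[`, "pred_grid")
  } else {
    stage_X <- lapply(1:3, function(s) stk$X_raw)
    stage_grid_X <- lapply(1:3, function(s) sim$scenario$covariates)
  }
  fit <- fit_continuation_ratio(
    pre$obs, stage_X, sim$scenario$grid, cfg,
    seed = child_seed(config$seed, "fit"),
    stage_grid_X = stage_grid_X,
    country_map = sim$scenario$country_map$values)
  fit
}

# draw-level aggregates of every indicator at one admin level
aggregate_indicators <- function(draws, population, unit_map, mask, years) {
  out <- lapply(names(draws), function(ind) {
    a <- aggregate_to_admin(draws[[ind]], population, unit_map, mask, years)
    a[, indicator := ind]
    a
  })
  data.table::rbindlist(out)
}

stage_postest <- function(config, ws) {
  sim <- read_artifact(ws, "simulate")
  fit <- read_artifact(ws, "fit")
  scen <- sim$scenario
  pe <- config$postest
  msk <- apply_mask(scen$stage_truths$overall, scen$population,
                    scen$land_class, pe$mask_threshold_per_km2)
  levels_maps <- list(admin0 = scen$admin$country_map$values,
                      admin1 = scen$admin$admin1_map$values,
                      admin2 = scen$admin$admin2_map$values)
  aggs <- lapply(levels_maps, function(um)
    aggregate_indicators(fit$draws, scen$population, um, msk$mask,
                         scen$grid$years))
  dw <- disability_weights(pe$dw_mild, pe$dw_moderate, pe$dw_severe)
  wra <- lapply(levels_maps, function(um)
    wra_population(scen$population, um, pe$wra_fraction, msk$mask))
  counts <- lapply(names(aggs), function(lv)
    compute_counts(aggs[[lv]], wra[[lv]]))
  names(counts) <- names(aggs)
  ylds <- lapply(counts, function(ct)
    compute_ylds(ct[indicator %in% c("mild", "moderate", "severe"),
                    .(unit, year, draw, indicator, count)], dw))
  summaries <- data.table::rbindlist(lapply(names(aggs), function(lv) {
    s <- aggs[[lv]][, .(mean = mean(value),
                        lower = stats::quantile(value, 0.025, names = FALSE),
                        upper = stats::quantile(value, 0.975, names = FALSE)),
                    by = .(unit, year, indicator)]
    s[, level := lv]
    s
  }))
  admin2_overall <- summaries[level == "admin2" & indicator == "overall"]
  admin2_overall[, phc_class := classify_public_health_problem(mean)]
  ineq_in <- merge(
    admin2_overall[year == max(year), .(unit, mean)],
    scen$admin$lookup[, .(unit = admin2, country)], by = "unit")
  ineq <- inequality_summaries(merge(ineq_in, wra$admin2, by = "unit"))
  data.table::fwrite(summaries, ws_path(ws, "admin_summaries.csv"))
  data.table::fwrite(ineq$by_country, ws_path(ws, "inequality.csv"))
  list(aggs = aggs, counts = counts, ylds = ylds, summaries = summaries,
       inequality = ineq, mask = msk$mask, wra = wra,
       phc = admin2_overall)
}

stage_rake <- function(config, ws) {
  sim <- read_artifact(ws, "simulate")
  fit <- read_artifact(ws, "fit")
  post <- read_artifact(ws, "postest")
  scen <- sim$scenario
  years <- scen$grid$years
  if (!config$raking$enabled) {
    return(list(draws = fit$draws, aggs = post$aggs, tables = NULL))
  }
  tables <- list()
  for (ind in c("mild", "moderate", "severe")) {
    nat <- post$aggs$admin0[indicator == ind,
                            .(country = unit, year, draw, value)]
    ext <- sim$national[indicator == ind, .(country, year, value)]
    tables[[ind]] <- interpolate_factors(
      compute_raking_factors(nat, ext), years)
  }
  raked <- rake_severity_draws(fit$draws, tables,
                               scen$country_map$values, years)
  levels_maps <- list(admin0 = scen$admin$country_map$values,
                      admin1 = scen$admin$admin1_map$values,
                      admin2 = scen$admin$admin2_map$values)
  aggs <- lapply(levels_maps, function(um)
    aggregate_indicators(raked, scen$population, um, post$mask, years))
  table_out <- data.table::rbindlist(lapply(names(tables), function(ind) {
    t <- tables[[ind]][, .(factor = mean(factor)),
                       by = .(country, year, provenance)]
    t[, indicator := ind]
    t
  }))
  data.table::fwrite(table_out, ws_path(ws, "raking_factors.csv"))
  list(draws = raked, aggs = aggs, tables = tables)
}

stage_project <- function(config, ws) {
  rake <- read_artifact(ws, "rake")
  tr <- config$trends
  res <- list()
  for (lv in c("admin0", "admin2")) {
    agg <- rake$aggs[[lv]][indicator == "overall",
                           .(unit, year, draw, value)]
    t <- trend_analysis(agg, tr$baseline_year, unlist(tr$target_years),
                        tr$aroc_gamma, tr$reduction)
    t[, level := lv]
    res[[lv]] <- t
  }
  out <- data.table::rbindlist(res)
  data.table::fwrite(out, ws_path(ws, "trends.csv"))
  out
}

stage_validate <- function(config, ws) {
  sim <- read_artifact(ws, "simulate")
  pre <- read_artifact(ws, "preprocess")
  scen <- sim$scenario
  v <- config$validation
  obs <- pre$obs
  part <- bitree_partition(obs$lon, obs$lat, obs$weight * obs$N,
                           target_size = v$target_size,
                           min_size = v$min_size)
  folds <- assign_folds(part, v$k, seed = child_seed(config$seed, "folds"))
  X_raw <- obs_covariates(scen, obs)
  cfg <- model_config_from(config)
  cv <- cross_validate(obs, X_raw, scen$covariates, scen$grid, cfg, folds,
                       stage = 1, seed = child_seed(config$seed, "cv"))
  ci <- cells_at(scen$grid, obs$lon, obs$lat)
  unit_maps <- list(admin0 = scen$admin$country_map$values[ci],
                    admin1 = scen$admin$admin1_map$values[ci],
                    admin2 = scen$admin$admin2_map$values[ci])
  report <- data.table::rbindlist(lapply(names(unit_maps), function(lv) {
    oos <- validation_metrics(obs, cv$pred_draws, unit_maps[[lv]])
    ins <- validation_metrics(obs, cv$in_sample_draws, unit_maps[[lv]])
    oos$sample <- "out_of_sample"; ins$sample <- "in_sample"
    oos$level <- lv; ins$level <- lv
    data.table::rbindlist(list(oos, ins))
  }))
  data.table::fwrite(report, ws_path(ws, "validation.csv"))
  list(report = report, folds = folds, partition = part, cv = cv)
}

#' Run the full pipeline
#'
#' @inheritParams run_stage
#' @export
run_pipeline <- function(config = default_config(), workspace,
                         force = FALSE) {
  run_stage("all", config, workspace, force)
  invisible(workspace)
}
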