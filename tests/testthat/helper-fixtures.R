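# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small grid for algebra tests
tiny_grid <- function(years = 2013:2014)
  grid_spec(0, 0, 0.5, 3, 3, years)

# default-condition scenario shared across files
default_scenario <- function()
  fixture("scenario", function() make_scenario(seed = 42))

# collapsed cluster observations from the default scenario
default_observations <- function() {
  fixture("observations", function() {
    sc <- default_scenario()
    md <- simulate_cluster_microdata(sc, n_clusters = 300,
                                     mean_cluster_size = 35, seed = 43)
    adj <- adjust_hemoglobin(md$raw_hb, md$elevation, md$smoker,
                             adjustment_tables())
    md$category <- classify_severity(adj, md$pregnant)
    collapse_to_clusters(md)
  })
}

# raw covariate values at the default observations
default_X_raw <- function() {
  fixture("X_raw", function() {
    sc <- default_scenario()
    obs <- default_observations()
    ci <- cbind(cells_at(sc$grid, obs$lon, obs$lat),
                match(obs$year, sc$grid$years))
    X <- vapply(sc$covariates, function(M) M[ci], numeric(nrow(obs)))
    colnames(X) <- names(sc$covariates)
    X
  })
}

# one standard-model stage-1 fit with grid draws, reused by several files
default_stage1_fit <- function() {
  fixture("stage1_fit", function() {
    sc <- default_scenario()
    obs <- default_observations()
    st <- fit_stackers(obs, default_X_raw(), sc$covariates, stage = 1,
                       seed = 44)
    cfg <- model_config(variant = "stackers_gp", draws = 300,
                        theta_draws = 15)
    fit_stage(obs, st$pred_obs, 1, sc$grid, cfg, seed = 45,
              grid_data = list(X_grid = st$pred_grid,
                               country_map = sc$country_map$values))
  })
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
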