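#' Minimal GeoJSON output for rectilinear polygons
#'
#' Writes a named list of rectangles (as produced by
#' [make_admin_hierarchy()]) as a GeoJSON FeatureCollection of closed
#' polygon rings, with the list names as feature `id` properties. Only the
#' rectilinear geometry this package produces is supported; no geospatial
#' dependency is involved.
#'
#' @param polygons named list of rectangles (`lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`).
#' @param path output file.
#' @param properties optional data.frame of extra per-feature properties
#'   (one row per polygon).
#' @return the path, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path, properties = NULL) {
  features <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    ring <- list(c(p$lon_min, p$lat_min), c(p$lon_max, p$lat_min),
                 c(p$lon_max, p$lat_max), c(p$lon_min, p$lat_max),
                 c(p$lon_min, p$lat_min))
    props <- list(id = names(polygons)[i] %||% as.character(i))
    if (!is.null(properties)) props <- c(props, as.list(properties[i, ]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  out <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    lons <- vapply(ring, function(v) as.numeric(v[[1]]), 0)
    lats <- vapply(ring, function(v) as.numeric(v[[2]]), 0)
    list(lon_min = min(lons), lon_max = max(lons),
         lat_min = min(lats), lat_max = max(lats))
  })
  names(out) <- vapply(gj$features, function(f)
    as.character(f$properties$id), "")
  out
}

#' Default pipeline configuration
#'
#' The full configuration tree of the analysis pipeline, with the
#' package's standard study conditions as defaults. Any subset can be
#' overridden by a YAML file ([read_config()]) or an override list;
#' unknown keys are rejected.
#'
#' @param overrides nested named list of overrides.
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1,
    scenario = list(n_rows = 20, n_cols = 20, cell_size = 0.25,
                    origin_lon = 30, origin_lat = -10,
                    years = 2013:2018, n_countries = 3, n_admin1 = 2,
                    n_admin2 = 2, beta0 = -0.7,
                    covariate_effects = c(0.4, -0.3),
                    omega2 = 0.3, delta = 2, rho = 0.8,
                    gamma2_country = 0.05, sigma2_nugget = 0.03,
                    n_clusters = 300, mean_cluster_size = 35,
                    n_areal_per_polygon = 1000, barren_frac = 0.03,
                    national_bias = 1.15),
    adjustments = list(smoking_decrement = 0.3),
    stackers = list(cv_folds = 5),
    model = list(variant = "stackers_gp", knots_x = 9, knots_y = 9,
                 draws = 250, theta_draws = 20),
    postest = list(mask_threshold_per_km2 = 10, wra_fraction = 0.25,
                   dw_mild = 0.004, dw_moderate = 0.052, dw_severe = 0.149),
    raking = list(enabled = TRUE),
    trends = list(aroc_gamma = 1, baseline_year = 2013,
                  target_years = c(2025, 2030), reduction = 0.5),
    validation = list(k = 5, target_size = 2000, min_size = 500))
  merge_lists <- function(base, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base))
        stop("unknown config key: ", paste0(path, nm))
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]],
                                  paste0(path, nm, "."))
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_lists(cfg, overrides), class = "pipeline_config")
}

#' @rdname default_config
#' @param path YAML file with (a subset of) the configuration tree.
#' @export
read_config <- function(path) {
  default_config(yaml::read_yaml(path))
}

#' @rdname default_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
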