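#' Hemoglobin adjustment tables
#'
#' Elevation and smoking decrements applied to raw hemoglobin before WHO
#' severity classification. Defaults follow the WHO/CDC convention (elevation
#' bins in meters with g/dl decrements rising with altitude; a single smoking
#' decrement); both are configuration data and fully overridable.
#'
#' @param elevation_breaks ascending left edges of elevation bins (m); the
#'   first bin must include 0 m.
#' @param elevation_decrements g/dl decrement per bin (same length), first 0.
#' @param smoking_decrement g/dl decrement for smokers.
#' @return object of class `adjustment_tables`.
#' @export
adjustment_tables <- function(
    elevation_breaks = c(0, 1000, 1500, 2000, 2500, 3000, 3500, 4000, 4500),
    elevation_decrements = c(0, 0.2, 0.5, 0.8, 1.3, 1.9, 2.7, 3.5, 4.5),
    smoking_decrement = 0.3) {
  stopifnot(length(elevation_breaks) == length(elevation_decrements),
            elevation_breaks[1] <= 0 || elevation_breaks[1] == 0,
            elevation_decrements[1] == 0,
            !is.unsorted(elevation_breaks, strictly = TRUE),
            all(elevation_decrements >= 0), smoking_decrement >= 0)
  structure(list(elevation_breaks = elevation_breaks,
                 elevation_decrements = elevation_decrements,
                 smoking_decrement = smoking_decrement),
            class = "adjustment_tables")
}

#' Elevation decrement lookup
#'
#' @param elevation meters (negative values treated as 0).
#' @param tables an [adjustment_tables()].
#' @return g/dl decrement per input.
#' @export
elevation_decrement <- function(elevation, tables) {
  bin <- findInterval(pmax(elevation, 0), tables$elevation_breaks)
  tables$elevation_decrements[bin]
}

#' Adjust raw hemoglobin for smoking and elevation
#'
#' Applies the decrements a measurement still needs, given its provenance:
#' `"raw"` gets both, `"smoking-adjusted"` gets only the elevation decrement,
#' `"elevation-adjusted"` only the smoking decrement, and `"fully-adjusted"`
#' passes through unchanged. An adjustment is never applied twice. Adjusted
#' values that would fall to zero or below are clamped to 0.1 g/dl with a
#' warning.
#'
#' @param raw_hb hemoglobin, g/dl.
#' @param elevation residential elevation, m.
#' @param smoker logical smoking flag.
#' @param tables an [adjustment_tables()].
#' @param provenance one of `"raw"`, `"smoking-adjusted"`,
#'   `"elevation-adjusted"`, `"fully-adjusted"` (scalar or per-record).
#' @return adjusted hemoglobin, g/dl.
#' @export
adjust_hemoglobin <- function(raw_hb, elevation, smoker, tables,
                              provenance = "raw") {
  ok <- c("raw", "smoking-adjusted", "elevation-adjusted", "fully-adjusted")
  if (!all(provenance %in% ok))
    stop("unknown hemoglobin provenance: ",
         paste(setdiff(unique(provenance), ok), collapse = ", "))
  n <- length(raw_hb)
  provenance <- rep_len(provenance, n)
  need_elev <- provenance %in% c("raw", "smoking-adjusted")
  need_smoke <- provenance %in% c("raw", "elevation-adjusted")
  adj <- raw_hb -
    ifelse(need_elev, elevation_decrement(elevation, tables), 0) -
    ifelse(need_smoke & smoker, tables$smoking_decrement, 0)
  low <- adj <= 0
  if (any(low)) {
    warning(sprintf("%d adjusted hemoglobin value(s) <= 0 clamped to 0.1 g/dl",
                    sum(low)))
    adj[low] <- 0.1
  }
  adj
}

#' WHO anemia severity thresholds
#'
#' Severity cutoffs in g/dl by pregnancy status. Bands are closed on the left
#' and open on the right, so for non-pregnant women mild is \[11.0, 12.0),
#' moderate \[8.0, 11.0), severe (0, 8.0), non-anemic >= 12.0; for pregnant
#' women the bands shift down by 1 g/dl.
#'
#' @param nonpregnant,pregnant named vectors with elements `severe`,
#'   `moderate`, `overall`: the left edges of moderate and mild bands and the
#'   overall-anemia cutoff.
#' @return object of class `severity_thresholds`.
#' @export
severity_thresholds <- function(
    nonpregnant = c(severe = 8.0, moderate = 11.0, overall = 12.0),
    pregnant = c(severe = 7.0, moderate = 10.0, overall = 11.0)) {
  check <- function(v) stopifnot(v[["severe"]] < v[["moderate"]],
                                 v[["moderate"]] < v[["overall"]])
  check(nonpregnant); check(pregnant)
  structure(list(nonpregnant = nonpregnant, pregnant = pregnant),
            class = "severity_thresholds")
}

#' Classify adjusted hemoglobin into WHO severity categories
#'
#' @param adjusted_hb adjusted hemoglobin, g/dl (> 0).
#' @param pregnant logical flag (scalar or per-record).
#' @param thresholds a [severity_thresholds()].
#' @return factor with levels `non-anemic`, `mild`, `moderate`, `severe`.
#' @export
classify_severity <- function(adjusted_hb, pregnant,
                              thresholds = severity_thresholds()) {
  stopifnot(all(adjusted_hb > 0))
  n <- length(adjusted_hb)
  pregnant <- rep_len(as.logical(pregnant), n)
  cuts <- function(preg) if (preg) thresholds$pregnant else thresholds$nonpregnant
  lv <- c("non-anemic", "mild", "moderate", "severe")
  out <- character(n)
  for (st in c(TRUE, FALSE)) {
    idx <- pregnant == st
    if (!any(idx)) next
    v <- cuts(st)
    out[idx] <- ifelse(adjusted_hb[idx] >= v[["overall"]], "non-anemic",
                ifelse(adjusted_hb[idx] >= v[["moderate"]], "mild",
                ifelse(adjusted_hb[idx] >= v[["severe"]], "moderate", "severe")))
  }
  factor(out, levels = lv)
}

#' Collapse woman-level records to cluster binomial observations
#'
#' Aggregates classified microdata to per-cluster-year totals: `N` women
#' sampled, overall anemic count `C` and its mild/moderate/severe split.
#' Records outside the 15-49 age range are dropped before collapsing, as are
#' clusters that end up empty. Directly geolocated clusters get weight 1.
#'
#' @param records data.frame with columns `cluster_id`, `lon`, `lat`, `year`,
#'   `country`, `category` (factor from [classify_severity()]), and `age`.
#' @return data.table of cluster observations: `cluster_id`, `lon`, `lat`,
#'   `year`, `country`, `weight`, `N`, `C`, `mild`, `moderate`, `severe`.
#' @export
collapse_to_clusters <- function(records) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0) {
    return(data.table::data.table(
      cluster_id = integer(), lon = numeric(), lat = numeric(),
      year = integer(), country = integer(), weight = numeric(),
      N = integer(), C = integer(), mild = integer(), moderate = integer(),
      severe = integer()))
  }
  n0 <- nrow(dt)
  dt <- dt[age >= 15 & age <= 49]
  if (nrow(dt) < n0)
    message(sprintf("collapse_to_clusters: dropped %d record(s) outside ages 15-49",
                    n0 - nrow(dt)))
  out <- dt[, .(
    lon = lon[1], lat = lat[1], country = country[1], weight = 1,
    N = .N,
    mild = sum(category == "mild"),
    moderate = sum(category == "moderate"),
    severe = sum(category == "severe")
  ), by = .(cluster_id, year)]
  out[, C := mild + moderate + severe]
  data.table::setcolorder(out, c("cluster_id", "lon", "lat", "year", "country",
                                 "weight", "N", "C", "mild", "moderate", "severe"))
  out[]
}

#' Resample an areal observation to population-weighted pseudo-points
#'
#' Polygon-referenced survey records carry no point location; they are
#' resampled to `k` pseudo-points drawn among the polygon's grid cells with
#' probability proportional to cell population. `k` scales with the number of
#' cells covered (`points_per_cells` cells per point, clamped to
#' `[min_points, max_points]`). Each pseudo-point carries the full counts of
#' the areal record and weight `1/k`, so the weights sum to 1 and the
#' weighted effective sample size equals the areal `N`.
#'
#' @param areal one-row data.frame / list with `polygon_id`, `year`,
#'   `country`, `N`, `C`, `mild`, `moderate`, `severe`.
#' @param polygon list with `lon_min`, `lon_max`, `lat_min`, `lat_max`
#'   (rectilinear polygon in grid coordinates).
#' @param population a [grid_raster()] of persons per cell.
#' @param points_per_cells cells per resampled point (default 10).
#' @param min_points,max_points clamp on the number of points.
#' @param seed integer seed.
#' @return data.table of weighted pseudo-cluster observations.
#' @export
resample_polygon <- function(areal, polygon, population, points_per_cells = 10,
                             min_points = 1, max_points = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- population$grid
  cc <- cell_centers(grid)
  inside <- cc$lon > polygon$lon_min & cc$lon < polygon$lon_max &
    cc$lat > polygon$lat_min & cc$lat < polygon$lat_max
  cells <- cc[inside, , drop = FALSE]
  if (nrow(cells) == 0) stop("polygon covers no grid cells")
  pop <- population$values[cells$cell]
  if (all(pop <= 0) || sum(pop) <= 0) stop("polygon has zero total population")
  k <- max(min_points, min(max_points, ceiling(nrow(cells) / points_per_cells)))
  pick <- if (nrow(cells) == 1) rep(1L, k) else
    sample.int(nrow(cells), k, replace = TRUE, prob = pop / sum(pop))
  data.table::data.table(
    cluster_id = paste0("poly", areal$polygon_id, "_p", seq_len(k)),
    lon = cells$lon[pick], lat = cells$lat[pick],
    year = areal$year, country = areal$country,
    weight = 1 / k,
    N = areal$N, C = areal$C, mild = areal$mild,
    moderate = areal$moderate, severe = areal$severe)
}
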