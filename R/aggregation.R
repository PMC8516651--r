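#' Mask uninhabited and barren cells
#'
#' Prediction surfaces are only reported where people live: cells whose
#' population density falls below `threshold_per_km2` persons per 1 x 1-km
#' cell (scaled to the actual cell area) and cells whose land class is
#' barren or sparsely vegetated are set to missing. Masked cells take no
#' part in any downstream aggregation, numerator or denominator.
#'
#' @param surface matrix `cells x years` (or vector per cell).
#' @param population a [grid_raster()], persons per cell.
#' @param land_class a [grid_raster()]; values of 1 mark barren cells.
#' @param threshold_per_km2 masking density threshold (persons per km^2).
#' @param km_per_degree flat-earth degree-to-km conversion used for cell
#'   area at these scales.
#' @return list with `surface` (masked copy) and `mask` (logical per cell,
#'   TRUE = kept).
#' @export
apply_mask <- function(surface, population, land_class = NULL,
                       threshold_per_km2 = 10, km_per_degree = 111.32) {
  grid <- population$grid
  if (!is.null(land_class) &&
      !identical(land_class$grid[c("cell_size", "n_rows", "n_cols")],
                 grid[c("cell_size", "n_rows", "n_cols")]))
    stop("land-class raster not aligned with population raster")
  cell_km2 <- (grid$cell_size * km_per_degree)^2
  keep <- population$values >= threshold_per_km2 * cell_km2
  if (!is.null(land_class)) keep <- keep & land_class$values != 1
  if (is.matrix(surface)) {
    stopifnot(nrow(surface) == n_cells(grid))
    surface[!keep, ] <- NA_real_
  } else {
    stopifnot(length(surface) == n_cells(grid))
    surface[!keep] <- NA_real_
  }
  list(surface = surface, mask = keep)
}

#' Population-weighted aggregation of draw surfaces to admin units
#'
#' Aggregates cell-level prevalence draws to administrative units:
#' unit value = sum(pop_i p_i) / sum(pop_i) over the unit's unmasked cells,
#' applied draw-wise so the unit-level uncertainty is the draw distribution
#' of the weighted mean. Units whose cells are all masked are dropped with
#' a warning.
#'
#' @param draws array `cells x years x D` (or a `cells x years` matrix for
#'   point surfaces).
#' @param population a [grid_raster()].
#' @param unit_map integer unit id per cell (e.g. a `*_map` raster's values).
#' @param mask logical keep-vector per cell (from [apply_mask()]); default
#'   keeps everything.
#' @param years year labels for the output.
#' @return data.table with `unit`, `year`, `draw`, `value`.
#' @export
aggregate_to_admin <- function(draws, population, unit_map, mask = NULL,
                               years = NULL) {
  grid <- population$grid
  nc <- n_cells(grid)
  if (is.matrix(draws)) draws <- array(draws, c(dim(draws), 1L))
  stopifnot(dim(draws)[1] == nc, length(unit_map) == nc)
  keep <- mask %||% rep(TRUE, nc)
  years <- years %||% grid$years
  stopifnot(length(years) == dim(draws)[2])
  units <- sort(unique(unit_map))
  pop <- population$values * keep
  out <- vector("list", length(units))
  for (ui in seq_along(units)) {
    idx <- which(unit_map == units[ui] & keep)
    if (length(idx) == 0 || sum(pop[idx]) <= 0) {
      warning(sprintf("unit %s has no unmasked population; dropped", units[ui]))
      next
    }
    w <- pop[idx] / sum(pop[idx])
    # w' draws[idx, , ]: collapse cells, keep years x D
    vals <- apply(draws[idx, , , drop = FALSE], c(2, 3),
                  function(v) sum(w * v))
    out[[ui]] <- data.table::data.table(
      unit = units[ui],
      year = rep(years, times = dim(draws)[3]),
      draw = rep(seq_len(dim(draws)[3]), each = length(years)),
      value = as.vector(vals))
  }
  data.table::rbindlist(out)
}

#' Summarize draw-level admin aggregates
#'
#' @param agg output of [aggregate_to_admin()].
#' @return data.table with mean and central 95% bounds per unit-year.
#' @export
summarize_admin <- function(agg) {
  agg[, .(mean = mean(value),
          lower = stats::quantile(value, 0.025, names = FALSE),
          upper = stats::quantile(value, 0.975, names = FALSE)),
      by = .(unit, year)]
}

#' Affected-women counts from prevalence draws
#'
#' @param agg draw-level admin aggregates (prevalence).
#' @param wra_population data.table with `unit` and `wra` (women of
#'   reproductive age per unit), or a named vector.
#' @return copy of `agg` with a `count` column (prevalence x WRA).
#' @export
compute_counts <- function(agg, wra_population) {
  if (!is.data.frame(wra_population))
    wra_population <- data.table::data.table(
      unit = as.integer(names(wra_population)), wra = as.numeric(wra_population))
  out <- merge(agg, wra_population, by = "unit")
  out[, count := value * wra]
  out[]
}

#' Women-of-reproductive-age population per admin unit
#'
#' The package carries no age-sex structure; WRA counts default to a
#' configured fraction of the total population raster.
#'
#' @param population a [grid_raster()].
#' @param unit_map integer unit id per cell.
#' @param wra_fraction fraction of total population that is WRA.
#' @param mask logical keep-vector (masked cells contribute no population).
#' @return data.table with `unit`, `wra`.
#' @export
wra_population <- function(population, unit_map, wra_fraction = 0.25,
                           mask = NULL) {
  keep <- mask %||% rep(TRUE, length(unit_map))
  dt <- data.table::data.table(unit = unit_map,
                               pop = population$values * keep)
  out <- dt[, .(wra = wra_fraction * sum(pop)), by = unit]
  data.table::setkey(out, unit)
  out[]
}

#' Disability weights for anemia severity
#'
#' Severity-specific disability weights (dimensionless, GBD convention);
#' configuration data, not estimates.
#'
#' @param mild,moderate,severe weights in \[0, 1\], strictly increasing.
#' @return named list.
#' @export
disability_weights <- function(mild = 0.004, moderate = 0.052,
                               severe = 0.149) {
  stopifnot(mild < moderate, moderate < severe,
            mild >= 0, severe <= 1)
  list(mild = mild, moderate = moderate, severe = severe)
}

#' Years lived with disability from severity counts
#'
#' YLD per severity = affected count x disability weight; total anemia YLD
#' is the sum over severities. Linear in both counts and weights.
#'
#' @param counts data.table with `unit`, `year`, `draw`, `indicator`
#'   (mild/moderate/severe), `count`.
#' @param dw a [disability_weights()].
#' @return data.table with per-severity and `total` YLD rows (`indicator`
#'   column; `yld` values).
#' @export
compute_ylds <- function(counts, dw = disability_weights()) {
  stopifnot(all(counts$indicator %in% c("mild", "moderate", "severe")))
  out <- data.table::copy(data.table::as.data.table(counts))
  out[, yld := count * unlist(dw)[indicator]]
  tot <- out[, .(indicator = "total", yld = sum(yld)),
             by = .(unit, year, draw)]
  data.table::rbindlist(list(out[, .(unit, year, draw, indicator, yld)], tot),
                        use.names = TRUE)
}

#' WHO public-health-problem classification of anemia prevalence
#'
#' Bands: none < 5%, low 5-19.9%, medium 20-39.9%, high >= 40%.
#'
#' @param prevalence values in \[0, 1\].
#' @return factor with levels `none`, `low`, `medium`, `high`.
#' @export
classify_public_health_problem <- function(prevalence) {
  stopifnot(all(prevalence >= 0 & prevalence <= 1, na.rm = TRUE))
  cut(prevalence, breaks = c(-Inf, 0.05, 0.20, 0.40, Inf),
      labels = c("none", "low", "medium", "high"), right = FALSE)
}

#' Within-country inequality summaries of subnational estimates
#'
#' Absolute range, max/min fold difference and per-unit ratios to the
#' population-weighted national mean, from unit-level prevalence means.
#'
#' @param unit_means data.table with `unit`, `country`, `mean` (prevalence)
#'   and `wra` (population weight of the unit).
#' @return list with `by_country` (range, fold difference) and `ratios`
#'   (per-unit ratio to national mean).
#' @export
inequality_summaries <- function(unit_means) {
  dt <- data.table::as.data.table(unit_means)
  stopifnot(all(c("unit", "country", "mean", "wra") %in% names(dt)))
  nat <- dt[, .(national = sum(mean * wra) / sum(wra)), by = country]
  dt <- merge(dt, nat, by = "country")
  dt[, ratio := mean / national]
  by_country <- dt[, .(
    n_units = .N,
    min = min(mean), max = max(mean),
    fold = if (min(mean) > 0) max(mean) / min(mean) else NA_real_,
    national = national[1]), by = country]
  if (any(by_country$n_units < 2))
    warning("country with < 2 subnational units; inequality not meaningful")
  list(by_country = by_country[],
       ratios = dt[, .(country, unit, mean, national, ratio)])
}
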