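#' Raking factors from national aggregates and an external series
#'
#' The raking factor of a country-year is the ratio of the external
#' (national calibration) estimate to the model's population-weighted
#' national aggregate, computed per posterior draw against that draw's
#' aggregate. Factors are only produced where both sides exist.
#'
#' @param national_draws data.table with `country`, `year`, `draw`, `value`
#'   (model aggregates; [aggregate_to_admin()] output with `unit` renamed
#'   to `country`).
#' @param external data.table with `country`, `year`, `value`.
#' @return data.table of class `raking_table`: `country`, `year`, `draw`,
#'   `factor`, `provenance = "computed"`.
#' @export
compute_raking_factors <- function(national_draws, external) {
  nd <- data.table::as.data.table(national_draws)
  ex <- data.table::as.data.table(external)
  if (any(ex[, .N, by = country]$N < 2))
    stop("external series must cover >= 2 years per country")
  m <- merge(nd, ex[, .(country, year, external = value)],
             by = c("country", "year"))
  if (any(m$value <= 0))
    stop("zero national aggregate; raking factor undefined")
  out <- m[, .(country, year, draw, factor = external / value,
               provenance = "computed")]
  data.table::setattr(out, "class",
                      c("raking_table", class(out)))
  out[]
}

#' Complete a raking table over target years
#'
#' Linearly interpolates factors between available years within each
#' country (per draw); years outside the available span carry the nearest
#' factor forward or backward and are flagged `extrapolated`. A country
#' with a single available year gets a constant factor with a warning.
#'
#' @param table a [compute_raking_factors()] result.
#' @param target_years years the completed table must cover.
#' @return completed raking table with `provenance` in
#'   `computed | interpolated | extrapolated`.
#' @export
interpolate_factors <- function(table, target_years) {
  dt <- data.table::as.data.table(table)
  fill_one <- function(sub) {
    sub <- sub[order(year)]
    if (nrow(sub) == 1) {
      warning(sprintf("country %s: single raking year; constant factor",
                      sub$country[1]))
      return(data.table::data.table(
        year = target_years, factor = sub$factor,
        provenance = ifelse(target_years == sub$year, "computed",
                            "extrapolated")))
    }
    ap <- stats::approx(sub$year, sub$factor, xout = target_years,
                        rule = 2)  # rule 2: carry nearest value outward
    prov <- ifelse(target_years %in% sub$year, "computed",
                   ifelse(target_years < min(sub$year) |
                            target_years > max(sub$year),
                          "extrapolated", "interpolated"))
    data.table::data.table(year = ap$x, factor = ap$y, provenance = prov)
  }
  out <- dt[, fill_one(.SD), by = .(country, draw),
            .SDcols = c("country", "year", "factor")]
  data.table::setattr(out, "class", c("raking_table", class(out)))
  out[]
}

#' Apply raking factors to prevalence draws on the grid
#'
#' Multiplies every grid cell of a country-year by that country-year's
#' (draw-specific) factor. Values pushed above 1 are clipped with a
#' message; within-country cell ratios and rank order are preserved
#' whenever no clipping occurs.
#'
#' @param draws array `cells x years x D`.
#' @param table completed raking table covering all years and draws.
#' @param country_map integer country id per cell.
#' @param years year labels of the draws array.
#' @return array of the same shape, raked (and clipped to \[0, 1\]).
#' @export
apply_raking <- function(draws, table, country_map, years) {
  dt <- data.table::as.data.table(table)
  stopifnot(dim(draws)[2] == length(years))
  D <- dim(draws)[3]
  clipped <- 0L
  for (cn in sort(unique(country_map))) {
    cells <- which(country_map == cn)
    sub <- dt[country == cn]
    if (nrow(sub) == 0) stop(sprintf("no raking factors for country %s", cn))
    fac <- matrix(NA_real_, length(years), D)
    fac[cbind(match(sub$year, years), sub$draw)] <- sub$factor
    if (anyNA(fac)) stop("raking table incomplete for country ", cn)
    for (t in seq_along(years)) {
      block <- draws[cells, t, ] * matrix(fac[t, ], length(cells), D,
                                          byrow = TRUE)
      over <- block > 1
      clipped <- clipped + sum(over, na.rm = TRUE)
      block[over] <- 1
      draws[cells, t, ] <- block
    }
  }
  if (clipped > 0)
    message(sprintf("apply_raking: clipped %d cell-draw value(s) at 1", clipped))
  draws
}

#' Rake the severity draw surfaces to an external series
#'
#' Applies [apply_raking()] to the three marginal severities independently
#' (each against its own external series), then recomputes overall anemia
#' as their sum so the severity identity stays intact.
#'
#' @param draw_list list with arrays `overall`, `mild`, `moderate`,
#'   `severe` (`cells x years x D`).
#' @param tables named list of completed raking tables for `mild`,
#'   `moderate`, `severe`.
#' @param country_map integer country id per cell.
#' @param years year labels.
#' @return draw list of the same shape, raked.
#' @export
rake_severity_draws <- function(draw_list, tables, country_map, years) {
  out <- list()
  for (ind in c("mild", "moderate", "severe"))
    out[[ind]] <- apply_raking(draw_list[[ind]], tables[[ind]],
                               country_map, years)
  total <- out$mild + out$moderate + out$severe
  if (any(total > 1)) {
    message("rake_severity_draws: severity sum exceeded 1; rescaled")
    sc <- pmin(1 / total, 1)
    for (ind in c("mild", "moderate", "severe")) out[[ind]] <- out[[ind]] * sc
    total <- pmin(total, 1)
  }
  out$overall <- total
  out[c("overall", "mild", "moderate", "severe")]
}
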