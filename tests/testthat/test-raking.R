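make_agg <- function(values, country = 1L, years = 2013:2014, D = 2) {
  data.table::CJ(country = country, year = years, draw = seq_len(D))[
    , value := rep(values, length.out = .N)][]
}

test_that("raking factors are the external / model ratio, per draw", {
  nd <- make_agg(0.25)
  ex <- data.table::data.table(country = 1L, year = 2013:2014,
                               value = c(0.30, 0.25))
  rt <- compute_raking_factors(nd, ex)
  expect_equal(rt[year == 2013, factor], rep(1.2, 2))
  expect_equal(rt[year == 2014, factor], rep(1.0, 2))
  expect_true(all(rt$factor > 0))
  # draw-specific aggregates give draw-specific factors
  nd2 <- make_agg(c(0.2, 0.25))
  rt2 <- compute_raking_factors(nd2, ex)
  expect_equal(sort(rt2[year == 2013, factor]), c(1.2, 1.5))
  # zero aggregate is an error
  expect_error(compute_raking_factors(make_agg(0), ex), "zero")
  # short external series rejected
  expect_error(compute_raking_factors(nd, ex[1]), ">= 2 years")
})

test_that("factor interpolation is linear inside and flat outside", {
  rt <- data.table::data.table(country = 1L, year = c(2000L, 2002L),
                               draw = 1L, factor = c(1.0, 2.0),
                               provenance = "computed")
  out <- interpolate_factors(rt, 2000:2003)
  expect_equal(out[year == 2001, factor], 1.5)
  expect_equal(out[year == 2001, provenance], "interpolated")
  expect_equal(out[year == 2000, factor], 1.0)       # exact at computed year
  expect_equal(out[year == 2000, provenance], "computed")
  expect_equal(out[year == 2003, factor], 2.0)       # carried forward
  expect_equal(out[year == 2003, provenance], "extrapolated")
  # single-year series: constant with warning
  expect_warning(one <- interpolate_factors(rt[1], 2000:2001), "single")
  expect_true(all(one$factor == 1.0))
})

test_that("raking is exact at computed years and preserves structure", {
  sc <- default_scenario()
  years <- sc$grid$years
  set.seed(51)
  D <- 4
  nc <- n_cells(sc$grid)
  draws <- array(runif(nc * length(years) * D, 0.05, 0.4),
                 c(nc, length(years), D))
  ctry <- sc$country_map$values
  nat <- aggregate_to_admin(draws, sc$population, ctry)
  ext <- nat[, .(value = 1.1 * mean(value)), by = .(country = unit, year)]
  rt <- interpolate_factors(
    compute_raking_factors(nat[, .(country = unit, year, draw, value)], ext),
    years)
  raked <- apply_raking(draws, rt, ctry, years)
  nat2 <- aggregate_to_admin(raked, sc$population, ctry)
  cmp <- merge(nat2[, .(country = unit, year, draw, value)], ext,
               by = c("country", "year"), suffixes = c("", ".ext"))
  expect_lt(max(abs(cmp$value - cmp$value.ext) / cmp$value.ext), 1e-9)
  # factor 1 leaves draws unchanged
  rt1 <- data.table::copy(rt)[, factor := 1]
  expect_equal(apply_raking(draws, rt1, ctry, years), draws)
  # within-country cell ratios and rank order preserved (no clipping)
  cells <- which(ctry == 1)[1:5]
  r0 <- draws[cells, 1, 1] / draws[cells[1], 1, 1]
  r1 <- raked[cells, 1, 1] / raked[cells[1], 1, 1]
  expect_equal(r0, r1, tolerance = 1e-12)
  expect_equal(order(draws[cells, 1, 1]), order(raked[cells, 1, 1]))
})

test_that("values raked above one are clipped and logged", {
  g <- grid_spec(0, 0, 1, 1, 2, 2013:2014)
  draws <- array(0.8, c(2, 2, 1))
  rt <- data.table::CJ(country = 1L, year = 2013:2014, draw = 1L)[
    , `:=`(factor = 1.5, provenance = "computed")][]
  expect_message(rk <- apply_raking(draws, rt, c(1, 1), 2013:2014),
                 "clipped")
  expect_true(all(rk == 1))
})

test_that("severity raking preserves the severity identity", {
  sc <- default_scenario()
  years <- sc$grid$years
  set.seed(52)
  nc <- n_cells(sc$grid); D <- 3
  base <- array(runif(nc * length(years) * D, 0.02, 0.2),
                c(nc, length(years), D))
  dl <- list(overall = 3 * base, mild = base, moderate = base, severe = base)
  ctry <- sc$country_map$values
  tables <- lapply(c(mild = "mild", moderate = "moderate", severe = "severe"),
                   function(ind) {
    nat <- aggregate_to_admin(dl[[ind]], sc$population, ctry)
    ext <- nat[, .(value = 0.9 * mean(value)), by = .(country = unit, year)]
    interpolate_factors(
      compute_raking_factors(nat[, .(country = unit, year, draw, value)],
                             ext), years)
  })
  raked <- rake_severity_draws(dl, tables, ctry, years)
  expect_equal(raked$overall, raked$mild + raked$moderate + raked$severe,
               tolerance = 1e-12)
  expect_true(all(raked$overall <= 1))
})
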