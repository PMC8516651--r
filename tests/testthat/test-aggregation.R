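test_that("masking applies the scaled density threshold and barren class", {
  g <- grid_spec(0, 0, 0.25, 2, 2, 2013)
  cell_km2 <- (0.25 * 111.32)^2
  # densities 5, 9.9, 10, 100 persons/km^2
  pop <- grid_raster(g, c(5, 9.9, 10, 100) * cell_km2)
  lc <- grid_raster(g, c(0, 0, 0, 1))
  m <- apply_mask(rep(0.5, 4), pop, lc)
  expect_equal(m$mask, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(is.na(m$surface), !m$mask)
  # sparse population everywhere -> fully masked
  m2 <- apply_mask(rep(0.5, 4), grid_raster(g, rep(5 * cell_km2, 4)))
  expect_true(all(!m2$mask))
  # dense population, no barren cells -> unchanged
  m3 <- apply_mask(rep(0.5, 4), grid_raster(g, rep(100 * cell_km2, 4)))
  expect_true(all(m3$mask))
  expect_error(apply_mask(rep(0.5, 4), pop,
                          grid_raster(grid_spec(0, 0, 1, 3, 3, 2013),
                                      rep(0, 9))),
               "aligned")
})

test_that("admin aggregation is the population-weighted mean", {
  g <- grid_spec(0, 0, 1, 1, 2, 2013)
  pop <- grid_raster(g, c(100, 300))
  draws <- array(c(0.2, 0.4), c(2, 1, 1))
  agg <- aggregate_to_admin(draws, pop, unit_map = c(1, 1))
  expect_equal(agg$value, 0.35)
  # constant surface aggregates to the constant at every level
  dc <- array(0.3, c(2, 1, 5))
  for (um in list(c(1, 1), c(1, 2)))
    expect_true(all(aggregate_to_admin(dc, pop, um)$value == 0.3))
  # zero-population unit dropped with warning
  pop0 <- grid_raster(g, c(100, 0))
  expect_warning(a0 <- aggregate_to_admin(draws, pop0, c(1, 2)), "dropped")
  expect_equal(nrow(a0), 1)
})

test_that("hierarchy aggregation is consistent across levels", {
  sc <- default_scenario()
  set.seed(41)
  D <- 8
  draws <- array(runif(n_cells(sc$grid) * 6 * D), c(n_cells(sc$grid), 6, D))
  msk <- apply_mask(sc$stage_truths$overall, sc$population,
                    sc$land_class)$mask
  lu <- sc$admin$lookup
  a2 <- aggregate_to_admin(draws, sc$population, sc$admin$admin2_map$values,
                           msk)
  a0 <- aggregate_to_admin(draws, sc$population, sc$country_map$values, msk)
  # re-aggregating admin2 values by admin2 population equals direct admin0
  wra2 <- wra_population(sc$population, sc$admin$admin2_map$values,
                         wra_fraction = 1, mask = msk)
  a2m <- merge(merge(a2, wra2, by = "unit"),
               lu[, .(unit = admin2, country)], by = "unit")
  re0 <- a2m[, .(value = sum(value * wra) / sum(wra)),
             by = .(country, year, draw)]
  cmp <- merge(re0, a0[, .(country = unit, year, draw, direct = value)],
               by = c("country", "year", "draw"))
  expect_lt(max(abs(cmp$value - cmp$direct) / cmp$direct), 1e-9)
})

test_that("counts and YLDs are linear and conserved", {
  agg <- data.table::data.table(unit = 1L, year = 2013L, draw = 1L,
                                value = 0.25)
  ct <- compute_counts(agg, c("1" = 2000))
  expect_equal(ct$count, 500)
  expect_equal(compute_counts(data.table::data.table(
    unit = 1L, year = 2013L, draw = 1L, value = 0), c("1" = 2000))$count, 0)

  counts <- data.table::data.table(
    unit = 1L, year = 2013L, draw = 1L,
    indicator = c("mild", "moderate", "severe"),
    count = c(1000, 800, 500))
  dw <- disability_weights()
  y <- compute_ylds(counts, dw)
  expect_equal(y[indicator == "severe", yld], 500 * 0.149)
  expect_equal(y[indicator == "total", yld],
               1000 * 0.004 + 800 * 0.052 + 500 * 0.149)
  # zero weights -> zero YLDs (degenerate weights bypass the constructor)
  y0 <- compute_ylds(counts, list(mild = 0, moderate = 0, severe = 0))
  expect_true(all(y0$yld == 0))
  # linearity in counts
  y2 <- compute_ylds(data.table::copy(counts)[, count := count * 2], dw)
  expect_equal(y2[indicator == "total", yld], 2 * y[indicator == "total", yld])
})

test_that("public-health-problem bands match the WHO cutpoints", {
  x <- c(0.04, 0.05, 0.199, 0.20, 0.25, 0.399, 0.40, 0.8)
  expect_equal(as.character(classify_public_health_problem(x)),
               c("none", "low", "low", "medium", "medium", "medium",
                 "high", "high"))
})

test_that("inequality summaries report ranges, folds and ratios", {
  um <- data.table::data.table(
    unit = 1:4, country = c(1, 1, 2, 2),
    mean = c(0.1, 0.3, 0.2, 0.2), wra = c(100, 100, 50, 150))
  out <- inequality_summaries(um)
  c1 <- out$by_country[country == 1]
  expect_equal(c(c1$min, c1$max), c(0.1, 0.3))
  expect_equal(c1$fold, 3.0)
  c2 <- out$by_country[country == 2]
  expect_equal(c2$fold, 1.0)
  expect_true(all(out$ratios[country == 2, ratio] == 1))
  # ratios use the population-weighted national mean
  expect_equal(c1$national, (0.1 * 100 + 0.3 * 100) / 200)
  expect_equal(out$ratios[unit == 1, ratio], 0.1 / 0.2)
  # min of zero -> fold difference missing
  um0 <- data.table::copy(um)[unit == 1, mean := 0]
  expect_true(is.na(inequality_summaries(um0)$by_country[country == 1, fold]))
})
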