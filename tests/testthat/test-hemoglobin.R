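test_that("hemoglobin adjustment applies the configured decrements once", {
  tb <- adjustment_tables()
  # sea level, non-smoker: identity
  expect_equal(adjust_hemoglobin(12.7, 0, FALSE, tb), 12.7)
  # hand-checked table lookup: 1,500 m sits in the 0.5 g/dl bin
  expect_equal(adjust_hemoglobin(13.0, 1500, FALSE, tb), 12.5)
  # smoking decrement on top
  expect_equal(adjust_hemoglobin(13.0, 1500, TRUE, tb), 12.5 - 0.3)
  # provenance: already-adjusted factors are not re-applied
  expect_equal(adjust_hemoglobin(13.0, 1500, TRUE, tb,
                                 provenance = "elevation-adjusted"), 12.7)
  expect_equal(adjust_hemoglobin(13.0, 1500, TRUE, tb,
                                 provenance = "smoking-adjusted"), 12.5)
  expect_equal(adjust_hemoglobin(13.0, 4800, TRUE, tb,
                                 provenance = "fully-adjusted"), 13.0)
  expect_error(adjust_hemoglobin(13, 0, FALSE, tb, provenance = "mystery"),
               "provenance")
  expect_warning(adjust_hemoglobin(0.2, 4800, TRUE, tb), "clamped")
})

test_that("severity classification reproduces every WHO band", {
  # probes spanning all boundaries, non-pregnant then pregnant
  np <- c("7.9" = "severe", "8.0" = "moderate", "10.9" = "moderate",
          "11.0" = "mild", "11.5" = "mild", "11.9" = "mild",
          "12.0" = "non-anemic", "14.2" = "non-anemic")
  pg <- c("6.9" = "severe", "7.0" = "moderate", "9.9" = "moderate",
          "10.0" = "mild", "10.5" = "mild", "10.9" = "mild",
          "11.0" = "non-anemic", "13.0" = "non-anemic")
  got_np <- classify_severity(as.numeric(names(np)), pregnant = FALSE)
  got_pg <- classify_severity(as.numeric(names(pg)), pregnant = TRUE)
  expect_equal(as.character(got_np), unname(np))
  expect_equal(as.character(got_pg), unname(pg))
  # severity is monotone non-increasing in hemoglobin
  hb <- seq(3, 16, by = 0.05)
  sev_rank <- as.integer(classify_severity(hb, FALSE))  # severe = 4
  expect_true(all(diff(sev_rank) <= 0))
})

test_that("adjust-then-classify recovers the generating category", {
  sc <- default_scenario()
  md <- simulate_cluster_microdata(sc, n_clusters = 40,
                                   mean_cluster_size = 20, seed = 9)
  adj <- adjust_hemoglobin(md$raw_hb, md$elevation, md$smoker,
                           adjustment_tables())
  got <- classify_severity(adj, md$pregnant)
  expect_equal(as.character(got), md$category_true)
})

test_that("collapse to clusters does exact bookkeeping", {
  rec <- data.table::data.table(
    cluster_id = 1, lon = 0.1, lat = 0.2, year = 2013, country = 1,
    age = rep(30, 10),
    category = factor(c(rep("mild", 3), rep("moderate", 2), "severe",
                        rep("non-anemic", 4)),
                      levels = levels(classify_severity(10, FALSE))))
  out <- collapse_to_clusters(rec)
  expect_equal(out$N, 10)
  expect_equal(out$C, 6)
  expect_equal(out[, c(mild, moderate, severe)], c(3, 2, 1))
  # two years in one cluster -> two observations
  rec2 <- data.table::copy(rec)[6:10, year := 2014]
  expect_equal(nrow(collapse_to_clusters(rec2)), 2)
  # age filter applied before collapsing
  rec3 <- data.table::copy(rec)[1:3, age := 70]
  expect_message(out3 <- collapse_to_clusters(rec3), "15-49")
  expect_equal(out3$N, 7)
  # empty input -> empty output
  expect_equal(nrow(collapse_to_clusters(rec[0])), 0)
})

test_that("polygon resampling is population-weighted with conserved weights", {
  sc <- default_scenario()
  ar <- list(polygon_id = "5", year = 2013, country = 2, N = 800, C = 240,
             mild = 120, moderate = 100, severe = 20)
  pg <- sc$admin$polygons[["5"]]
  pts <- resample_polygon(ar, pg, sc$population, seed = 3)
  expect_equal(sum(pts$weight), 1, tolerance = 1e-12)
  expect_equal(sum(pts$weight * pts$N), 800)         # effective sample size
  expect_true(all(pts$lon > pg$lon_min & pts$lon < pg$lon_max))
  expect_true(all(pts$C == 240))
  # one-cell polygon: single point at that cell's center, weight 1
  cc <- cell_centers(sc$grid)
  half <- sc$grid$cell_size / 2
  one <- list(lon_min = cc$lon[1] - half, lon_max = cc$lon[1] + half,
              lat_min = cc$lat[1] - half, lat_max = cc$lat[1] + half)
  p1 <- resample_polygon(ar, one, sc$population, seed = 4)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$weight, 1)
  expect_equal(p1$lon, cc$lon[1])
})

test_that("resampled point frequencies follow cell population", {
  # uniform population: per-cell frequencies uniform within 3 multinomial SE
  grid <- grid_spec(0, 0, 1, 2, 2, 2013)
  pop <- grid_raster(grid, rep(1000, 4))
  ar <- list(polygon_id = "all", year = 2013, country = 1, N = 10,
             C = 5, mild = 2, moderate = 2, severe = 1)
  pg <- list(lon_min = -1, lon_max = 3, lat_min = -1, lat_max = 3)
  set.seed(21)
  draws <- replicate(2500, {
    p <- resample_polygon(ar, pg, pop, points_per_cells = 1, max_points = 4,
                          seed = NULL)
    paste(p$lon[1], p$lat[1])
  })
  k <- 2500
  freq <- table(draws) / k
  se <- sqrt(0.25 * 0.75 / k)
  expect_equal(length(freq), 4L)
  expect_true(all(abs(freq - 0.25) < 3 * se))
  # zero population fails
  pop0 <- grid_raster(grid, rep(0, 4))
  expect_error(resample_polygon(ar, pg, pop0), "population")
})
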