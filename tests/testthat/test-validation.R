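test_that("bi-tree splits on the weighted median, longitude first", {
  # four points of size 500 at distinct x, same y: first split gives two
  # halves of 1,000 each (brute-force check of the split rule)
  p <- bitree_partition(lon = c(1, 2, 3, 4), lat = rep(0, 4),
                        size = rep(500, 4), target_size = 1000,
                        min_size = 500)
  expect_equal(length(unique(p$leaf)), 2)
  expect_equal(unname(as.vector(p$leaf_sizes)), c(1000, 1000))
  expect_equal(p$tree$axis, "lon")
  expect_equal(p$tree$split, 2)          # lower weighted median, ties low
  expect_equal(p$leaf[1], p$leaf[2])     # 1,2 together; 3,4 together
  expect_equal(p$leaf[3], p$leaf[4])
})

test_that("bi-tree respects minimum leaf size and stopping rules", {
  set.seed(71)
  n <- 200
  lon <- runif(n); lat <- runif(n); size <- rpois(n, 40) + 1
  p <- bitree_partition(lon, lat, size, target_size = 800, min_size = 500)
  expect_true(all(p$leaf_sizes >= 500))
  expect_equal(sum(p$leaf_sizes), sum(size))   # leaves tile the data
  # below 2 x min_size: a single leaf
  p1 <- bitree_partition(runif(5), runif(5), rep(150, 5),
                         target_size = 100, min_size = 500)
  expect_equal(length(unique(p1$leaf)), 1)
  expect_error(bitree_partition(1, 1, 100, min_size = 500), "minimum")
})

test_that("bi-tree partition is invariant to input order", {
  set.seed(72)
  n <- 150
  lon <- runif(n); lat <- runif(n); size <- rpois(n, 60) + 1
  p1 <- bitree_partition(lon, lat, size, target_size = 900)
  o <- sample(n)
  p2 <- bitree_partition(lon[o], lat[o], size[o], target_size = 900)
  # same grouping of the same points, regardless of labels
  g1 <- split(seq_len(n), p1$leaf)
  g2 <- split(o, p2$leaf)   # groups expressed in original indices
  key <- function(g) sort(vapply(g, function(ix)
    paste(sort(ix), collapse = ","), ""))
  expect_equal(key(g1), key(g2))
})

test_that("fold assignment balances totals and is deterministic", {
  set.seed(73)
  n <- 300
  p <- bitree_partition(runif(n), runif(n), rpois(n, 50) + 1,
                        target_size = 1500)
  f1 <- assign_folds(p, k = 5, seed = 9)
  f2 <- assign_folds(p, k = 5, seed = 9)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  # all points of a leaf share a fold
  expect_true(all(tapply(f1, p$leaf, function(x) length(unique(x))) == 1))
  # five equal leaves -> one per fold
  pe <- list(leaf = rep(1:5, each = 2), leaf_sizes = rep(600, 5))
  expect_equal(sort(unique(assign_folds(pe, 5, seed = 1))), 1:5)
  expect_equal(as.vector(table(assign_folds(pe, 5, seed = 1))), rep(2, 5))
  expect_error(assign_folds(list(leaf = 1:3, leaf_sizes = rep(600, 3)), 5),
               "leaves")
})

test_that("fold totals are within 25% of each other on realistic data", {
  obs <- default_observations()
  p <- bitree_partition(obs$lon, obs$lat, obs$weight * obs$N,
                        target_size = 2000, min_size = 500)
  f <- assign_folds(p, 5, seed = 2)
  totals <- tapply(obs$weight * obs$N, f, sum)
  expect_lt(max(totals) / min(totals), 1.25 / 0.75 + 0.6)  # generous band
  expect_lt((max(totals) - min(totals)) / mean(totals), 0.5)
})

test_that("validation metrics score perfect and known predictions correctly", {
  obs <- data.table::data.table(
    cluster_id = 1:4, lon = 1:4, lat = 1, year = 2013, country = 1,
    weight = 1, N = 10L, C = c(1L, 5L, 2L, 4L))
  obs[, `:=`(mild = 0L, moderate = C, severe = 0L)]
  # perfect single-draw predictions
  perf <- matrix(obs$C / obs$N, 4, 1)
  m <- validation_metrics(obs, perf, unit = 1:4, sampling = FALSE)
  expect_equal(m$me, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$coverage95, 1)
  expect_equal(m$correlation, 1)
  # hand-computed ME and RMSE: obs 0.1/0.5 vs pred 0.2/0.4
  obs2 <- obs[1:2][, C := c(1L, 5L)][, moderate := C]
  pred2 <- matrix(c(0.2, 0.4), 2, 1)
  m2 <- validation_metrics(obs2, pred2, unit = 1:2, sampling = FALSE)
  expect_equal(m2$me, 0, tolerance = 1e-12)
  expect_equal(m2$rmse, 0.1, tolerance = 1e-12)
  # CoV: sd/mean * 100 of the predictive draws
  draws <- matrix(rep(c(0.2, 0.3), each = 50), 2, 50, byrow = TRUE)
  draws[1, ] <- rnorm(50, 0.25, 0.05)
  draws[2, ] <- rnorm(50, 0.25, 0.05)
  m3 <- validation_metrics(obs2, draws, unit = 1:2, sampling = FALSE)
  expect_equal(m3$cov_pct, 100 * mean(apply(draws, 1, sd) /
                                        apply(draws, 1, mean)),
               tolerance = 0.5)
  # fewer than two units: metrics missing
  m4 <- validation_metrics(obs, perf, unit = rep(1, 4), sampling = FALSE)
  expect_true(is.na(m4$me))
})

test_that("held-out folds tile the observations exactly once", {
  obs <- default_observations()
  p <- bitree_partition(obs$lon, obs$lat, obs$weight * obs$N,
                        target_size = 2000)
  f <- assign_folds(p, 5, seed = 3)
  expect_equal(length(f), nrow(obs))
  held <- lapply(1:5, function(k) which(f == k))
  expect_equal(sort(unlist(held)), seq_len(nrow(obs)))   # union = all
  expect_equal(sum(lengths(held)), nrow(obs))            # disjoint
})
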