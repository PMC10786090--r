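test_that("pearson matches the covariance formula and printed toy case", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), class = "ZeroVarianceError")

  direct <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  set.seed(12)
  for (k in 1:1000) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- pearson(x, y)
    expect_equal(r, direct(x, y), tolerance = 1e-12)
    expect_equal(r, cor(x, y), tolerance = 1e-12)
  }
})

test_that("spatial timecourse equals an exhaustive small-scale computation", {
  # 3 items, 2 channels, 4 samples, 2 participants: hand-checkable scale
  set.seed(13)
  data <- array(rnorm(6 * 2 * 4), c(6, 2, 4))
  ep <- tiny_epochs(data, sampling_rate = 250,
                    participants = rep(c("p1", "p2"), each = 3),
                    item_ids = rep(c("a", "b", "c"), 2))
  items <- toy_items()
  design <- enumerate_pairs(items)
  tc <- spatial_similarity_timecourse(ep, design)
  for (p in 1:2) {
    rows <- which(ep$trials$participant == c("p1", "p2")[p])
    for (t in 1:4) {
      r_ab <- cor(data[rows[1], , t], data[rows[2], , t])
      r_ac <- cor(data[rows[1], , t], data[rows[3], , t])
      r_bc <- cor(data[rows[2], , t], data[rows[3], , t])
      expect_equal(tc$values[p, "within", t], r_ab, tolerance = 1e-12)
      expect_equal(tc$values[p, "between", t], mean(c(r_ac, r_bc)),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical item data yields unit similarity in both conditions", {
  pattern <- rnorm(8)
  data <- array(0, c(6, 8, 10))
  for (tr in 1:6) for (t in 1:10) data[tr, , t] <- pattern
  ep <- tiny_epochs(data, participants = rep(c("p1", "p2"), each = 3),
                    item_ids = rep(c("a", "b", "c"), 2))
  tc <- spatial_similarity_timecourse(ep, toy_items() |> enumerate_pairs())
  expect_true(all(abs(tc$values - 1) < 1e-12))
})

test_that("pairs missing a trial are dropped and counted", {
  # 2 sets x 2 items: 2 within pairs (ab, cd), 4 between pairs
  items4 <- data.frame(
    item_id = c("a", "b", "c", "d"),
    char1 = paste0("c", 1:4), char2 = paste0("c", 5:8),
    char3 = paste0("c", 9:12), char4 = paste0("c", 13:16),
    syl1 = c("ba1", "po2", "mi3", "fa4"),
    syl2 = c("de1", "te2", "ne3", "le4"),
    syl3 = c("ge1", "ge1", "ke2", "ke2"),
    syl4 = c("he1", "ji2", "qi3", "xi4"),
    set_id = c("s1", "s1", "s2", "s2"), stringsAsFactors = FALSE)
  design <- enumerate_pairs(items4)
  set.seed(14)
  data <- array(rnorm(7 * 4 * 6), c(7, 4, 6))
  ep <- tiny_epochs(data,
                    participants = c(rep("p1", 4), rep("p2", 3)),
                    item_ids = c("a", "b", "c", "d", "a", "b", "c"))
  tc <- spatial_similarity_timecourse(ep, design)
  expect_identical(unname(tc$n_pairs["p1", ]), c(2L, 4L))
  # p2 lost item d: within cd gone, between ad and bd gone
  expect_identical(unname(tc$n_pairs["p2", ]), c(1L, 2L))
  expect_identical(tc$dropped, 3L)
  # a participant with no usable pairs in a condition raises
  ep2 <- tiny_epochs(data[1:6, , ],
                     participants = c(rep("p1", 4), "p2", "p2"),
                     item_ids = c("a", "b", "c", "d", "a", "c"))
  expect_error(spatial_similarity_timecourse(ep2, design),
               class = "NoPairsError")
})

test_that("window test reduces to the textbook paired t", {
  # identical conditions: t = 0, p = 1
  vals <- array(rnorm(6 * 2 * 20), c(6, 2, 20))
  vals[, 2, ] <- vals[, 1, ]
  tc0 <- fake_timecourse(vals)
  wt0 <- window_test(tc0, c(-1400, -1300))
  expect_equal(wt0$t, 0)
  expect_equal(wt0$p, 1)

  # fixed 6-participant difference vector vs the hand formula
  d <- c(0.08, 0.02, -0.01, 0.05, 0.03, 0.06)
  vals2 <- array(0, c(6, 2, 20))
  vals2[, 1, ] <- 0.3 + d
  vals2[, 2, ] <- 0.3
  tc2 <- fake_timecourse(vals2)
  wt2 <- window_test(tc2, c(-1400, -1300))
  t_hand <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(wt2$t, t_hand, tolerance = 1e-12)
  expect_equal(wt2$df, 5)
  expect_equal(wt2$p, 2 * pt(-abs(t_hand), 5), tolerance = 1e-12)

  # forced separation
  vals3 <- vals2
  vals3[, 1, ] <- vals3[, 2, ] + 0.1 + rnorm(6, sd = 1e-4)
  expect_lt(window_test(fake_timecourse(vals3), c(-1400, -1300))$p, 1e-3)
  expect_error(window_test(tc2, c(5000, 6000)), class = "WindowError")
})

test_that("time-cluster permutation finds no clusters in flat data and needs a seed", {
  vals <- array(0, c(8, 2, 50))
  vals[, 1, ] <- 0.2 + rnorm(8, sd = 1e-3) # constant over time, no threshold crossing
  vals[, 2, ] <- 0.2 + rnorm(8, sd = 1e-3)
  tc <- fake_timecourse(vals)
  expect_error(cluster_permutation_time(tc, c(-1100, 0), n_perm = 50),
               class = "SeedError")
  set.seed(15)
  vals2 <- array(rnorm(8 * 2 * 50, sd = 1e-6), c(8, 2, 50))
  tc2 <- fake_timecourse(vals2)
  cl <- cluster_permutation_time(tc2, c(-1100, 0), n_perm = 50, seed = 1)
  # with iid noise some singleton clusters may appear; all non-significant
  if (nrow(cl)) expect_true(all(cl$p > 0.05))
  # determinism under the seed
  cl2 <- cluster_permutation_time(tc2, c(-1100, 0), n_perm = 50, seed = 1)
  expect_identical(as.data.frame(cl), as.data.frame(cl2))
})

test_that("cluster mass equals the summed per-timepoint paired t", {
  set.seed(16)
  vals <- array(rnorm(10 * 2 * 60, sd = 0.02) + 0.2, c(10, 2, 60))
  vals[, 1, 30:45] <- vals[, 1, 30:45] + 0.08 # strong mid-epoch effect
  tc <- fake_timecourse(vals)
  cl <- cluster_permutation_time(tc, c(-1400, -1000), n_perm = 200, seed = 2)
  big <- cl[which.max(abs(cl$mass)), ]
  idx <- which(tc$time >= big$start & tc$time <= big$end)
  t_hand <- vapply(idx, function(t) {
    d <- vals[, 1, t] - vals[, 2, t]
    mean(d) / (sd(d) / sqrt(10))
  }, 0)
  expect_equal(big$mass, sum(t_hand), tolerance = 1e-9)
  expect_identical(big$size, length(idx))
  expect_lte(big$p, 0.05)
})

test_that("window statistics are calibrated on exchangeable null data", {
  set.seed(17)
  ps <- replicate(400, {
    vals <- array(rnorm(12 * 2 * 10), c(12, 2, 10))
    window_test(fake_timecourse(vals), c(-1400, -1350))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})

test_that("matched subsample equals the within count and tracks the full mean", {
  cfg <- scaled_config(seed = 61)
  items <- generate_stimuli(cfg)
  design <- enumerate_pairs(items)
  ep <- baseline_correct(generate_dataset(cfg, items)$epochs)
  ms <- matched_subsample_test(ep, design, seed = 62)
  n_within <- sum(design$condition == "within")
  expect_true(all(lengths(ms$subsample) == n_within))
  # subsampled indices point at between pairs only
  expect_true(all(unlist(ms$subsample) %in% which(design$condition == "between")))
  # subsample mean is an unbiased estimate of the full between mean
  expect_lt(max(abs(ms$participant_means$between_sub -
                    ms$participant_means$between_full)), 0.05)
})
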