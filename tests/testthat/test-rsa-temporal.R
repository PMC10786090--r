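test_that("distance-threshold adjacency matches simple geometries", {
  # 3 collinear electrodes spaced d, threshold 1.5d: a chain
  coords <- data.frame(label = c("e1", "e2", "e3"),
                       x = c(0, 1, 2), y = 0, z = 0)
  adj <- build_adjacency(coords, threshold = 1.5)
  expect_true(adj["e1", "e2"] && adj["e2", "e3"])
  expect_false(adj["e1", "e3"])
  expect_false(any(diag(adj)))
  expect_true(isSymmetric(unclass(adj)))

  # threshold >= max distance: complete graph
  full <- build_adjacency(coords, threshold = 2)
  expect_true(all(full[upper.tri(full)]))

  # coincident electrodes are rejected
  coords$x[2] <- 0
  expect_error(build_adjacency(coords), class = "DegenerateLayoutError")
})

test_that("grow_patch returns connected patches of the requested size", {
  m <- montage_layout(62)
  adj <- build_adjacency(m)
  patch <- grow_patch(adj, "POz", 6, coords = as.matrix(m[, c("x", "y", "z")]))
  expect_identical(length(patch), 6L)
  idx <- match(patch, rownames(adj))
  comps <- phonrsa:::connected_components(adj, idx)
  expect_identical(length(comps), 1L)
  expect_true("POz" %in% patch)
})

test_that("temporal map equals exhaustive per-electrode computation", {
  set.seed(23)
  data <- array(rnorm(6 * 3 * 20), c(6, 3, 20))
  ep <- tiny_epochs(data, sampling_rate = 125,
                    participants = rep(c("p1", "p2"), each = 3),
                    item_ids = rep(c("a", "b", "c"), 2))
  design <- enumerate_pairs(toy_items())
  interval <- c(-1400, -1300) # first 13 samples at 125 Hz
  topo <- temporal_similarity_map(ep, design, interval)
  idx <- which(ep$time >= interval[1] & ep$time <= interval[2])
  for (p in 1:2) {
    rows <- which(ep$trials$participant == c("p1", "p2")[p])
    for (e in 1:3) {
      r_ab <- cor(data[rows[1], e, idx], data[rows[2], e, idx])
      r_ac <- cor(data[rows[1], e, idx], data[rows[3], e, idx])
      r_bc <- cor(data[rows[2], e, idx], data[rows[3], e, idx])
      expect_equal(topo$values[p, "within", e], r_ab, tolerance = 1e-12)
      expect_equal(topo$values[p, "between", e], mean(c(r_ac, r_bc)),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical trials give a unit topography", {
  series <- rnorm(20)
  data <- array(0, c(6, 3, 20))
  for (tr in 1:6) for (e in 1:3) data[tr, e, ] <- series
  ep <- tiny_epochs(data, sampling_rate = 125,
                    participants = rep(c("p1", "p2"), each = 3),
                    item_ids = rep(c("a", "b", "c"), 2))
  topo <- temporal_similarity_map(ep, enumerate_pairs(toy_items()),
                                  c(-1400, -1300))
  expect_true(all(abs(topo$values - 1) < 1e-12))
})

test_that("outputs are invariant to pair item order", {
  cfg <- sim_config(n_participants = 4, n_sets = 2, items_per_set = 3,
                    n_channels = 8, sampling_rate = 125, seed = 71)
  items <- generate_stimuli(cfg)
  ep <- generate_dataset(cfg, items)$epochs
  design <- enumerate_pairs(items)
  swapped <- design
  tmp <- swapped$item_a
  swapped$item_a <- swapped$item_b
  swapped$item_b <- tmp
  attr(swapped, "item_ids") <- attr(design, "item_ids")
  topo1 <- temporal_similarity_map(ep, design)
  topo2 <- temporal_similarity_map(ep, swapped)
  expect_equal(topo1$values, topo2$values, tolerance = 1e-12)
  tc1 <- spatial_similarity_timecourse(ep, design)
  tc2 <- spatial_similarity_timecourse(ep, swapped)
  expect_equal(tc1$values, tc2$values, tolerance = 1e-12)
})

test_that("electrode permutation returns empty results on identical conditions", {
  labels <- montage_layout(16)$label
  vals <- array(0.3, c(8, 2, 16))
  topo <- fake_topo(vals, labels)
  adj <- build_adjacency(montage_layout(16))
  res <- cluster_permutation_electrodes(topo, adj, n_perm = 100, seed = 3)
  expect_identical(nrow(res), 0L)
  expect_error(cluster_permutation_electrodes(topo, adj, n_perm = 100),
               class = "SeedError")
})

test_that("reported electrode clusters are connected suprathreshold sets", {
  set.seed(24)
  labels <- montage_layout(16)$label
  vals <- array(rnorm(10 * 2 * 16, sd = 0.02) + 0.2, c(10, 2, 16))
  vals[, 1, 1:5] <- vals[, 1, 1:5] + 0.15 # strong effect on a patch
  topo <- fake_topo(vals, labels)
  adj <- build_adjacency(montage_layout(16))
  res <- cluster_permutation_electrodes(topo, adj, n_perm = 300, seed = 4)
  expect_gt(nrow(res), 0L)
  et <- attr(res, "electrode_table")
  for (k in seq_len(nrow(res))) {
    members <- strsplit(res$electrodes[k], ",")[[1]]
    idx <- match(members, rownames(adj))
    comps <- phonrsa:::connected_components(adj, idx)
    expect_identical(length(comps), 1L)
    # every member electrode is individually suprathreshold
    expect_true(all(et$p[idx] <= 0.05))
  }
  expect_identical(sum(res$size), length(unlist(strsplit(res$electrodes, ","))))
})

test_that("electrode-level permutation p-values are uniform under the null", {
  set.seed(25)
  labels <- montage_layout(8)$label
  adj <- build_adjacency(montage_layout(8))
  ps <- c()
  for (r in 1:60) {
    vals <- array(rnorm(12 * 2 * 8, sd = 0.05) + 0.2, c(12, 2, 8))
    topo <- fake_topo(vals, labels)
    res <- cluster_permutation_electrodes(topo, adj, n_perm = 200,
                                          seed = 100 + r)
    ps <- c(ps, attr(res, "electrode_table")$p)
  }
  # permutation p-values are discrete; use a binned goodness-of-fit test
  counts <- table(cut(ps, breaks = seq(0, 1, 0.1), include.lowest = TRUE))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("recovered cluster size grows with the true effect patch", {
  layout <- montage_layout(16)
  adj0 <- build_adjacency(layout)
  xyz <- as.matrix(layout[, c("x", "y", "z")])
  sizes <- c(3L, 6L, 9L)
  med_size <- vapply(sizes, function(k) {
    patch <- grow_patch(adj0, "CPz", k, coords = xyz)
    rec <- vapply(1:10, function(r) {
      cfg <- scaled_config(seed = 500000 + 1000 * k + r,
                           effect_channels = patch)
      items <- generate_stimuli(cfg)
      ep <- baseline_correct(generate_dataset(cfg, items)$epochs)
      topo <- temporal_similarity_map(ep, enumerate_pairs(items))
      cle <- cluster_permutation_electrodes(topo,
                                            build_adjacency(ep$channels),
                                            n_perm = 300,
                                            seed = 600000 + 1000 * k + r)
      sig <- significant_clusters(cle)
      if (nrow(sig)) max(sig$size) else 0L
    }, 0)
    median(rec)
  }, 0)
  expect_true(all(diff(med_size) >= 0))
  expect_gte(med_size[3], 6) # the large patch is substantially recovered
})
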