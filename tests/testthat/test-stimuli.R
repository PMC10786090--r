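test_that("validate_items accepts set-consistent designs and flags violations", {
  items <- generate_stimuli(sim_config(seed = 11))
  expect_identical(nrow(validate_items(items)), 100L)

  single <- items[1, ]
  expect_identical(validate_items(single), single)

  tone_clash <- toy_items()
  tone_clash$syl3 <- c("ji1", "ji2", "tou2") # same rime, tones differ
  expect_error(validate_items(tone_clash), class = "SetConsistencyError")

  dup <- toy_items()
  dup$item_id <- c("a", "a", "c")
  expect_error(validate_items(dup), class = "DuplicateIdError")
})

test_that("pair enumeration reproduces the design combinatorics", {
  # full design: 10 sets x 10 items
  items <- generate_stimuli(sim_config(seed = 11))
  design <- enumerate_pairs(items)
  per_set <- table(items$set_id[match(design$item_a, items$item_id)][
    design$condition == "within"])
  expect_true(all(per_set == 45L))
  expect_identical(sum(design$condition == "within"), 450L)
  expect_identical(sum(design$condition == "between"), 4500L)

  # one set of two items
  two <- toy_items()[1:2, ]
  d2 <- enumerate_pairs(two)
  expect_identical(as.vector(table(d2$condition)), c(1L, 0L))

  # 3 sets x 3 items, checked against brute-force enumeration
  items9 <- generate_stimuli(sim_config(n_sets = 3, items_per_set = 3,
                                        seed = 5))
  d9 <- enumerate_pairs(items9)
  brute <- 0L
  for (i in 1:8) for (j in (i + 1):9)
    if (items9$set_id[i] == items9$set_id[j]) brute <- brute + 1L
  expect_identical(sum(d9$condition == "within"), brute)
  expect_identical(sum(d9$condition == "within"), 9L)
  expect_identical(sum(d9$condition == "between"), 27L)
})

test_that("pair totals equal C(N,2) across design sizes", {
  for (spec in list(c(2, 3), c(5, 8), c(10, 20), c(4, 50))) {
    items <- generate_stimuli(sim_config(n_sets = spec[1],
                                         items_per_set = spec[2],
                                         seed = spec[1] * 100 + spec[2]))
    n <- nrow(items)
    expect_identical(nrow(enumerate_pairs(items)), as.integer(choose(n, 2)))
  }
})

test_that("syllable similarity matches its component-weight definition", {
  expect_equal(syllable_similarity("ji1", "ji1"), 1.0)
  expect_equal(syllable_similarity("ji1", "ji2"), 0.8) # tone mismatch only
  expect_equal(syllable_similarity("ji1", "wo3"), 0.0)
  expect_equal(syllable_similarity("zhang1", "zhen1"), 0.4 + 0.2) # initial+tone
  expect_error(syllable_similarity("ji1", "ji1", weights = c(1, 1, 1)),
               class = "WeightError")

  # symmetry and bounds over random syllable pairs
  pool <- phonrsa:::.syllable_pool()
  set.seed(42)
  for (k in 1:200) {
    ab <- sample(pool, 2, replace = TRUE)
    s1 <- syllable_similarity(ab[1], ab[2])
    expect_identical(s1, syllable_similarity(ab[2], ab[1]))
    expect_gte(s1, 0); expect_lte(s1, 1)
  }
})

test_that("phonological similarity matrix equals element-wise brute force", {
  items <- toy_items()
  for (pos in c(1L, 3L)) {
    m <- stimulus_similarity_matrix(items, pos)
    expect_true(isSymmetric(m))
    expect_equal(unname(diag(m)), rep(1, 3))
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      expect_equal(m[i, j],
                   syllable_similarity(items[[paste0("syl", pos)]][i],
                                       items[[paste0("syl", pos)]][j]))
    }
  }
  # shared third syllable scores exactly 1
  expect_equal(stimulus_similarity_matrix(items, 3)["a", "b"], 1.0)
})

test_that("external matrices pass through and incompleteness is flagged", {
  items <- toy_items()
  ident <- diag(3)
  dimnames(ident) <- list(items$item_id, items$item_id)
  expect_equal(stimulus_similarity_matrix(items, kind = "external",
                                          source = ident), ident)
  # TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(ident, path)
  expect_equal(stimulus_similarity_matrix(items, kind = "external",
                                          source = path), ident)
  short <- ident[1:2, 1:2]
  expect_error(stimulus_similarity_matrix(items, kind = "external",
                                          source = short),
               class = "MissingEntryError")
})

test_that("condition contrast of pair similarities follows the Welch formula", {
  items <- generate_stimuli(sim_config(n_sets = 3, items_per_set = 3, seed = 2))
  design <- enumerate_pairs(items)
  # identical values in both conditions: t = 0
  flat <- matrix(0.5, 9, 9, dimnames = list(items$item_id, items$item_id))
  diag(flat) <- 1
  r0 <- compare_pair_similarity(flat, design)
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)

  # forced separation
  sep <- flat
  sep[lower.tri(sep)] <- 1e-6 * seq_len(sum(lower.tri(sep)))
  sep[upper.tri(sep)] <- t(sep)[upper.tri(sep)]
  wi <- design$condition == "within"
  sep[cbind(design$item_a[wi], design$item_b[wi])] <- 1
  sep[cbind(design$item_b[wi], design$item_a[wi])] <- 1
  rs <- compare_pair_similarity(sep, design)
  expect_gt(rs$mean_within, 0.99)
  expect_lt(rs$mean_between, 0.01)
  expect_gt(rs$t_statistic, 50)

  # 5+5 fixed values vs the textbook Welch evaluation
  w <- c(0.9, 0.8, 1.0, 0.85, 0.95)
  b <- c(0.2, 0.3, 0.1, 0.25, 0.4)
  items5 <- generate_stimuli(sim_config(n_sets = 5, items_per_set = 2, seed = 3))
  d5 <- enumerate_pairs(items5) # 5 within, 40 between
  m5 <- matrix(NA_real_, 10, 10,
               dimnames = list(items5$item_id, items5$item_id))
  diag(m5) <- 1
  iw <- which(d5$condition == "within")[1:5]
  ib <- which(d5$condition == "between")[1:5]
  keep <- c(iw, ib)
  vals <- c(w, b)
  m5[cbind(d5$item_a[keep], d5$item_b[keep])] <- vals
  m5[cbind(d5$item_b[keep], d5$item_a[keep])] <- vals
  d5sub <- d5[keep, ]
  attr(d5sub, "item_ids") <- items5$item_id
  res <- compare_pair_similarity(m5, d5sub)
  se <- sqrt(var(w) / 5 + var(b) / 5)
  t_hand <- (mean(w) - mean(b)) / se
  df_hand <- se^4 / ((var(w) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
})

test_that("generated stimuli separate conditions only at the third position", {
  items <- generate_stimuli(sim_config(seed = 7))
  design <- enumerate_pairs(items)
  res3 <- compare_pair_similarity(stimulus_similarity_matrix(items, 3), design)
  expect_equal(res3$mean_within, 1.0) # shared syllable by construction
  expect_gt(res3$mean_within - res3$mean_between, 0.5)
  for (pos in c(1L, 2L, 4L)) {
    r <- compare_pair_similarity(stimulus_similarity_matrix(items, pos),
                                 design)
    expect_lt(abs(r$mean_within - r$mean_between), 0.02)
  }
})
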