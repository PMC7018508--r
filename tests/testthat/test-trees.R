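test_that("tree tables round-trip through read/write and validate", {
  df <- make_binary_table(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  fo <- as_lineage_forest(df)
  expect_equal(nrow(fo), 7)
  expect_equal(max(fo$generation), 2)
  expect_equal(length(unique(fo$tree_id)), 1)

  write_tree_table(fo, path)
  back <- read_tree_table(path)
  for (col in c("tree_id", "cell_id", "parent_id", "fate")) {
    expect_identical(back[[col]], fo[[col]])
  }
  expect_equal(back$birth_time_h, fo$birth_time_h)
  expect_equal(back$end_time_h, fo$end_time_h)

  # two trees distinguished by tree_id
  df2 <- rbind(make_binary_table(2, tree_id = "a"),
               make_binary_table(2, tree_id = "b"))
  fo2 <- as_lineage_forest(df2)
  expect_equal(length(unique(fo2$tree_id)), 2)
})

test_that("malformed tables raise parse errors naming the problem", {
  df <- make_binary_table(2)
  bad <- df
  bad$parent_id[2] <- "nonexistent"
  expect_error(as_lineage_forest(bad), class = "kc_parse_error")

  dup <- rbind(df, df[3, ])
  expect_error(as_lineage_forest(dup), class = "kc_parse_error")

  # three children of one mother
  extra <- df[2, ]
  extra$cell_id <- "99"
  expect_error(as_lineage_forest(rbind(df, extra)), class = "kc_parse_error")

  # child birth time inconsistent with parent division
  off <- df
  off$birth_time_h[2] <- off$birth_time_h[2] + 0.5
  expect_error(as_lineage_forest(off), class = "kc_parse_error")

  # children under a non-divided parent
  lost <- df
  lost$fate[1] <- "lost"
  expect_error(as_lineage_forest(lost), class = "kc_parse_error")
})

test_that("cycle_length subtracts times and rejects non-divided cells", {
  df <- data.frame(
    tree_id = "t", cell_id = c("a", "b", "c"), parent_id = c(NA, "a", "a"),
    birth_time_h = c(10, 28, 28), end_time_h = c(28, 50, 40),
    fate = c("divided", "divided", "lost")
  )
  fo <- as_lineage_forest(df)
  expect_equal(cycle_length(fo, "a"), 18)
  expect_error(cycle_length(fo, "c"), class = "kc_undefined_cycle")
  # translation invariance
  df$birth_time_h <- df$birth_time_h + 7.25
  df$end_time_h <- df$end_time_h + 7.25
  expect_equal(cycle_length(as_lineage_forest(df), "a"), 18)
})

test_that("kinship_of matches definitions and the ancestor-path oracle", {
  fo <- as_lineage_forest(make_binary_table(4))
  expect_equal(unclass(kinship_of(fo, "2", "1")), c(u = 0L, v = 1L),
               ignore_attr = TRUE)
  expect_equal(unclass(kinship_of(fo, "4", "6")), c(u = 2L, v = 2L),
               ignore_attr = TRUE)
  expect_equal(unclass(kinship_of(fo, "8", "1")), c(u = 0L, v = 3L),
               ignore_attr = TRUE)
  expect_equal(unclass(kinship_of(fo, "4", "3")), c(u = 1L, v = 2L),
               ignore_attr = TRUE)

  set.seed(11)
  ids <- as.character(sample(2:15))
  for (i in seq(1, 12, by = 2)) {
    a <- ids[i]; b <- ids[i + 1]
    k <- kinship_of(fo, a, b)
    expect_equal(as.integer(k), oracle_kinship(as.data.frame(fo), a, b))
  }

  two <- as_lineage_forest(rbind(make_binary_table(2, tree_id = "a"),
                                 make_binary_table(2, tree_id = "b")))
  expect_error(kinship_of(two, 1, 5), class = "kc_no_common_ancestor")
})

test_that("kin_pairs enumerates exactly the pairs of each kinship", {
  fo <- as_lineage_forest(make_binary_table(3))
  expect_equal(nrow(kin_pairs(fo, c(0, 1))), 6)
  expect_equal(nrow(kin_pairs(fo, c(1, 1))), 6)   # 3 unordered
  expect_equal(nrow(kin_pairs(fo, c(2, 2))), 8)   # 4 unordered
  expect_equal(nrow(kin_pairs(fo, c(1, 2))), 4)

  # losing one granddaughter removes 4 ordered cousin pairs
  df <- make_binary_table(3)
  df$fate[df$cell_id == "7"] <- "lost"
  fo2 <- as_lineage_forest(df)
  expect_equal(nrow(kin_pairs(fo2, c(2, 2))), 4)

  # elder first for asymmetric kinships
  pr <- attr(kin_pairs(fo, c(0, 2)), "rows")
  expect_true(all(fo$generation[pr$row_a] < fo$generation[pr$row_b]))
})

test_that("kin_pairs agrees with the brute-force double-loop oracle", {
  p <- ref_gp()
  fo <- generate_dataset("gp", p, n_trees = 4,
                         obs = observation_model(0.08, 0.04, 120),
                         seed = 5)
  for (k in list(c(0, 1), c(1, 1), c(1, 2), c(2, 2), c(0, 3))) {
    expect_equal(nrow(kin_pairs(fo, k)), oracle_pair_count(fo, k[1], k[2]),
                 label = sprintf("kinship (%d,%d)", k[1], k[2]))
  }
  # no pair ever contains a non-divided cell
  for (k in list(c(0, 1), c(2, 2))) {
    pr <- attr(kin_pairs(fo, k), "rows")
    expect_true(all(fo$fate[pr$row_a] == "divided"))
    expect_true(all(fo$fate[pr$row_b] == "divided"))
  }
})

test_that("truncation keeps the deepest fully completed generations", {
  # fully complete trees are unchanged
  fo <- as_lineage_forest(make_binary_table(4))
  tr <- truncate_trees(fo, 0.95)
  expect_equal(nrow(tr), nrow(fo))
  expect_equal(attr(tr, "truncation_depth"), 3)

  # forced rule: generations 0..4 complete, generation 5 not
  p <- ref_gp()
  full <- simulate_gp_trees(p, n_trees = 10, n_gen = 6, seed = 3)
  cut <- as.data.frame(full)
  g5 <- cut$generation == 5
  cut$fate[g5] <- "censored"
  cut$end_time_h[g5] <- cut$birth_time_h[g5] + 0.1
  # one incomplete cell in generation 4 (fraction still above 0.95)
  lost4 <- which(cut$generation == 4)[1]
  cut$fate[lost4] <- "lost"
  cut <- cut[!(cut$parent_id %in% cut$cell_id[lost4] &
                 cut$tree_id == cut$tree_id[lost4] &
                 cut$generation == 5), ]
  fo2 <- as_lineage_forest(cut[, c("tree_id", "cell_id", "parent_id",
                                   "birth_time_h", "end_time_h", "fate")],
                           validate = FALSE)
  tr2 <- truncate_trees(fo2)
  expect_equal(attr(tr2, "truncation_depth"), 4)
  expect_equal(max(tr2$generation), 4)  # generation 5 removed entirely
  # the incomplete generation-4 cell is retained but enters no pair
  expect_true(any(tr2$fate == "lost" & tr2$generation == 4))
  pr <- attr(kin_pairs(tr2, c(0, 1)), "rows")
  expect_true(all(tr2$fate[pr$row_b] == "divided"))

  # censored synthetic dataset: depth equals the per-generation count oracle
  cen <- generate_dataset("gp", p, n_trees = 40,
                          obs = observation_model(0.02, 0, 120), seed = 9)
  tr3 <- truncate_trees(cen, 0.95)
  comp <- oracle_completion(cen)
  ok <- comp >= 0.95
  expect_true(ok[1])  # design: generation 0 must complete for this fixture
  G_oracle <- max(which(cumprod(ok) > 0)) - 1L
  expect_equal(attr(tr3, "truncation_depth"), G_oracle)
  # every retained full generation above threshold; G+1 absent
  comp_tr <- oracle_completion(tr3)
  expect_true(all(comp_tr[seq_len(G_oracle)] >= 0.95))

  # no generation complete: G = 0 with a warning
  allc <- as.data.frame(fo2)
  allc$fate <- "censored"
  allc$end_time_h <- pmax(allc$end_time_h, allc$birth_time_h + 1e-3)
  fo3 <- as_lineage_forest(allc, validate = FALSE)
  expect_warning(tr4 <- truncate_trees(fo3), class = "kc_truncation_warning")
  expect_equal(attr(tr4, "truncation_depth"), 0)
})
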