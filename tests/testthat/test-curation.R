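test_that("equal-count split is contiguous, balanced, and partitions the table", {
  tab <- make_table(300, seed = 5)
  sp <- split_equal_count(tab, "thickness_nm", 3)
  expect_equal(sp$boundaries$n, rep(100L, 3))
  expect_equal(sort(unlist(lapply(sp$groups, rownames))), sort(rownames(tab)))
  # key ranges are non-overlapping except at shared boundaries
  expect_true(sp$boundaries$key_max[1] <= sp$boundaries$key_min[2])
  expect_true(sp$boundaries$key_max[2] <= sp$boundaries$key_min[3])

  tab9 <- make_table(9, seed = 6)
  expect_equal(split_equal_count(tab9, "thickness_nm", 3)$boundaries$n,
               rep(3L, 3))
  tab10 <- make_table(10, seed = 6)
  expect_equal(split_equal_count(tab10, "thickness_nm", 3)$boundaries$n,
               c(4L, 3L, 3L))   # extra particle goes to the lowest-key group
  expect_error(split_equal_count(tab9, "thickness_nm", 10), "exceeds")
})

test_that("depth-bin selection equals the brute-force nearest-neighbour oracle", {
  tab <- data.frame(x = 0, y = 0, z = 0, depth_nm = as.numeric(1:2000))
  sel <- select_depth_bins(tab, centers = 5, per_center_n = 3)
  expect_equal(sel$groups[[1]]$depth_nm, c(4, 5, 6))
  expect_equal(select_depth_bins(tab, 5, 1)$groups[[1]]$depth_nm, 5)

  set.seed(7)
  tab2 <- data.frame(x = 0, y = 0, z = 0, depth_nm = runif(5000, 0, 90))
  sel2 <- select_depth_bins(tab2, centers = seq(5, 50, 5), per_center_n = 400)
  for (i in seq_along(sel2$index))
    expect_equal(sel2$index[[i]],
                 oracle_depth_bin(tab2$depth_nm, seq(5, 50, 5)[i], 400))
  expect_error(select_depth_bins(tab2, 5, 6000), "exceeds")
})

test_that("scarce near-surface particles force overlap between the 5 and 10 nm groups", {
  # only 600 particles shallower than 10 nm, groups of 1000
  set.seed(8)
  tab <- data.frame(x = 0, y = 0, z = 0,
                    depth_nm = c(runif(600, 0, 10), runif(4400, 10, 90)))
  sel <- select_depth_bins(tab, centers = c(5, 10), per_center_n = 1000)
  expect_gt(max(sel$groups[[1]]$depth_nm), 10)
  ov <- sel$overlap$overlap_fraction[1]
  expect_gt(ov, 0)
  expect_equal(ov, length(intersect(oracle_depth_bin(tab$depth_nm, 5, 1000),
                                    oracle_depth_bin(tab$depth_nm, 10, 1000))) / 1000)
})

test_that("high-quality filter applies strict inequalities and is idempotent/monotone", {
  set.seed(9)
  tab <- make_table(100, seed = 9)
  hq <- select_high_quality(tab)
  expect_equal(nrow(hq), sum(tab$thickness_nm < 180 & tab$depth_nm > 30))
  # boundary records are excluded
  edge <- tab
  edge$depth_nm[1] <- 30; edge$thickness_nm[1] <- 100
  edge$depth_nm[2] <- 50; edge$thickness_nm[2] <- 180
  hq_edge <- select_high_quality(edge)
  expect_false(any(rownames(hq_edge) %in% rownames(edge)[1:2]))
  # identity under vacuous thresholds
  expect_equal(nrow(select_high_quality(tab, Inf, 0)),
               sum(tab$depth_nm > 0))
  # idempotent
  expect_equal(select_high_quality(hq)$depth_nm, hq$depth_nm)
  # monotone: relaxing thresholds never drops a retained particle
  hq2 <- select_high_quality(tab, 200, 20)
  expect_true(all(rownames(hq) %in% rownames(hq2)))
})

test_that("random subsets are nested, deterministic, and thickness-unbiased", {
  tab4 <- make_table(4, seed = 10)
  rs <- random_subsets(tab4, c(2, 4), seed = 42, match_key = NULL)
  expect_true(all(rownames(rs$subsets$n2) %in% rownames(rs$subsets$n4)))
  rs2 <- random_subsets(tab4, c(2, 4), seed = 42, match_key = NULL)
  expect_identical(rs$subsets, rs2$subsets)

  big <- make_table(20000, seed = 10)
  rs3 <- random_subsets(big, c(250, 1000, 4000, 16114), seed = 7)
  for (i in 1:3)
    expect_true(all(rownames(rs3$subsets[[i]]) %in% rownames(rs3$subsets[[i + 1]])))
  expect_true(all(rs3$checks$ks_p > 0.01))
})

test_that("tomogram-level selection adds whole tomograms then trims the last", {
  tab <- data.frame(tomo = rep(c("a", "b", "c"), each = 10),
                    x = 1, y = 1, z = 1)
  sel <- select_by_tomogram(tab, 25, seed = 3)
  expect_equal(nrow(sel), 25)
  expect_length(attr(sel, "tomograms"), 3)
  cnt <- table(sel$tomo)
  expect_equal(sort(as.vector(cnt)), c(5L, 10L, 10L))
  # the trimmed tomogram is the last one added
  expect_equal(cnt[[attr(sel, "tomograms")[3]]], 5L)
  expect_identical(sel, select_by_tomogram(tab, 25, seed = 3))
  # single tomogram holding exactly n_target
  one <- tab[tab$tomo == "a", ]
  expect_equal(nrow(select_by_tomogram(one, 10, seed = 1)), 10)
})
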