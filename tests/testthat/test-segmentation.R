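test_that("epsilon follows the clamped linear policy on the mean hue", {
  pol <- epsilon_policy(scale_factor = 0.1, floor = 2, cap = 30)
  uni <- hsv_from_hue(matrix(120L, 10, 10))
  expect_equal(suppressMessages(compute_epsilon(uni, pol)), 12)

  zero <- hsv_from_hue(matrix(0L, 10, 10))
  expect_equal(suppressMessages(compute_epsilon(zero, pol)), 2)  # floor clamp
  expect_message(compute_epsilon(zero, pol), "degenerate")

  half <- hsv_from_hue(rbind(matrix(60L, 5, 10), matrix(120L, 5, 10)))
  expect_equal(compute_epsilon(half, pol), 9)                    # mean 90
})

test_that("a two-hue block image clusters into exactly its two regions", {
  hue <- matrix(120L, 20, 20)
  hue[8:13, 8:13] <- 15L                     # 6x6 foreground block
  img <- hsv_from_hue(hue)
  map <- modified_dbscan(img, epsilon = 10, min_neighbors = 8,
                         edge_margin = 1)
  expect_equal(map$n_groups, 2L)
  groups <- extract_groups(map)
  fg <- groups[[2]]                          # smaller group
  expect_equal(fg$n_pixels, 36L)             # whole block: cores + ring
  expect_equal(unname(fg$bbox), c(7L, 7L, 12L, 12L))  # 0-based tight box
  # interior 4x4 are cores (label 2), ring is boundary (label 1)
  expect_equal(sum(map$labels[9:12, 9:12] == 2L), 16L)
  expect_equal(sum(map$labels == 2L & map$group_ids == fg$id), 16L)
  # matches the brute-force emulator exactly
  bf <- bf_dbscan(hue, eps = 10)
  expect_identical(map$labels, bf$labels)
  expect_identical(canonical_partition(map$group_ids),
                   canonical_partition(bf$group_ids))
})

test_that("a uniform image forms one group covering all non-edge pixels", {
  img <- hsv_from_hue(matrix(90L, 12, 15))
  map <- modified_dbscan(img, epsilon = 5)
  expect_equal(map$n_groups, 1L)
  expect_true(all(map$group_ids[2:11, 2:14] == 0L))
  expect_true(all(map$group_ids[1, ] == -1L))   # edge margin
})

test_that("a checkerboard of extreme hues is all outliers at tiny epsilon", {
  hue <- outer(1:16, 1:16, function(i, j) ifelse((i + j) %% 2 == 0, 0L, 90L))
  map <- modified_dbscan(hsv_from_hue(hue), epsilon = 1)
  expect_equal(map$n_groups, 0L)
  expect_true(all(map$labels == -1L))
})

test_that("every pixel gets exactly one label and counts conserve", {
  set.seed(42)
  hue <- matrix(sample(0:179, 30 * 25, TRUE), 30, 25)
  map <- modified_dbscan(hsv_from_hue(hue), epsilon = 20, min_neighbors = 6)
  expect_true(all(map$labels %in% c(-1L, 1L, 2L)))
  expect_equal(sum(table(map$labels)), 30 * 25)
  # outliers and only outliers lack a group
  expect_identical(map$group_ids == -1L, map$labels == -1L)
  # every group contains at least one core pixel
  for (g in seq_len(map$n_groups) - 1L)
    expect_gt(sum(map$labels[map$group_ids == g] == 2L), 0L)
})

test_that("raising epsilon never increases the number of outliers", {
  set.seed(7)
  hue <- matrix(sample(0:60, 24 * 24, TRUE), 24, 24)
  img <- hsv_from_hue(hue)
  outliers <- vapply(c(2, 5, 10, 20, 40),
                     function(e) sum(modified_dbscan(img, e)$labels == -1L),
                     numeric(1))
  expect_true(all(diff(outliers) <= 0))
})

test_that("the partition is equivariant under image mirroring", {
  set.seed(11)
  hue <- matrix(120L, 24, 24)
  hue[4:9, 5:12] <- 20L
  hue[14:20, 10:16] <- 55L
  img <- hsv_from_hue(hue)
  mir <- hsv_from_hue(hue[, ncol(hue):1])
  a <- canonical_partition(modified_dbscan(img, 10)$group_ids)
  b <- canonical_partition(modified_dbscan(mir, 10)$group_ids)
  expect_identical(canonical_partition(b[, ncol(b):1]), a)
})

test_that("extract_groups sorts by size with tight boxes; empty map ok", {
  hue <- matrix(120L, 20, 20)
  hue[3:6, 3:6] <- 15L                      # 16 px
  hue[10:17, 8:15] <- 55L                   # 64 px
  map <- modified_dbscan(hsv_from_hue(hue), 10)
  groups <- extract_groups(map)
  sizes <- vapply(groups, `[[`, integer(1), "n_pixels")
  expect_true(all(diff(sizes) <= 0))        # descending
  for (g in groups) {
    expect_equal(g$bbox[["p1Y"]], min(g$pixels[, "y"]))
    expect_equal(g$bbox[["p2X"]], max(g$pixels[, "x"]))
    expect_equal(g$n_pixels, nrow(g$pixels))
  }
  empty <- modified_dbscan(hsv_from_hue(
    outer(1:12, 1:12, function(i, j) ifelse((i + j) %% 2 == 0, 0L, 90L))), 1)
  expect_identical(extract_groups(empty), list())
})

test_that("background discard removes only strictly oversized groups", {
  big <- rect_group(0L, 0L, 0L, 100L, 50L)     # 5000 px
  mid <- rect_group(1L, 0L, 60L, 30L, 10L)     # 300 px
  sml <- rect_group(2L, 50L, 60L, 12L, 10L)    # 120 px
  kept <- suppressMessages(discard_background(list(big, mid, sml), 100 * 100))
  expect_identical(vapply(kept, `[[`, integer(1), "id"), c(1L, 2L))

  edge <- rect_group(0L, 0L, 0L, 40L, 25L)     # exactly total/10
  expect_length(suppressMessages(discard_background(list(edge), 10000)), 1L)
  expect_identical(discard_background(list(), 100), list())
})
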