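# Binarization, 3D labeling, VVF, volume quartiles.

test_that("a two-valued stack binarizes to exactly its bright class", {
  x <- array(0, c(4, 4, 4)); x[1:2, , ] <- 100
  bv <- binarize(x)
  expect_identical(bv$mask, x == 100)
  expect_true(bv$threshold_used > 0 && bv$threshold_used < 100)
  expect_error(binarize(array(7, c(3, 3, 3))), "constant")
})

test_that("histogram threshold equals the exhaustive between-class-variance maximizer", {
  set.seed(31)
  for (i in 1:10) {
    # toy data summarized by an 8-bin histogram
    x <- c(rnorm(80, 10, 3), rnorm(40, 40, 5), runif(10, 0, 50))
    expect_equal(otsu_threshold(x, levels = 8L), otsu_brute(x, 8L))
  }
})

test_that("inverted-contrast stacks with invert = TRUE give the same mask", {
  x <- array(0, c(4, 4, 4)); x[, 1:2, ] <- 100
  inv <- max(x) + min(x) - x
  expect_identical(binarize(inv, invert = TRUE)$mask, binarize(x)$mask)
})

test_that("two consecutive slices concatenate axially with additive volume", {
  a <- array(runif(4 * 3 * 3), c(4, 3, 3))
  b <- array(runif(6 * 3 * 3), c(6, 3, 3))
  m <- merge_consecutive_slices(a, b)
  expect_identical(dim(m), c(10L, 3L, 3L))
  expect_identical(m[1:4, , ], a)
  expect_identical(m[5:10, , ], b)
  expect_error(merge_consecutive_slices(a, array(0, c(4, 2, 3))),
               "shapes differ")
})

test_that("VVF of a self-merged volume equals VVF of one slice", {
  net <- generate_vessel_network(
    segment_counts = c(capillary_venule = 5L),
    volume_shape = c(12L, 32L, 32L), seed = 11)
  st <- render_confocal(net, psf_sigma = 0, noise_sd = 0, background = 0)
  one <- compute_vvf(label_components_3d(binarize(st)))
  both <- compute_vvf(label_components_3d(binarize(
    merge_consecutive_slices(st, st))))
  expect_equal(both, one)
})

test_that("disjoint cubes are counted as separate objects with exact volumes", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:3, 1:3, 1:3] <- TRUE
  m[6:8, 6:8, 6:8] <- TRUE
  attr(m, "voxel_size") <- c(2, 2, 2)
  tab <- label_components_3d(m)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$voxel_count, c(27, 27))
  expect_equal(tab$volume_um3, c(216, 216))
  expect_identical(attr(tab, "total_volume_voxels"), 1000L)
})

test_that("corner-touching cubes merge under 26- but not 6-connectivity", {
  m <- array(FALSE, c(6, 6, 6))
  m[1:2, 1:2, 1:2] <- TRUE
  m[3:4, 3:4, 3:4] <- TRUE        # shares only the corner at (2,2,2)-(3,3,3)
  expect_identical(nrow(label_components_3d(m, connectivity = 26L)), 1L)
  expect_identical(nrow(label_components_3d(m, connectivity = 6L)), 2L)
})

test_that("3D labeling matches the flood-fill oracle on random masks", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- array(runif(16^3) > 0.75, c(16, 16, 16))
    for (conn in c(26L, 6L)) {
      tab <- label_components_3d(m, connectivity = conn)
      oracle <- flood_fill_labels(m, connectivity = conn)
      got <- attr(tab, "label_array")
      got[is.na(got)] <- 0L
      expect_identical(got, oracle)   # same raster-scan labeling order
      expect_identical(nrow(tab), max(oracle))
      expect_equal(sort(tab$voxel_count),
                   sort(as.integer(table(oracle[oracle > 0]))))
    }
  }
})

test_that("minimum-size filtering keeps ids contiguous", {
  m <- array(FALSE, c(8, 8, 8))
  m[1, 1, 1] <- TRUE                 # singleton
  m[4:6, 4:6, 4:6] <- TRUE           # 27 voxels
  tab <- label_components_3d(m, min_size = 2L)
  expect_identical(tab$id, 1L)
  expect_equal(tab$voxel_count, 27)
})

test_that("the VVF formula scales vessel voxels to percent of the section", {
  m <- array(FALSE, c(10, 10, 100))
  m[sample.int(10000, 1000)] <- TRUE   # exactly 1000 of 10000 voxels
  tab <- label_components_3d(m)
  expect_equal(compute_vvf(tab), 10)
  empty <- label_components_3d(array(FALSE, c(5, 5, 5)))
  expect_equal(compute_vvf(empty), 0)
  expect_identical(nrow(empty), 0L)
})

test_that("greedy volume quartiles follow the 25% first-crossing rule", {
  # hand-traced: volumes 40/30/20/10 -> one object per quartile
  m <- array(FALSE, c(7, 50, 50))
  put <- function(k, n) m[k, 1, seq_len(n)] <<- TRUE
  put(1, 40); put(3, 30); put(5, 20); put(7, 10)
  tab <- label_components_3d(m, connectivity = 6L)
  part <- volume_quartile_partition(tab)
  vols <- tab$voxel_count[order(tab$id)]
  expect_equal(part$n_objects, c(Q1 = 1L, Q2 = 1L, Q3 = 1L, Q4 = 1L))
  # the largest object sits alone in Q1, the smallest in Q4
  big <- tab$id[which.max(tab$voxel_count)]
  expect_identical(part$assignment$quartile[part$assignment$id == big], "Q1")
  expect_equal(unname(part$volume_share), c(40, 30, 20, 10))
})

test_that("a single object holds all volume in Q1 and Q2-Q4 stay empty", {
  m <- array(FALSE, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- TRUE
  part <- volume_quartile_partition(label_components_3d(m))
  expect_equal(unname(part$volume_share), c(100, 0, 0, 0))
  expect_equal(unname(part$n_objects), c(1L, 0L, 0L, 0L))
  expect_error(volume_quartile_partition(
    label_components_3d(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("per-quartile VVFs always sum to the total VVF (conservation)", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- array(runif(12^3) > 0.8, c(12, 12, 12))
    if (!any(m)) next
    tab <- label_components_3d(m)
    part <- volume_quartile_partition(tab)
    expect_equal(sum(part$vvf_per_quartile), part$vvf_total)
    expect_equal(sum(part$vvf_per_quartile), compute_vvf(tab))
    # greedy bound: every quartile within one largest-object volume of 25%
    bound <- 100 * max(tab$voxel_count) / sum(tab$voxel_count)
    expect_true(all(abs(part$volume_share - 25) <= bound + 1e-9))
  }
})

test_that("normalized vessel count is objects per cubic millimeter", {
  m <- array(FALSE, c(50, 100, 100))          # 0.5 mm^3 at 10 um voxels
  idx <- arrayInd(seq(1, 50 * 100 * 100, length.out = 50), dim(m))
  for (i in seq_len(nrow(idx))) m[idx[i, 1], idx[i, 2], idx[i, 3]] <- TRUE
  attr(m, "voxel_size") <- c(10, 10, 10)
  tab <- label_components_3d(m)
  expect_identical(nrow(tab), 50L)            # spots are disjoint by spacing
  expect_equal(normalized_vessel_count(tab), 100)
})

test_that("objects spanning the slice seam merge as the oracle says they do", {
  a <- array(FALSE, c(3, 6, 6)); a[3, 3, 3] <- TRUE    # touches the seam
  b <- array(FALSE, c(3, 6, 6)); b[1, 3, 3] <- TRUE
  merged <- merge_consecutive_slices(a, b)
  tab <- label_components_3d(merged)
  oracle <- flood_fill_labels(merged)
  expect_identical(nrow(tab), max(oracle))
  expect_identical(nrow(tab), 1L)             # seam-spanning voxels fuse
  # same two voxels apart do not fuse
  b2 <- array(FALSE, c(3, 6, 6)); b2[2, 3, 3] <- TRUE
  merged2 <- merge_consecutive_slices(a, b2)
  expect_identical(nrow(label_components_3d(merged2)),
                   max(flood_fill_labels(merged2)))
  expect_identical(nrow(label_components_3d(merged2)), 2L)
})

test_that("the largest caliber class dominates Q1 membership", {
  net <- generate_vessel_network(
    segment_counts = c(large_artery_vein = 1L, capillary_venule = 40L),
    volume_shape = c(64L, 96L, 96L), branch_prob = 0, seed = 77)
  tab <- label_components_3d(net$mask)
  part <- volume_quartile_partition(tab)
  # the component containing the large vessel's centerline is in Q1
  lab <- attr(tab, "label_array")
  seg <- net$segments[[1]]
  mid <- (seg$centerline[1, ] + seg$centerline[2, ]) / 2
  vox <- pmax(1, round(mid / net$voxel_size))
  big_id <- lab[vox[1], vox[2], vox[3]]
  expect_false(is.na(big_id))
  expect_identical(
    part$assignment$quartile[part$assignment$id == big_id], "Q1")
})
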