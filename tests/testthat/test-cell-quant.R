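test_that("intensity normalization divides by the bit-depth maximum", {
  m <- matrix(c(0, 255), 1, 2)
  t8 <- normalize_intensity(m, bit_depth = 8)
  expect_equal(as.numeric(t8$pixels), c(0, 1))

  const <- normalize_intensity(matrix(128, 4, 4), bit_depth = 8)
  expect_true(all(const$pixels == 128 / 255))

  # 16-bit: plain division, not min-max stretching
  t16 <- normalize_intensity(matrix(6554, 1, 1), bit_depth = 16)
  expect_equal(as.numeric(t16$pixels), 6554 / 65535)

  expect_error(normalize_intensity(matrix(300, 1, 1), bit_depth = 8),
               "exceed")
})

test_that("maximum projection equals the plane-wise elementwise maximum", {
  set.seed(11)
  stack <- array(runif(5 * 6 * 3), dim = c(5, 6, 3))
  proj <- max_project(stack)
  # loop oracle
  expected <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6) expected[i, j] <- max(stack[i, j, ])
  expect_identical(proj, expected)

  one <- array(runif(12), dim = c(3, 4, 1))
  expect_identical(max_project(one), one[, , 1])
  zero <- array(0, dim = c(3, 4, 2)); zero[, , 2] <- 7 * 0.1
  expect_identical(max_project(zero), zero[, , 2])
  expect_error(max_project(array(0, dim = c(3, 4, 0))), "plane")
})

test_that("morphological opening matches the brute-force sliding min/max oracle", {
  # flat field is invariant
  const <- matrix(0.37, 20, 20)
  expect_equal(open_filter(const, 3), const)

  # a 2 px bright line is suppressed by a radius-4 disk
  line <- matrix(0.05, 30, 30)
  line[14:15, ] <- 0.9
  opened <- open_filter(line, 4)
  expect_equal(opened, oracle_open(line, 4))
  expect_true(all(opened <= 0.05 + 1e-12))

  # a bright disk wider than the structuring element keeps its interior
  blob <- matrix(0.05, 30, 30)
  ctr <- expand.grid(r = 1:30, c = 1:30)
  blob[as.matrix(ctr[(ctr$r - 15)^2 + (ctr$c - 15)^2 <= 8^2, ])] <- 0.8
  opened_blob <- open_filter(blob, 4)
  expect_equal(opened_blob, oracle_open(blob, 4))
  expect_equal(opened_blob[15, 15], 0.8)

  # random images, several radii, bit-exact agreement with the oracle
  set.seed(21)
  for (rad in c(1, 2, 3.5)) {
    x <- matrix(runif(32 * 32), 32, 32)
    expect_equal(open_filter(x, rad), oracle_open(x, rad))
  }

  expect_error(open_filter(matrix(0, 10, 10), 6), "exceeds")
})

test_that("thresholding is strict and anti-monotone in the threshold", {
  m <- matrix(c(0.10, 0.14, 0.20), 1, 3)
  expect_identical(as.logical(binarize(m, 0.14)), c(FALSE, FALSE, TRUE))

  set.seed(3)
  x <- matrix(runif(400), 20, 20)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th) sum(binarize(x, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("connected-components labeling matches the flood-fill oracle", {
  # diagonal touch: one object under 8-connectivity, two under 4
  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_identical(nrow(label_objects(diag2, 8)$objects), 1L)
  expect_identical(nrow(label_objects(diag2, 4)$objects), 2L)

  expect_identical(nrow(label_objects(matrix(FALSE, 5, 5))$objects), 0L)

  set.seed(31)
  for (i in 1:6) {
    mask <- matrix(runif(20 * 20) < 0.35, 20, 20)
    for (conn in c(4L, 8L)) {
      got <- nrow(label_objects(mask, conn)$objects)
      expect_identical(got, oracle_component_count(mask, conn))
    }
  }

  # object IDs follow raster order of first pixels and areas are correct
  m <- matrix(FALSE, 5, 5)
  m[4:5, 1] <- TRUE   # first in column-major order
  m[1, 3] <- TRUE
  objs <- label_objects(m, 8)$objects
  expect_identical(objs$area_px, c(2L, 1L))
  expect_equal(objs$centroid_row, c(4.5, 1))
})

test_that("small-object removal uses a strict area floor", {
  mask <- matrix(FALSE, 10, 30)
  mask[2, 1:3] <- TRUE     # area 3
  mask[5, 1:4] <- TRUE     # area 4
  mask[8, 1:5] <- TRUE     # area 5
  mask[9:10, 10:12] <- TRUE # area 6
  objs <- label_objects(mask, 8)
  kept <- remove_small(objs, 5)
  expect_identical(sort(kept$objects$area_px), c(5L, 6L))
  expect_identical(nrow(remove_small(objs, 1)$objects), 4L)

  ones <- label_objects(diag(3) > 0, 4)
  expect_identical(nrow(remove_small(ones, 5)$objects), 0L)
})

test_that("the large-object QC fraction counts strict exceedances", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:2, 1:5] <- TRUE    # 10 px
  mask[10:15, 10:19] <- TRUE # 60 px
  objs <- label_objects(mask, 8)
  expect_equal(qc_large_fraction(objs, 50), 0.5)
  expect_equal(qc_large_fraction(objs, 100), 0)
  expect_equal(qc_large_fraction(label_objects(matrix(FALSE, 4, 4)), 50), 0)
})

test_that("erosion splitting separates bridged cells and retains annihilated objects", {
  # single disk of radius 4 stays one object
  disk_mask <- matrix(FALSE, 20, 20)
  g <- expand.grid(r = 1:20, c = 1:20)
  disk_mask[as.matrix(g[(g$r - 10)^2 + (g$c - 10)^2 <= 16, ])] <- TRUE
  one <- split_merged(label_objects(disk_mask, 8), 1)
  expect_identical(nrow(one$objects), 1L)

  # two radius-3 disks joined by a 1 px x 3 px bridge split into two;
  # checked against a brute-force binary erosion + flood fill oracle
  bridged <- matrix(FALSE, 20, 40)
  g <- expand.grid(r = 1:20, c = 1:40)
  bridged[as.matrix(g[(g$r - 10)^2 + (g$c - 12)^2 <= 9, ])] <- TRUE
  bridged[as.matrix(g[(g$r - 10)^2 + (g$c - 22)^2 <= 9, ])] <- TRUE
  bridged[10, 15:19] <- TRUE
  expect_identical(nrow(label_objects(bridged, 8)$objects), 1L)
  got <- split_merged(label_objects(bridged, 8), 1)
  oracle_eroded <- oracle_morph(bridged * 1, 1, min) > 0.5
  expect_identical(nrow(got$objects), 2L)
  expect_identical(nrow(got$objects), oracle_component_count(oracle_eroded, 8))

  # a 2x2 square vanishes under radius-1 erosion but is retained as one cell
  # at its original centroid
  sq <- matrix(FALSE, 10, 10)
  sq[5:6, 5:6] <- TRUE
  res <- split_merged(label_objects(sq, 8), 1)
  expect_identical(nrow(res$objects), 1L)
  expect_true(res$objects$retained)
  expect_equal(res$objects$centroid_row, 5.5)
  expect_equal(res$objects$centroid_col, 5.5)
})

test_that("counting and density follow the calibrated geometry", {
  # 100 cells in a 1 mm^2 ROI at 10 um depth -> 10,000 cells/mm^3
  set.seed(8)
  n <- 100
  mask <- matrix(FALSE, 1250, 1250)
  pos <- cbind(sample(5:1245, n), sample(5:1245, n))
  mask[pos] <- TRUE
  tile <- intensity_tile(matrix(0, 1250, 1250), 0.8, 10)
  objs <- label_objects(mask, 8)
  rec <- count_and_density(objs, tile)
  expect_equal(rec$volume_mm3, 0.01)
  expect_lte(abs(rec$count - n), 2) # adjacent draws may merge
  expect_equal(rec$density_cells_per_mm3, rec$count / 0.01)

  # empty objects -> zero density
  rec0 <- count_and_density(label_objects(matrix(FALSE, 100, 100)),
                            intensity_tile(matrix(0, 100, 100), 0.8, 10))
  expect_identical(rec0$count, 0L)
  expect_equal(rec0$density_cells_per_mm3, 0)

  # ROI restricts by centroid membership; zero-area ROI errors
  roi <- matrix(FALSE, 1250, 1250)
  roi[1:625, ] <- TRUE
  rec_half <- count_and_density(objs, tile, roi_mask = roi)
  expect_equal(rec_half$count, sum(pos[, 1] <= 625), tolerance = 0.05)
  expect_error(count_and_density(objs, tile,
                                 roi_mask = matrix(FALSE, 1250, 1250)),
               "zero-area")
})

test_that("the full pipeline is empty-safe and recovers generated densities monotonically", {
  blank <- intensity_tile(matrix(0, 300, 300), 0.8, 10)
  res <- count_cells(blank, seg_preset("WT"))
  expect_identical(res$record$count, 0L)
  expect_equal(res$record$density_cells_per_mm3, 0)

  densities <- c(500, 1000, 2000, 4000)
  est <- vapply(densities, function(d) {
    mean(vapply(1:2, function(i) {
      out <- generate_tile(tile_spec(true_density_cells_per_mm3 = d,
                                     seed = 100 * d + i))
      count_cells(out$tile, seg_preset("WT"))$record$density_cells_per_mm3
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("count validation averages absolute percent differences and guards zero references", {
  expect_equal(validate_counts(c(10, 20), c(10, 20)), 0)
  expect_equal(validate_counts(c(95, 105), c(100, 100)), 5)
  expect_warning(out <- validate_counts(c(5, 7), c(10, 0)), "zero reference")
  expect_equal(out, 50)
  expect_error(suppressWarnings(validate_counts(5, 0)), "no pairs")
})
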