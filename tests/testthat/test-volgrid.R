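# Volume/mask data model, NIfTI round trips, and the 3D grid primitives.

test_that("volume and mask constructors validate their invariants", {
  expect_error(volume(array(1, c(4, 4))), "3D")
  expect_error(volume(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)), "spacing")
  expect_error(binary_mask(array(c(0, 2), c(2, 1, 1))), "0 or 1")
  m <- binary_mask(array(c(TRUE, FALSE), c(2, 1, 1)))
  expect_identical(as.vector(m$data), c(1L, 0L))
})

test_that("NIfTI round trip reproduces data, shape and spacing exactly", {
  set.seed(1)
  v <- volume(array(rnorm(16^3), c(16, 16, 16)), spacing = c(1.25, 1.25, 1.25))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_identical(dim(v2$data), dim(v$data))
  expect_equal(v2$data, v$data, tolerance = 0)
  expect_equal(v2$spacing, v$spacing)

  m <- binary_mask(array(as.integer(runif(16^3) < 0.2), c(16, 16, 16)))
  mpath <- tempfile(fileext = ".nii.gz")
  write_mask(m, mpath)
  expect_identical(read_mask(mpath)$data, m$data)
})

test_that("mask files with values {0, 255} are normalized with a warning", {
  arr <- array(0, c(8, 8, 8))
  arr[3:5, 3:5, 3:5] <- 255
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  expect_warning(m <- read_mask(path), "normalized")
  expect_identical(sort(unique(as.vector(m$data))), c(0L, 1L))
  expect_equal(sum(m$data), 27)
})

test_that("4D input is rejected", {
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4, 3))), path)
  expect_error(read_volume(path), "3D")
  expect_error(read_mask(path), "3D")
})

test_that("dsc matches direct voxel counting and its edge cases", {
  a <- array(0L, c(4, 4, 2))
  a[1:2, 1:2, 1] <- 1L            # |A| = 4
  b <- array(0L, c(4, 4, 2))
  b[2:3, 1:2, 1] <- 1L            # |B| = 4, |A^B| = 2
  expect_equal(dsc(a, b), 0.5)
  expect_equal(dsc(a, a), 1.0)
  disj <- array(0L, c(4, 4, 2))
  disj[4, 4, 2] <- 1L
  expect_equal(dsc(a, disj), 0)
  expect_error(dsc(array(0L, c(4, 4, 2)), array(0L, c(4, 4, 2))), "empty")
  expect_error(dsc(a, array(0L, c(4, 4, 1))), "shape")
})

test_that("dsc is symmetric on random mask pairs", {
  set.seed(7)
  for (i in 1:50) {
    a <- random_mask(c(6, 6, 6), 0.4)
    b <- random_mask(c(6, 6, 6), 0.4)
    if (sum(a) + sum(b) == 0) next
    expect_identical(dsc(a, b), dsc(b, a))
  }
})

test_that("largest_component matches the flood-fill oracle", {
  set.seed(11)
  for (conn in c(6, 18, 26)) {
    for (i in 1:40) {
      m <- random_mask(c(8, 8, 8), 0.25)
      if (sum(m) == 0) next
      expect_identical(largest_component(m, conn)$data,
                       flood_fill_largest(m, conn),
                       info = sprintf("conn=%d i=%d", conn, i))
    }
  }
})

test_that("largest_component tie-break keeps the smallest linear index", {
  m <- array(0L, c(8, 8, 8))
  m[2:4, 2, 2] <- 1L    # 3-voxel component containing small linear index
  m[5:7, 7, 7] <- 1L    # 3-voxel component later in scan order
  out <- largest_component(m, 26)$data
  expect_equal(sum(out), 3)
  expect_equal(out[2, 2, 2], 1L)
  expect_equal(out[5, 7, 7], 0L)
  expect_error(largest_component(array(0L, c(4, 4, 4))), "empty")
})

test_that("dilation matches its definition and the brute-force oracle", {
  e <- binary_mask(array(0L, c(5, 5, 5)))
  expect_equal(sum(dilate_mask(e)$data), 0)

  one <- array(0L, c(5, 5, 5))
  one[3, 3, 3] <- 1L
  expect_equal(sum(dilate_mask(one, "cross6")$data), 7)

  corner <- array(0L, c(5, 5, 5))
  corner[1, 1, 1] <- 1L
  expect_equal(sum(dilate_mask(corner, "cube26")$data), 8)

  set.seed(3)
  for (i in 1:30) {
    m <- random_mask(c(7, 7, 7), 0.2)
    for (el in c("cross6", "cube26"))
      expect_identical(dilate_mask(m, el)$data, dilate_oracle(m, el))
  }
})

test_that("dilation is extensive and monotone", {
  set.seed(4)
  for (i in 1:25) {
    m1 <- random_mask(c(7, 7, 7), 0.15)
    m2 <- m1
    extra <- which(m2 == 0L)
    m2[sample(extra, min(10, length(extra)))] <- 1L   # m1 subset of m2
    d1 <- dilate_mask(m1)$data
    d2 <- dilate_mask(m2)$data
    expect_true(all(d1 >= m1))
    expect_true(all(d2 >= d1))
  }
})

test_that("percentile uses linear interpolation between order statistics", {
  expect_equal(pctile(c(1, 2, 3), 50), 2)
  expect_equal(pctile(rep(4.2, 10), 73), 4.2)
  expect_equal(pctile(c(10, 20, 30, 40), 66), 29.8)
  expect_equal(pctile(c(5, 1, 9), 0), 1)
  expect_equal(pctile(c(5, 1, 9), 100), 9)
  expect_error(pctile(numeric(0), 50), "empty")
  set.seed(5)
  for (i in 1:40) {
    v <- rnorm(sample(1:30, 1))
    q <- runif(1, 0, 100)
    expect_equal(pctile(v, q), percentile_oracle(v, q))
    perm <- v[sample.int(length(v))]
    expect_equal(pctile(perm, q), pctile(v, q))         # permutation-invariant
  }
})

test_that("percentile is non-decreasing in q", {
  set.seed(6)
  v <- rnorm(25)
  qs <- sort(runif(20, 0, 100))
  ps <- vapply(qs, function(q) pctile(v, q), numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("binarize_band is inclusive at both ends", {
  v <- array(1:27, c(3, 3, 3))
  expect_equal(sum(binarize_band(v, 1, 27)$data), 27)
  expect_equal(sum(binarize_band(v, 10, 20)$data), 11)
  expect_equal(which(binarize_band(v, 13, 13)$data == 1L), 13L)
  expect_error(binarize_band(v, 5, 2), "lo")
})
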