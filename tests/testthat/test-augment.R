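# Joint image/mask augmentation: normalization, flips, crops, rigid affine
# with b-spline interpolation, and the composed pipeline.

test_that("intensity normalization rescales the maximum to exactly 1", {
  v <- array(runif(4^3) * 500, c(4, 4, 4))
  nv <- normalize_intensity(v)
  expect_equal(max(nv$data), 1)
  expect_identical(normalize_intensity(nv$data)$data, nv$data)  # idempotent
  two <- array(c(100, 50, rep(1, 6)), c(2, 2, 2))
  expect_equal(normalize_intensity(two)$data[1:2], c(1, 0.5))
  expect_error(normalize_intensity(array(0, c(2, 2, 2))), "positive")
})

test_that("flips permute jointly, deterministically, and are involutions", {
  set.seed(1)
  v <- array(rnorm(6^3), c(6, 6, 6))
  m <- random_mask(c(6, 6, 6), 0.3)
  f1 <- random_flip(v, m, seed = 5L)
  expect_equal(sum(f1$mask$data), sum(m))
  f2 <- random_flip(v, m, seed = 5L)
  expect_identical(f1$volume$data, f2$volume$data)
  # applying the same flip pattern to the flipped pair restores the input
  f3 <- random_flip(f1$volume, f1$mask, seed = 5L)
  expect_identical(f3$volume$data, v)
  expect_identical(f3$mask$data, m)
})

test_that("random crop produces the requested shape with one shared offset", {
  set.seed(2)
  v <- array(rnorm(20^3), c(20, 20, 20))
  m <- array(0L, c(20, 20, 20))
  m[9:12, 9:12, 9:12] <- 1L
  cr <- random_crop(v, m, c(16, 16, 16), seed = 3L)
  expect_identical(dim(cr$volume$data), c(16L, 16L, 16L))
  # image and mask share the offset: masked intensities survive cropping
  expect_setequal(unique(v[m == 1L]),
                  unique(cr$volume$data[cr$mask$data == 1L]))

  # smaller input is zero-padded
  small <- array(1, c(8, 8, 8))
  sm <- array(1L, c(8, 8, 8))
  pd <- random_crop(small, sm, c(12, 12, 12), seed = 1L)
  expect_identical(dim(pd$volume$data), c(12L, 12L, 12L))
  expect_equal(sum(pd$volume$data), 8^3)
  expect_equal(sum(pd$mask$data), 8^3)

  # crop equal to the input size is the identity
  idc <- random_crop(v, m, c(20, 20, 20), seed = 9L)
  expect_identical(idc$volume$data, v)
})

test_that("identity affine reproduces the input to floating tolerance", {
  set.seed(3)
  v <- array(rnorm(12^3), c(12, 12, 12))
  m <- random_mask(c(12, 12, 12), 0.3)
  pr <- augment_params(crop_size = c(12, 12, 12), max_rotation = 0,
                       max_translation = 0)
  af <- random_affine(v, m, pr, seed = 1L)
  expect_lt(max(abs(af$volume$data - v)), 1e-6)
  expect_identical(af$mask$data, m)
})

test_that("integer translation preserves the in-field mask voxel count", {
  m <- array(0L, c(16, 16, 16))
  m[6:9, 6:9, 6:9] <- 1L
  shifted <- chiasmseg:::affine_resample(m * 1.0, diag(3), c(3, -2, 4), "nearest")
  expect_equal(sum(shifted), sum(m))   # structure stays in field
  # shift-and-count oracle
  oracle <- array(0L, c(16, 16, 16))
  oracle[6:9 + 3, 6:9 - 2, 6:9 + 4] <- 1L
  expect_identical(array(as.integer(shifted), dim(shifted)), oracle)
})

test_that("rotation draws never exceed the configured bound", {
  v <- array(rnorm(8^3), c(8, 8, 8))
  m <- random_mask(c(8, 8, 8), 0.3)
  pr <- augment_params(crop_size = c(8, 8, 8), max_rotation = 15,
                       max_translation = 20)
  set.seed(4)
  angs <- replicate(300, {
    af <- random_affine(v, m, pr)
    max(abs(attr(af, "angles")))
  })
  expect_true(all(angs <= 15))
  expect_gt(max(angs), 10)   # bound is actually exercised
})

test_that("image and mask receive the identical spatial transform", {
  set.seed(5)
  m <- random_mask(c(12, 12, 12), 0.25)
  pr_near <- augment_params(crop_size = c(12, 12, 12),
                            image_interpolation = "nearest")
  # transform a copy of the mask as the image with nearest interpolation
  af <- random_affine(m * 1.0, m, pr_near, seed = 8L)
  expect_identical(array(as.integer(af$volume$data > 0.5), dim(af$mask$data)),
                   af$mask$data)
})

test_that("the composed pipeline keeps masks binary and is reproducible", {
  s <- make_phantom(tiny_phantom_params(seed = 31L))
  pr <- augment_params(crop_size = c(32, 32, 32), max_rotation = 15,
                       max_translation = 8)
  a1 <- augment(s$volume, s$manual_mask, pr, seed = 10L)
  a2 <- augment(s$volume, s$manual_mask, pr, seed = 10L)
  expect_identical(a1$volume$data, a2$volume$data)
  expect_identical(a1$mask$data, a2$mask$data)
  expect_true(all(a1$mask$data %in% c(0L, 1L)))
  expect_identical(dim(a1$volume$data), c(32L, 32L, 32L))
})

test_that("b-spline overshoot beyond the normalized maximum stays below 5%", {
  s <- make_phantom(tiny_phantom_params(seed = 77L))
  pr <- augment_params(crop_size = c(32, 32, 32), max_rotation = 15,
                       max_translation = 8)
  mx <- vapply(1:60, function(i)
    max(augment(s$volume, s$manual_mask, pr, seed = i)$volume$data), numeric(1))
  expect_true(all(mx <= 1.05))
})
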