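# Synthetic phantom generator: geometry, intensity model, determinism,
# corruption behavior, and cohort manifests.

test_that("phantom generation is deterministic and seed-sensitive", {
  p <- tiny_phantom_params(seed = 5L)
  s1 <- make_phantom(p)
  s2 <- make_phantom(p)
  expect_identical(s1$volume$data, s2$volume$data)
  expect_identical(s1$manual_mask$data, s2$manual_mask$data)
  s3 <- make_phantom(tiny_phantom_params(seed = 6L))
  expect_false(identical(s1$volume$data, s3$volume$data))
})

test_that("without degradation every mask voxel sits exactly at wm intensity", {
  p <- tiny_phantom_params(seed = 2L, noise_sd = 0, blur_sd = 0)
  s <- make_phantom(p)
  inside <- s$volume$data[s$manual_mask$data == 1L]
  expect_true(all(inside == p$wm_intensity))
  # trimodal intensity histogram: background / white matter / vessel only
  vals <- sort(unique(as.vector(s$volume$data)))
  expect_setequal(vals, c(p$background_intensity, p$wm_intensity,
                          p$vessel_intensity))
})

test_that("manual mask is one nonempty 26-connected component", {
  for (seed in c(1L, 9L, 23L)) {
    s <- make_phantom(tiny_phantom_params(seed = seed))
    expect_gt(sum(s$manual_mask$data), 0)
    comp <- largest_component(s$manual_mask, 26)
    expect_identical(comp$data, s$manual_mask$data)
  }
})

test_that("malformation shrinks the mask of a seed-matched control", {
  pc <- tiny_phantom_params(seed = 4L)
  pm <- tiny_phantom_params(seed = 4L, malformed = TRUE)
  nc <- sum(make_phantom(pc)$manual_mask$data)
  nm <- sum(make_phantom(pm)$manual_mask$data)
  expect_lt(nm, nc)
  expect_identical(make_phantom(pm)$label, "malformed")
})

test_that("a structure too large for the grid is rejected", {
  expect_error(make_phantom(phantom_params(grid_shape = c(16, 16, 16),
                                           chiasm_width = 14, nerve_width = 12,
                                           width_jitter = 0)),
               "fit")
})

test_that("corruption is seeded, near-identity at low severity, monotone", {
  s <- make_phantom(tiny_phantom_params(seed = 3L))
  m1 <- corrupt_to_initial(s, 42L, severity = 0.5)
  m2 <- corrupt_to_initial(s, 42L, severity = 0.5)
  expect_identical(m1$data, m2$data)

  gentle <- corrupt_to_initial(s, 42L, severity = 0.01)
  expect_gte(dsc(gentle, s$manual_mask), 0.95)

  sev_means <- vapply(c(0.2, 0.6, 1.0), function(sev) {
    mean(vapply(1:12, function(i)
      dsc(corrupt_to_initial(s, 100L + i, sev), s$manual_mask), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sev_means) < 0))
})

test_that("cohorts have the requested composition and deterministic manifests", {
  co <- make_cohort(8, 9, tiny_phantom_params(), master_seed = 21L)
  expect_length(co$samples, 17)
  expect_equal(sum(co$manifest$label == "control"), 8)
  expect_equal(sum(co$manifest$label == "malformed"), 9)
  expect_false(any(duplicated(co$manifest$seed)))

  empty <- make_cohort(0, 0, tiny_phantom_params(), master_seed = 21L)
  expect_equal(nrow(empty$manifest), 0)

  dir <- tempfile()
  make_cohort(2, 1, tiny_phantom_params(), master_seed = 5L, out_dir = dir)
  bytes1 <- readBin(file.path(dir, "manifest.csv"), "raw", 1e6)
  make_cohort(2, 1, tiny_phantom_params(), master_seed = 5L, out_dir = dir)
  bytes2 <- readBin(file.path(dir, "manifest.csv"), "raw", 1e6)
  expect_identical(bytes1, bytes2)
  expect_true(file.exists(file.path(dir, "sub-001_T1w.nii.gz")))
  v <- read_volume(file.path(dir, "sub-001_T1w.nii.gz"))
  expect_identical(dim(v$data), c(32L, 32L, 32L))
})

test_that("malformed phantoms share the control intensity model", {
  pc <- tiny_phantom_params(seed = 8L, noise_sd = 0, blur_sd = 0)
  pm <- tiny_phantom_params(seed = 8L, noise_sd = 0, blur_sd = 0,
                            malformed = TRUE)
  vc <- sort(unique(as.vector(make_phantom(pc)$volume$data)))
  vm <- sort(unique(as.vector(make_phantom(pm)$volume$data)))
  expect_identical(vc, vm)
})
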