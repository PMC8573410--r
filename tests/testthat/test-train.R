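# Dataset splitting, the training loop, prediction, and mask extraction.

test_that("split_dataset partitions 1049 ids into 932/107/10", {
  ids <- sprintf("sub-%04d", 1:1049)
  sp <- split_dataset(ids, c(932, 107, 10), seed = 1L)
  expect_length(sp$train, 932)
  expect_length(sp$validation, 107)
  expect_length(sp$test, 10)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  sp2 <- split_dataset(ids, c(932, 107, 10), seed = 1L)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(ids, c(932, 107, 10), seed = 2L)))
  expect_error(split_dataset(ids, c(900, 100, 10)), "sum")
})

test_that("training records one loss per epoch and responds to validation", {
  s <- make_phantom(tiny_phantom_params(seed = 60L))
  pair <- list(image = normalize_intensity(s$volume), target = s$manual_mask)
  fit <- train_unet(list(pair), net_config(3L, 2L),
                    train_config(batch_size = 1L, max_epochs = 4L, seed = 2L),
                    validation = list(pair))
  expect_equal(fit$history$epoch, 1:4)
  expect_false(any(is.na(fit$history$val_loss)))
  expect_lt(fit$history$val_loss[4], 1)
})

test_that("training is reproducible under a fixed seed", {
  s <- make_phantom(tiny_phantom_params(seed = 61L))
  pair <- list(image = normalize_intensity(s$volume), target = s$manual_mask)
  cfg <- train_config(batch_size = 1L, max_epochs = 2L, seed = 5L)
  f1 <- train_unet(list(pair), net_config(3L, 2L), cfg)
  f2 <- train_unet(list(pair), net_config(3L, 2L), cfg)
  expect_identical(f1$net$params, f2$net$params)
  expect_identical(f1$history, f2$history)
})

test_that("grid mode runs exactly the five default combinations", {
  grid <- default_hyperparameter_grid()
  expect_identical(grid$epochs, c(13L, 15L, 30L, 40L, 100L))
  expect_identical(grid$learning_rate, c(0.0025, 0.0030, 0.0025, 0.0015, 0.0005))

  # tiny problem so the full grid runs in seconds
  x <- array(rnorm(8^3, sd = 0.1), c(8, 8, 8))
  y <- array(0L, c(8, 8, 8)); y[4:5, 4:5, 4:5] <- 1L
  fits <- train_grid(list(list(image = x, target = y)), net_config(2L, 1L),
                     train_config(batch_size = 1L, seed = 3L,
                                  grid = grid[1:5, ]))
  expect_length(fits, 5)
  expect_equal(vapply(fits, function(f) nrow(f$history), integer(1)),
               grid$epochs)
  expect_equal(vapply(fits, function(f) f$learning_rate, numeric(1)),
               grid$learning_rate)
})

test_that("prediction pads odd sizes and returns probabilities in [0,1]", {
  net <- build_unet(net_config(3L, 2L), seed = 4L)
  x <- array(runif(10 * 12 * 10), c(10, 12, 10))   # not multiples of 4
  p <- predict_probability(net, x)
  expect_identical(dim(p$fg), c(10L, 12L, 10L))
  expect_true(all(p$fg >= 0 & p$fg <= 1))
})

test_that("mask extraction thresholds then keeps the biggest cluster", {
  p <- array(0, c(10, 10, 10))
  p[2:4, 2:4, 2:4] <- 1.0                  # 27-voxel plateau at 1.0
  scatter <- rbind(c(8, 8, 8), c(1, 9, 5), c(9, 1, 2))
  p[scatter] <- 0.6                         # sub-threshold scatter
  m <- extract_cnn_mask(p, inference_params(threshold = 1.0))
  expect_equal(sum(m$data), 27)
  expect_true(all(m$data[2:4, 2:4, 2:4] == 1L))

  # two suprathreshold clusters: sizes 12 and 5 -> the 12-cluster
  q <- array(0, c(10, 10, 10))
  q[2:4, 2:5, 2] <- 0.9                    # 12 voxels
  q[7:8, 7:8, 7] <- 0.9; q[7, 7, 8] <- 0.9 # 5 voxels
  m2 <- extract_cnn_mask(q, inference_params(threshold = 0.75))
  expect_equal(sum(m2$data), 12)
  expect_equal(sum(m2$data[2:4, 2:5, 2]), 12)

  # threshold monotonicity before cluster selection
  r <- array(runif(1000), c(10, 10, 10))
  hi <- r >= 0.75 - 1e-6
  lo <- r >= 0.25 - 1e-6
  expect_true(all(lo[hi]))

  expect_warning(empty <- extract_cnn_mask(array(0, c(4, 4, 4))), "empty")
  expect_equal(sum(empty$data), 0)

  # values strictly below threshold - epsilon are irrelevant
  p2 <- p
  p2[p2 < 0.999] <- runif(sum(p2 < 0.999), 0, 0.9)
  m3 <- extract_cnn_mask(p2, inference_params(threshold = 1.0))
  expect_identical(m3$data, m$data)
})

test_that("inference parameters are validated", {
  expect_error(inference_params(threshold = 0), "threshold")
  expect_error(inference_params(threshold = 1.2), "threshold")
})
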