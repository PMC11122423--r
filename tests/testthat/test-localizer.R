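# Small-network tests for the U-Net localizer. Training-scale behavior
# (JI/RMSE on held-out frames) lives in test-acceptance.R.

test_that("localization loss matches its definition on hand-built grids", {
  z <- matrix(0, 16, 16)
  expect_equal(loss_loc(z, z), 0)

  # perfect prediction of a unit spike leaves only the L1 penalty
  t1 <- z; t1[5, 7] <- 1
  expect_equal(loss_loc(t1, t1, g_sigma = 1), 1)

  # zero prediction against one unit spike: MSE term is sum(g^2)
  # (g is the loss kernel: Gaussian normalized to unit peak)
  g <- dssmlm:::.loss_kernel(1)
  expect_equal(loss_loc(z, t1, g_sigma = 1), sum(g^2), tolerance = 1e-12)

  # independent R convolution oracle on a random pair
  set.seed(4)
  a <- matrix(runif(256), 16, 16)
  b <- matrix(runif(256), 16, 16)
  blur <- dssmlm:::cpp_conv_same(a - b, g)
  # brute-force same-padding convolution
  ref <- matrix(0, 16, 16)
  d <- a - b
  pad <- matrix(0, 16 + 6, 16 + 6)
  pad[4:19, 4:19] <- d
  for (i in 1:16) for (j in 1:16)
    ref[i, j] <- sum(pad[i:(i + 6), j:(j + 6)] * g)
  expect_equal(blur, ref, tolerance = 1e-12)
  expect_equal(loss_loc(a, b), sum(ref^2) + sum(abs(a)), tolerance = 1e-9)

  expect_error(loss_loc(z, matrix(0, 8, 8)), "same shape")
})

test_that("epochs = 0 returns an untrained model, reproducibly", {
  st <- fix_stack_small()
  pairs <- make_spatial_training_set(st, st$truth, fix_optics(),
                                     patch_size = 16L, upsampling = 2L,
                                     n_pairs = 4L, seed = 1,
                                     min_emitters = 1L)
  spec <- localizer_spec(depth = 1L, base_filters = 2L, upsampling = 2L)
  m1 <- train_localizer(pairs, spec, epochs = 0L, seed = 3)
  m2 <- train_localizer(pairs, spec, epochs = 0L, seed = 3)
  expect_equal(nrow(m1$history), 0L)
  expect_identical(m1$params, m2$params)
  # no optimizer step happened: parameters are a fresh He initialization
  expect_equal(m1$params$out_b, 0)
})

test_that("training reduces the loss on a small fixed dataset", {
  st <- fix_stack_small()
  pairs <- make_spatial_training_set(st, st$truth, fix_optics(),
                                     patch_size = 16L, upsampling = 2L,
                                     n_pairs = 120L, seed = 2,
                                     min_emitters = 1L)
  spec <- localizer_spec(depth = 1L, base_filters = 4L, upsampling = 2L)
  m <- train_localizer(pairs, spec, epochs = 6L, seed = 3)
  h <- m$history
  expect_equal(nrow(h), 6L)
  expect_lt(h$train_loss[6], h$train_loss[1])
  expect_true(all(is.finite(h$val_loss)))
})

test_that("training is deterministic under a fixed seed", {
  st <- fix_stack_small()
  pairs <- make_spatial_training_set(st, st$truth, fix_optics(),
                                     patch_size = 16L, upsampling = 2L,
                                     n_pairs = 30L, seed = 2,
                                     min_emitters = 1L)
  spec <- localizer_spec(depth = 1L, base_filters = 2L, upsampling = 2L)
  m1 <- train_localizer(pairs, spec, epochs = 2L, seed = 7)
  m2 <- train_localizer(pairs, spec, epochs = 2L, seed = 7)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("local maxima agree with an exhaustive neighborhood scan", {
  set.seed(6)
  g <- matrix(runif(900), 30, 30)
  pk <- find_local_maxima(g, threshold = 0.2, min_separation = 0)
  # brute force: strictly-not-smaller than all 8 neighbors, above threshold
  ref <- NULL
  thr <- 0.2 * max(g)
  for (i in 1:30) for (j in 1:30) {
    v <- g[i, j]
    if (v <= thr) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 >= 1 && i2 <= 30 && j2 >= 1 && j2 <= 30) nb <- c(nb, g[i2, j2])
    }
    if (all(v >= nb)) ref <- rbind(ref, c(i - 1, j - 1))
  }
  expect_equal(nrow(pk), nrow(ref))
  expect_setequal(paste(pk$row, pk$col), paste(ref[, 1], ref[, 2]))

  # two spikes 20 px apart are both found at their positions
  z <- matrix(0, 40, 40)
  z[10, 10] <- 1
  z[10, 30] <- 0.9
  zb <- dssmlm:::.gauss_blur2d(z, 1.5)
  pk2 <- find_local_maxima(zb, threshold = 0.2, min_separation = 4)
  expect_equal(nrow(pk2), 2L)
  expect_setequal(paste(pk2$row, pk2$col), c("9 9", "9 29"))

  # all-zero grid: nothing
  expect_equal(nrow(find_local_maxima(matrix(0, 5, 5))), 0L)

  # merging keeps the brighter of two close maxima
  z2 <- matrix(0, 20, 20)
  z2[8, 8] <- 1
  z2[8, 11] <- 0.8
  pk3 <- find_local_maxima(z2, threshold = 0.1, min_separation = 5)
  expect_equal(nrow(pk3), 1L)
  expect_equal(c(pk3$row, pk3$col), c(7, 7))
})

test_that("a one-pixel input shift moves the prediction by one pixel", {
  # pooling makes the network exactly equivariant to shifts that are
  # multiples of 2^depth fine pixels; one camera pixel at U = 4, depth 2
  # is exactly such a shift
  opt <- fix_optics(background_rate = 0, read_noise_sd = 0)
  dy <- fix_af647()
  dims <- dssmlm:::.frame_dims(opt, list(dy))
  mk <- function(xpx) {
    tr <- data.frame(frame = 1L, x_nm = xpx * opt$camera_pixel_size,
                     y_nm = 30 * opt$camera_pixel_size, photons = 2000,
                     dye = "AF647")
    dssmlm:::.render_expected(tr, opt, setNames(list(dy), "AF647"), dims,
                              spectral = FALSE)$spatial
  }
  f1 <- mk(30)[1:32, 1:32]
  f2 <- mk(31)[1:32, 1:32]
  spec <- localizer_spec(depth = 2L, base_filters = 4L, upsampling = 4L)
  # an untrained model suffices: equivariance is architectural
  m <- structure(list(params = dssmlm:::.init_localizer_params(spec, seed = 1),
                      spec = spec,
                      history = data.frame()), class = "localizer_model")
  g1 <- dssmlm:::.predict_grid(m, f1)
  g2 <- dssmlm:::.predict_grid(m, f2)
  # interior comparison: g2 shifted left by 4 fine px equals g1
  U <- 4L
  keep <- 33:96
  expect_equal(g2[keep, keep + U], g1[keep, keep], tolerance = 1e-4)
})
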