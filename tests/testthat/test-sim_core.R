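test_that("noise-free render conserves photon mass across both channels", {
  opt <- fix_optics(background_rate = 0, read_noise_sd = 0)
  dy <- fix_af647()
  tr <- data.frame(frame = 1L, x_nm = 3500, y_nm = 3600, photons = 1000,
                   dye = "AF647")
  dims <- dssmlm:::.frame_dims(opt, list(dy))
  ex <- dssmlm:::.render_expected(tr, opt, setNames(list(dy), "AF647"), dims)

  # quadrature oracle: Riemann integration of the 2-D Gaussian on a fine grid
  px <- opt$camera_pixel_size
  sig <- opt$psf_sigma / px
  h <- 0.02
  g1 <- function(mu, n) {
    x <- seq(-0.5, n - 0.5, by = h)
    v <- dnorm(x, mu, sig)
    sum(v) * h
  }
  frac <- g1(3500 / px, dims$nx) * g1(3600 / px, dims$ny)
  expect_equal(sum(ex$spatial), (1 - opt$split_ratio) * 1000 * frac,
               tolerance = 0.005)
  # spectral channel carries the split_ratio fraction
  expect_equal(sum(ex$spectral), opt$split_ratio * 1000,
               tolerance = 0.005)
  expect_true(all(ex$spatial >= 0) && all(ex$spectral >= 0))
})

test_that("background-only frames have mean equal to background_rate", {
  opt <- fix_optics(background_rate = 10, read_noise_sd = 0,
                    fov = c(3.52, 3.52))
  st <- simulate_stack(opt, fix_af647(), n_frames = 50, density = 1e-9,
                       seed = 3)
  expect_equal(nrow(st$truth), 0L)
  m <- mean(vapply(st$frames, function(f) mean(f$spatial_image), numeric(1)))
  expect_equal(m, 10, tolerance = 0.05)
})

test_that("shot noise is Poisson: per-pixel variance tracks the mean", {
  opt <- fix_optics(background_rate = 8, read_noise_sd = 0,
                    fov = c(1.76, 1.76))
  st <- simulate_stack(opt, fix_af647(), n_frames = 1200, density = 1e-9,
                       seed = 4, render_spectral = FALSE)
  arr <- vapply(st$frames, function(f) f$spatial_image,
                st$frames[[1]]$spatial_image)
  mu <- apply(arr, c(1, 2), mean)
  v <- apply(arr, c(1, 2), var)
  expect_equal(mean(v) / mean(mu), 1, tolerance = 0.05)
})

test_that("identical seeds give bit-identical stacks and truths", {
  a <- simulate_stack(fix_optics(), fix_af647(), 4, density = 0.1, seed = 42)
  b <- simulate_stack(fix_optics(), fix_af647(), 4, density = 0.1, seed = 42)
  expect_identical(a$truth, b$truth)
  expect_identical(a$frames[[3]]$spatial_image, b$frames[[3]]$spatial_image)
  expect_identical(a$frames[[3]]$spectral_image, b$frames[[3]]$spectral_image)
  # truth list is invariant to the noise switch under the same seed
  c <- simulate_stack(fix_optics(), fix_af647(), 4, density = 0.1, seed = 42,
                      add_noise = FALSE)
  expect_identical(a$truth, c$truth)
})

test_that("emitter counts are Poisson at density x area", {
  opt <- fix_optics(fov = c(25.6, 25.6))
  st <- simulate_stack(opt, fix_af647(), n_frames = 1000, density = 0.1,
                       seed = 8, render_spectral = FALSE)
  mu <- 0.1 * 25.6^2  # 65.536 expected emitters per frame
  counts <- tabulate(st$truth$frame, nbins = 1000)
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 1000))
})

test_that("invalid configurations are rejected", {
  expect_error(optics_config(split_ratio = 1.2), "split_ratio")
  expect_error(optics_config(fov = c(0.2, 0.2)), "too small")
  dy <- fix_af647()
  tr <- data.frame(frame = 1L, x_nm = 100, y_nm = 100, photons = 10,
                   dye = "nope")
  dims <- dssmlm:::.frame_dims(fix_optics(), list(dy))
  expect_error(
    dssmlm:::.render_expected(tr, fix_optics(), setNames(list(dy), "AF647"),
                              dims),
    "unknown dye")
})

test_that("spatial training patches obey the min-emitter rule and spike rounding", {
  st <- fix_stack_small()
  pairs <- make_spatial_training_set(st, st$truth, fix_optics(),
                                     patch_size = 32L, upsampling = 4L,
                                     n_pairs = 25L, seed = 1)
  expect_gt(length(pairs), 0)
  expect_true(all(vapply(pairs, `[[`, integer(1), "emitter_count") >= 3L))
  for (p in pairs[seq_len(min(3, length(pairs)))]) {
    g <- spatial_target_grid(p)
    expect_equal(sum(g), p$emitter_count)
    expect_true(all(g >= 0))
    expect_identical(dim(g), c(128L, 128L))
  }

  # independent rounding oracle: an emitter at patch position (10.3, 20.7) px
  # must land on fine-grid index (col 41, row 83) at upsampling 4
  opt <- fix_optics(background_rate = 0, read_noise_sd = 0)
  px <- opt$camera_pixel_size
  truth <- data.frame(frame = 1L,
                      x_nm = c(10.3, 3.1, 20.0) * px,
                      y_nm = c(20.7, 5.0, 11.2) * px,
                      photons = rep(1000, 3), dye = "AF647")
  st1 <- simulate_stack(opt, fix_af647(), 1, density = 1e-9, seed = 1,
                        add_noise = FALSE)
  pr <- make_spatial_training_set(st1$frames, truth, opt, patch_size = 32L,
                                  upsampling = 4L, n_pairs = 1L, seed = 1)
  sp <- pr[[1]]$spikes
  expect_true(any(sp[, "col"] == round(10.3 * 4) & sp[, "row"] == round(20.7 * 4)))
  expect_equal(sort(sp[, "col"]), sort(as.integer(round(c(10.3, 3.1, 20) * 4))))
})

test_that("patches below the emitter minimum are excluded and shortfall warned", {
  st <- fix_stack_clean()
  expect_warning(
    pairs <- make_spatial_training_set(st, st$truth, fix_optics(),
                                       patch_size = 32L, n_pairs = 1e6L,
                                       seed = 2),
    "requested")
  counts <- vapply(pairs, `[[`, integer(1), "emitter_count")
  expect_true(all(counts >= 3L))
})

test_that("spectral training pairs have the mode's ROI shape", {
  st <- fix_stack_small()
  pr <- make_spectral_training_set(st$frames, truths = st$truth,
                                   optics = fix_optics(), mode = "labeled",
                                   n_pairs = 8L, seed = 3,
                                   use_clean_slot = TRUE)
  expect_true(all(vapply(pr, function(p)
    identical(p$roi_shape, c(5L, 50L)), logical(1))))

  optlf <- optics_config(mode = "label-free", fov = c(7.04, 7.04))
  stlf <- simulate_stack(optlf, dye_library("ssDNA"), 20, density = 0.1,
                         seed = 5, keep_clean = TRUE)
  prlf <- make_spectral_training_set(stlf$frames, truths = stlf$truth,
                                     optics = optlf, mode = "label-free",
                                     n_pairs = 4L, seed = 3,
                                     use_clean_slot = TRUE)
  expect_true(all(vapply(prlf, function(p)
    identical(p$roi_shape, c(9L, 95L)), logical(1))))
})

test_that("zero-noise configuration yields identical noisy and clean ROIs", {
  opt <- fix_optics(background_rate = 0, read_noise_sd = 0)
  st <- simulate_stack(opt, fix_af647(), 10, density = 0.1, seed = 6,
                       keep_clean = TRUE, add_noise = FALSE)
  pr <- make_spectral_training_set(st$frames, truths = st$truth,
                                   optics = opt, n_pairs = 5L, seed = 1,
                                   use_clean_slot = TRUE)
  for (p in pr) expect_identical(p$noisy_roi, p$clean_roi)
})

test_that("clean ROI profile peaks where the dye spectrum maps through the dispersion", {
  # independent oracle: re-derive the trace by direct convolution of the
  # resampled spectrum with the pixel-integrated PSF profile
  opt <- fix_optics(background_rate = 0, read_noise_sd = 0)
  dy <- fix_af647()
  cal <- sim_calibration(opt)
  px <- opt$camera_pixel_size
  truth <- data.frame(frame = 1L, x_nm = 10 * px, y_nm = 30 * px,
                      photons = 3000, dye = "AF647")
  dims <- dssmlm:::.frame_dims(opt, list(dy))
  ex <- dssmlm:::.render_expected(truth, opt, setNames(list(dy), "AF647"),
                                  dims)
  fr <- list(spectral_image = ex$spectral)
  roi <- crop_spectral_roi(fr, c(10 * px, 30 * px), cal, mode = "labeled",
                           optics = opt)
  prof <- colMeans(roi$pixels)
  peak_col0 <- roi$roi_origin[["col"]] + which.max(prof) - 1

  sig <- opt$psf_sigma / px
  cols <- 0:(dims$nx_spec - 1)
  lam <- (cols - 10 - opt$reference_offset) * opt$spectral_dispersion +
    opt$spectral_intercept
  w <- approx(dy$wavelengths, dy$intensities, xout = lam, yleft = 0,
              yright = 0)$y
  kk <- dssmlm:::.pix_gauss(seq(-8, 8), 0, sig)
  wf <- stats::convolve(c(rep(0, 8), w, rep(0, 8)), rev(kk / sum(kk)),
                        type = "filter")
  oracle_col <- cols[which.max(wf)]
  expect_lte(abs(peak_col0 - oracle_col), 1)
  # and through the calibration this is the dye peak within one step
  expect_lte(abs(pixel_to_wavelength(cal, 10, peak_col0) -
                   dy$peak_wavelength),
             2 * opt$spectral_dispersion)
})
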