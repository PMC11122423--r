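test_that("spectrum extraction handles delta, flat and forward-model cases", {
  opt <- fix_optics()
  cal <- sim_calibration(opt)
  mk_roi <- function(pix, x_nm = 1100, col0 = 40) {
    structure(list(pixels = pix, anchor = c(x = x_nm, y = 550),
                   roi_origin = c(row = 3, col = col0),
                   mode = "labeled"), class = "spectral_roi")
  }
  # single nonzero column -> delta spectrum at that column's wavelength
  pix <- matrix(0, 5, 50)
  pix[, 13] <- 7
  sp <- extract_spectrum(mk_roi(pix), cal, opt)
  expect_true(sp$valid)
  expect_equal(max(sp$intensities), 1)
  expect_equal(sp$peak_wavelength,
               pixel_to_wavelength(cal, 1100 / opt$camera_pixel_size,
                                   40 + 12))
  expect_equal(find_peak(sp), sp$peak_wavelength)

  # uniform ROI -> flat profile flagged invalid, find_peak refuses
  spf <- extract_spectrum(mk_roi(matrix(3, 5, 50)), cal, opt)
  expect_false(spf$valid)
  expect_true(all(spf$intensities == 1))
  expect_error(find_peak(spf), "flat")

  # clean simulated ROI: profile proportional to the dispersed dye spectrum
  dy <- fix_af647()
  opt0 <- fix_optics(background_rate = 0, read_noise_sd = 0)
  tr <- data.frame(frame = 1L, x_nm = 10 * opt0$camera_pixel_size,
                   y_nm = 30 * opt0$camera_pixel_size, photons = 5000,
                   dye = "AF647")
  dims <- dssmlm:::.frame_dims(opt0, list(dy))
  ex <- dssmlm:::.render_expected(tr, opt0, setNames(list(dy), "AF647"), dims)
  roi <- crop_spectral_roi(list(spectral_image = ex$spectral),
                           c(tr$x_nm, tr$y_nm), cal, mode = "labeled",
                           optics = opt0)
  sp2 <- extract_spectrum(roi, cal, opt0)
  ref <- approx(dy$wavelengths, dy$intensities, xout = sp2$wavelengths,
                yleft = 0, yright = 0)$y
  ref <- ref / max(ref)
  # equal up to the PSF blur along the dispersion axis
  expect_gt(cor(sp2$intensities, ref), 0.99)
  expect_lt(abs(find_peak(sp2) - dy$peak_wavelength),
            2 * opt0$spectral_dispersion)
})

test_that("find_peak is the exhaustive argmax with low-wavelength tie-break", {
  set.seed(12)
  for (i in 1:10) {
    wl <- seq(620, 718, by = 2)
    y <- runif(length(wl))
    sp <- structure(list(wavelengths = wl, intensities = y / max(y),
                         peak_wavelength = NA, valid = TRUE),
                    class = "spectrum_1d")
    expect_equal(find_peak(sp), wl[which.max(y)])
  }
  # exact tie: lower wavelength wins
  y2 <- c(0.2, 1, 0.5, 1, 0.1)
  sp2 <- structure(list(wavelengths = seq(600, 640, by = 10),
                        intensities = y2, peak_wavelength = NA,
                        valid = TRUE), class = "spectrum_1d")
  expect_equal(find_peak(sp2), 610)
  # parabolic refinement stays within one bin
  y3 <- c(0.1, 0.8, 1, 0.7, 0.2)
  sp3 <- structure(list(wavelengths = seq(600, 640, by = 10),
                        intensities = y3, peak_wavelength = NA,
                        valid = TRUE), class = "spectrum_1d")
  expect_lt(abs(find_peak(sp3, refine = TRUE) - 620), 10)
})

test_that("window filtering keeps exactly the in-window records, idempotently", {
  set.seed(13)
  locs <- data.frame(frame = 1:10, x_nm = runif(10), y_nm = runif(10),
                     wavelength_nm = c(630, 641, 659, 700, 701, 712, 640,
                                       699.5, NA, 550))
  w <- c(640, 700)
  out <- filter_by_window(locs, w)
  keep <- which(!is.na(locs$wavelength_nm) & locs$wavelength_nm >= 640 &
                  locs$wavelength_nm <= 700)
  expect_identical(out$frame, locs$frame[keep])  # order preserved
  expect_equal(nrow(out), 5L)
  expect_identical(filter_by_window(out, w), out)  # idempotent
  expect_equal(nrow(filter_by_window(locs[0, ], w)), 0L)
  expect_error(filter_by_window(locs, c(700, 640)), "window")
})

test_that("channel assignment partitions records across disjoint windows", {
  chans <- list(channel_spec("ATTO542", c(550, 610)),
                channel_spec("ATTO655", c(650, 710)))
  set.seed(14)
  wl <- c(runif(400, 540, 620), runif(550, 640, 720), runif(50, 615, 645))
  locs <- data.frame(frame = seq_along(wl), x_nm = 0, y_nm = 0,
                     wavelength_nm = wl)
  out <- assign_channels(locs, chans)
  expect_named(out, c("ATTO542", "ATTO655", "unassigned"))
  # partition property
  expect_equal(sum(vapply(out, nrow, integer(1))), nrow(locs))
  # brute-force membership counts
  expect_equal(nrow(out$ATTO542), sum(wl >= 550 & wl <= 610))
  expect_equal(nrow(out$ATTO655), sum(wl >= 650 & wl <= 710))
  # a record in the gap is unassigned
  g <- assign_channels(data.frame(frame = 1, x_nm = 0, y_nm = 0,
                                  wavelength_nm = 630), chans)
  expect_equal(nrow(g$unassigned), 1L)
  # overlapping windows rejected
  expect_error(assign_channels(locs, list(channel_spec("a", c(550, 660)),
                                          channel_spec("b", c(650, 710)))),
               "overlap")
})
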