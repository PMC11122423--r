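# Drift correction, spectral regression, rendering.

.cluster_locs <- function(n, drift_x = 0, drift_y = 0, frames = 100,
                          noise = 15, seed = 3) {
  set.seed(seed)
  ctr <- matrix(runif(60, 200, 2800), 30, 2)
  ci <- sample(30, n, replace = TRUE)
  fr <- sample(seq_len(frames), n, replace = TRUE)
  prog <- (fr - 1) / (frames - 1)
  data.frame(frame = fr,
             x_nm = ctr[ci, 1] + drift_x * prog + rnorm(n, 0, noise),
             y_nm = ctr[ci, 2] + drift_y * prog + rnorm(n, 0, noise),
             wavelength_nm = 670, photons = 1000)
}

test_that("zero-drift data yields near-zero recovered shifts", {
  locs <- .cluster_locs(4000)
  dc <- correct_drift(locs, n_bins = 5, render_pixel = 10)
  expect_lt(max(abs(c(dc$model$dx, dc$model$dy))), 10)
  expect_equal(c(dc$model$dx[1], dc$model$dy[1]), c(0, 0))
})

test_that("injected linear drift is recovered within 10 nm", {
  locs <- .cluster_locs(6000, drift_x = 50, drift_y = -30)
  dc <- correct_drift(locs, n_bins = 5, render_pixel = 10)
  # terminal bin-center drift relative to the first bin center: 80% of range
  expect_lt(abs(tail(dc$model$dx, 1) - 50 * 0.8), 10)
  expect_lt(abs(tail(dc$model$dy, 1) + 30 * 0.8), 10)
  # corrected positions carry much less residual drift
  dc2 <- correct_drift(dc$locs, n_bins = 5, render_pixel = 10)
  expect_lt(max(abs(c(dc2$model$dx, dc2$model$dy))), 6)
})

test_that("drift recovery is invariant to a global position offset", {
  locs <- .cluster_locs(5000, drift_x = 40)
  d1 <- correct_drift(locs, n_bins = 4, render_pixel = 10)$model
  locs2 <- locs
  locs2$x_nm <- locs2$x_nm + 5000
  locs2$y_nm <- locs2$y_nm + 1234
  d2 <- correct_drift(locs2, n_bins = 4, render_pixel = 10)$model
  expect_equal(d1$dx, d2$dx, tolerance = 3)
  expect_equal(d1$dy, d2$dy, tolerance = 3)
})

test_that("spectral regression merges repeats and conserves photons", {
  # exact repeat on consecutive frames collapses to one record
  two <- data.frame(frame = 1:2, x_nm = c(1000, 1000), y_nm = c(500, 500),
                    wavelength_nm = c(670, 670), photons = c(800, 1200))
  m <- spectral_regression(two, radius = 50, spectral_tol = 10, max_gap = 5)
  expect_equal(nrow(m), 1L)
  expect_equal(m$photons, 2000)
  expect_equal(m$merged_count, 2L)
  expect_equal(m$x_nm, 1000)

  # 200 nm apart with 50 nm radius: not merged
  far <- data.frame(frame = 1:2, x_nm = c(1000, 1200), y_nm = c(500, 500),
                    wavelength_nm = c(670, 670), photons = c(1, 1))
  expect_equal(nrow(spectral_regression(far, radius = 50)), 2L)

  # wavelength difference beyond tolerance prevents merging
  spec_far <- data.frame(frame = 1:2, x_nm = c(1000, 1010),
                         y_nm = c(500, 500),
                         wavelength_nm = c(670, 700), photons = c(1, 1))
  expect_equal(nrow(spectral_regression(spec_far, spectral_tol = 10)), 2L)

  # frame gap beyond max_gap prevents merging
  gap <- data.frame(frame = c(1, 20), x_nm = c(1000, 1000),
                    y_nm = c(500, 500), wavelength_nm = c(670, 670),
                    photons = c(1, 1))
  expect_equal(nrow(spectral_regression(gap, max_gap = 5)), 2L)

  # record count never increases; photons conserved
  set.seed(21)
  rnd <- data.frame(frame = sample(1:30, 200, TRUE),
                    x_nm = runif(200, 0, 3000), y_nm = runif(200, 0, 3000),
                    wavelength_nm = runif(200, 650, 690),
                    photons = runif(200, 100, 1000))
  mr <- spectral_regression(rnd)
  expect_lte(nrow(mr), nrow(rnd))
  expect_equal(sum(mr$photons), sum(rnd$photons), tolerance = 1e-9)
  expect_equal(sum(mr$merged_count), nrow(rnd))
})

test_that("merged centroids follow the 1/sqrt(N) precision scaling", {
  # Monte Carlo over 1000 molecules blinking N times with 20 nm noise
  set.seed(22)
  err_for <- function(n_blinks) {
    errs <- numeric(1000)
    for (i in 1:1000) {
      truth <- runif(2, 1000, 2000)
      ev <- data.frame(frame = seq_len(n_blinks),
                       x_nm = truth[1] + rnorm(n_blinks, 0, 20),
                       y_nm = truth[2] + rnorm(n_blinks, 0, 20),
                       wavelength_nm = 670, photons = 1000)
      m <- spectral_regression(ev, radius = 150, spectral_tol = 10,
                               max_gap = 2)
      errs[i] <- sqrt((m$x_nm[1] - truth[1])^2 + (m$y_nm[1] - truth[2])^2)
    }
    mean(errs)
  }
  e1 <- err_for(1)
  e4 <- err_for(4)
  e9 <- err_for(9)
  expect_lt(e4, e1)
  expect_lt(e9, e4)
  # ratios consistent with 1/sqrt(N) within 15%
  expect_lt(abs(e1 / e4 - 2) / 2, 0.15)
  expect_lt(abs(e1 / e9 - 3) / 3, 0.15)
})

test_that("rendering conserves mass and handles empty input", {
  empty <- render_localizations(data.frame(x_nm = numeric(),
                                           y_nm = numeric()), pixel = 10)
  expect_true(all(empty == 0))

  one <- data.frame(x_nm = 500, y_nm = 300)
  img <- render_localizations(one, pixel = 5, blur_sigma = 10)
  expect_equal(sum(img), 1, tolerance = 1e-6)

  set.seed(23)
  many <- data.frame(x_nm = runif(200, 0, 1000), y_nm = runif(200, 0, 1000))
  img2 <- render_localizations(many, pixel = 10, blur_sigma = 0)
  expect_equal(sum(img2), 200)
  many$photons <- runif(200, 1, 5)
  img3 <- render_localizations(many, pixel = 10, weight = "photons")
  expect_equal(sum(img3), sum(many$photons), tolerance = 1e-9)
  # 4.3 nm rendering (label-free scale) works
  img4 <- render_localizations(one, pixel = 4.3, blur_sigma = 4.3)
  expect_equal(sum(img4), 1, tolerance = 1e-6)
})
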