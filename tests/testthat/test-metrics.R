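test_that("matcher handles trivial cases", {
  P <- cbind(c(100, 300), c(100, 300))
  m <- match_localizations(P, P, radius = 100)
  expect_equal(m$tp, 2L)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
  expect_equal(jaccard_index(m), 1.0)

  far <- match_localizations(P, P + 1e5, radius = 100)
  expect_equal(far$tp, 0L)
  expect_equal(far$fp, 2L)
  expect_equal(far$fn, 2L)

  # one prediction within radius of two truths: one TP, one FN, no FP
  m2 <- match_localizations(cbind(0, 0), rbind(c(40, 0), c(-40, 0)),
                            radius = 100)
  expect_equal(c(m2$tp, m2$fn, m2$fp), c(1L, 1L, 0L))
})

test_that("optimal matcher agrees with exhaustive assignment (<= 8 points)", {
  set.seed(11)
  for (rep in 1:25) {
    np <- sample(0:4, 1)
    nt <- sample(0:4, 1)
    P <- matrix(runif(np * 2, 0, 250), np, 2)
    Tr <- matrix(runif(nt * 2, 0, 250), nt, 2)
    m <- match_localizations(P, Tr, radius = 100)
    o <- oracle_match(P, Tr, 100)
    expect_equal(m$tp, o$tp)
    if (m$tp > 0)
      expect_equal(sum(m$pairs[, "dist"]), o$dist, tolerance = 1e-9)
  }
})

test_that("Jaccard index and lateral RMSE follow their definitions", {
  m <- structure(list(tp = 2L, fp = 1L, fn = 1L,
                      pairs = cbind(pred = 1:2, truth = 1:2, dist = c(0, 0))),
                 class = "match_result")
  expect_equal(jaccard_index(m), 0.5)

  # single pair offset (3, 4) nm -> 5 nm
  m2 <- match_localizations(cbind(3, 4), cbind(0, 0), radius = 100)
  expect_equal(lateral_rmse(m2), 5)
  expect_error(lateral_rmse(match_localizations(cbind(0, 0),
                                                cbind(1e5, 0), 100)),
               "no matched")

  # translation invariance
  set.seed(3)
  P <- matrix(runif(10, 0, 100), 5, 2)
  Tr <- P + rnorm(10, 0, 5)
  r1 <- lateral_rmse(match_localizations(P, Tr, 100))
  r2 <- lateral_rmse(match_localizations(P + 777, Tr + 777, 100))
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("frame-wise evaluation accumulates correctly", {
  truth <- data.frame(frame = c(1, 1, 2), x_nm = c(0, 500, 0),
                      y_nm = c(0, 0, 0))
  pred <- data.frame(frame = c(1, 2, 2), x_nm = c(10, 3, 900),
                     y_nm = c(0, 4, 0))
  ev <- evaluate_localizations(pred, truth, radius = 100)
  expect_equal(c(ev$tp, ev$fp, ev$fn), c(2L, 1L, 1L))
  expect_equal(ev$ji, 0.5)
  expect_equal(ev$rmse_nm, sqrt(mean(c(10^2, 5^2))))
})

test_that("SSIM is 1 on identical images and matches the reference implementation", {
  set.seed(42)
  a <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ssim(a, a), 1.0, tolerance = 1e-12)
  # frozen oracle values computed with scikit-image 0.26.0
  # structural_similarity(a, b, gaussian_weights=True, sigma=1.5,
  #                       use_sample_covariance=False, data_range=...)
  b <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ssim(a, b), 0.009265544, tolerance = 1e-6)
  blur <- dssmlm:::.gauss_blur2d(a, 1.2)
  expect_equal(ssim(blur, a), 0.175934777, tolerance = 1e-6)
})

test_that("FWHM equals 2 sqrt(2 ln 2) sigma and fits recover sigma", {
  x <- seq(-20, 20, by = 0.5)
  y <- exp(-x^2 / 2)  # sigma = 1 nm
  f <- fwhm_from_profile(x, y)
  expect_equal(f$fwhm / f$sigma, 2 * sqrt(2 * log(2)), tolerance = 1e-12)
  expect_equal(f$fwhm, 2.355, tolerance = 1e-3)

  # sigma = 10 nm sampled at 1 nm with offset and amplitude
  x2 <- seq(-60, 60, by = 1)
  y2 <- 3 + 17 * exp(-(x2 - 4.5)^2 / (2 * 10^2))
  f2 <- fwhm_from_profile(x2, y2)
  expect_equal(f2$sigma, 10, tolerance = 1e-6)
  expect_equal(f2$center, 4.5, tolerance = 1e-6)
  expect_equal(f2$offset, 3, tolerance = 1e-6)
  expect_error(fwhm_from_profile(x2, rep(1, length(x2))), "constant")
})

test_that("FRC of uncorrelated noise stays near zero and never crosses high", {
  set.seed(5)
  locs <- data.frame(x_nm = runif(4000, 0, 2000), y_nm = runif(4000, 0, 2000))
  r <- frc_resolution(locs, pixel = 10, seed = 1)
  # uncorrelated high-frequency content: rings beyond the first few
  # fluctuate around 0 within the ring-count noise floor
  expect_lt(max(abs(tail(r$frc, length(r$frc) - 5))), 0.45)
  expect_lt(mean(abs(tail(r$frc, length(r$frc) - 5))), 0.1)
})

test_that("FRC resolution reflects the localization precision of a structure", {
  # clusters of localizations with sd 50 nm: expected FWHM-like resolution
  # ~ 2.355 * 50 * sqrt(2) = 166 nm; accept +/- 30% on the median of seeds
  set.seed(9)
  ctr <- as.matrix(expand.grid(x = seq(200, 1800, by = 200),
                               y = seq(200, 1800, by = 200)))
  draws <- function(n_per) {
    i <- rep(seq_len(nrow(ctr)), each = n_per)
    data.frame(x_nm = ctr[i, 1] + rnorm(length(i), 0, 50),
               y_nm = ctr[i, 2] + rnorm(length(i), 0, 50))
  }
  locs <- draws(60)
  res <- vapply(1:10, function(s)
    frc_resolution(locs, pixel = 20, seed = s)$resolution_nm, numeric(1))
  expected <- 2.355 * 50 * sqrt(2)
  expect_lt(abs(median(res) - expected) / expected, 0.30)

  # resolution improves (decreases) with localization count
  res_small <- median(vapply(1:5, function(s)
    frc_resolution(draws(15), pixel = 20, seed = s)$resolution_nm,
    numeric(1)))
  res_big <- median(vapply(1:5, function(s)
    frc_resolution(draws(120), pixel = 20, seed = s)$resolution_nm,
    numeric(1)))
  expect_lt(res_big, res_small)
})
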