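#' Match predicted to ground-truth localizations
#'
#' One-to-one assignment minimizing total distance among candidate pairs
#' within `radius` (optimal Hungarian assignment; the conventional lateral
#' threshold is 100 nm). Unmatched predictions count as false positives,
#' unmatched truths as false negatives. A greedy nearest-first matcher is
#' available for comparison.
#'
#' @param pred,truth two-column matrices or data.frames of positions in nm
#'   (`x_nm`/`y_nm` columns or the first two columns).
#' @param radius matching radius (nm).
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return object of class `match_result`: `tp`, `fp`, `fn`, and `pairs`
#'   (matrix with columns `pred`, `truth`, `dist`).
#' @export
match_localizations <- function(pred, truth, radius = 100,
                                method = c("optimal", "greedy")) {
  method <- match.arg(method)
  .assert_scalar_pos(radius, "radius")
  P <- .coords(pred)
  Tr <- .coords(truth)
  np <- nrow(P)
  nt <- nrow(Tr)
  if (np == 0 || nt == 0) {
    return(structure(list(tp = 0L, fp = np, fn = nt,
                          pairs = matrix(numeric(0), 0, 3,
                                         dimnames = list(NULL, c("pred", "truth", "dist")))),
                     class = "match_result"))
  }
  D <- sqrt(outer(P[, 1], Tr[, 1], "-")^2 + outer(P[, 2], Tr[, 2], "-")^2)
  pairs <- NULL
  if (method == "greedy") {
    Dm <- D
    repeat {
      m <- which.min(Dm)
      if (!length(m) || Dm[m] > radius || !is.finite(Dm[m])) break
      i <- (m - 1) %% np + 1
      j <- (m - 1) %/% np + 1
      pairs <- rbind(pairs, c(i, j, D[i, j]))
      Dm[i, ] <- Inf
      Dm[, j] <- Inf
    }
  } else {
    big <- 1e8 + max(D)  # forbidden assignment: worse than any chain of real ones
    C <- D
    C[C > radius] <- big
    n <- max(np, nt)
    Cs <- matrix(0, n, n)
    Cs[seq_len(np), seq_len(nt)] <- C
    a <- cpp_hungarian(Cs)
    for (i in seq_len(np)) {
      j <- a[i]
      if (j <= nt && D[i, j] <= radius)
        pairs <- rbind(pairs, c(i, j, D[i, j]))
    }
  }
  if (is.null(pairs))
    pairs <- matrix(numeric(0), 0, 3)
  colnames(pairs) <- c("pred", "truth", "dist")
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = np - tp, fn = nt - tp, pairs = pairs),
            class = "match_result")
}

.coords <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("x_nm", "y_nm") %in% names(x)))
      return(cbind(x$x_nm, x$y_nm))
    return(as.matrix(x[, 1:2]))
  }
  m <- as.matrix(x)
  if (!ncol(m)) m <- matrix(numeric(0), 0, 2)
  m[, 1:2, drop = FALSE]
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match result: TP %d  FP %d  FN %d  (JI %.3f)\n",
              x$tp, x$fp, x$fn, jaccard_index(x)))
  invisible(x)
}

#' Jaccard index of a match result
#'
#' `JI = TP / (TP + FP + FN)`: the fraction of correctly detected emitters,
#' 1 for perfect detection.
#'
#' @param m a `match_result`.
#' @return fraction in `[0, 1]`.
#' @export
jaccard_index <- function(m) {
  stopifnot(inherits(m, "match_result"))
  tot <- m$tp + m$fp + m$fn
  if (tot == 0) stop("undefined Jaccard index: empty matching problem")
  m$tp / tot
}

#' Lateral RMSE over matched pairs
#'
#' Root mean square Euclidean distance between matched predicted and
#' ground-truth positions.
#'
#' @param m a `match_result` (its `pairs` carry the distances).
#' @return RMSE in nm.
#' @export
lateral_rmse <- function(m) {
  stopifnot(inherits(m, "match_result"))
  if (m$tp < 1) stop("undefined RMSE: no matched pairs")
  sqrt(mean(m$pairs[, "dist"]^2))
}

#' Evaluate localization quality frame by frame
#'
#' Matches predictions to truths within each frame and accumulates TP/FP/FN
#' and squared distances over the whole stack.
#'
#' @param pred,truth data.frames with `frame`, `x_nm`, `y_nm`.
#' @param radius matching radius in nm (default 100).
#' @return list with `ji`, `rmse_nm`, `tp`, `fp`, `fn`.
#' @export
evaluate_localizations <- function(pred, truth, radius = 100) {
  frames <- sort(unique(c(pred$frame, truth$frame)))
  tp <- fp <- fn <- 0L
  sq <- numeric(0)
  for (f in frames) {
    m <- match_localizations(pred[pred$frame == f, , drop = FALSE],
                             truth[truth$frame == f, , drop = FALSE],
                             radius = radius)
    tp <- tp + m$tp
    fp <- fp + m$fp
    fn <- fn + m$fn
    if (m$tp) sq <- c(sq, m$pairs[, "dist"]^2)
  }
  list(ji = tp / (tp + fp + fn),
       rmse_nm = if (length(sq)) sqrt(mean(sq)) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with a Gaussian window (sd 1.5 px), constants k1 = 0.01 and
#' k2 = 0.03, and the dynamic range taken from the reference image `b`
#' unless given. The local statistics are computed by Gaussian filtering
#' with reflective edge padding and the SSIM map is averaged over all
#' pixels, so small images (e.g. 5x50 spectral ROIs) are supported.
#'
#' @param a test image.
#' @param b reference (ground-truth) image.
#' @param data_range dynamic range; default `max(b) - min(b)`.
#' @param window_sigma Gaussian window sd (px).
#' @return SSIM score in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = NULL, window_sigma = 1.5) {
  if (!all(dim(a) == dim(b))) stop("images must have the same shape")
  if (is.null(data_range)) data_range <- max(b) - min(b)
  if (data_range <= 0) data_range <- 1
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  r <- as.integer(floor(3.5 * window_sigma + 0.5))  # truncate = 3.5
  blur <- function(m) .sepconv2_replicate(m, window_sigma, r)
  mu_a <- blur(a)
  mu_b <- blur(b)
  va <- blur(a * a) - mu_a^2
  vb <- blur(b * b) - mu_b^2
  cab <- blur(a * b) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * cab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (va + vb + c2)
  s <- num / den
  # drop the filter-support border where the image allows it
  ci <- if (nrow(s) > 2L * r + 1L) (r + 1L):(nrow(s) - r) else seq_len(nrow(s))
  cj <- if (ncol(s) > 2L * r + 1L) (r + 1L):(ncol(s) - r) else seq_len(ncol(s))
  mean(s[ci, cj])
}

# Gaussian blur with replicate (nearest) edge padding, as used by the
# standard SSIM reference implementations.
.sepconv2_replicate <- function(m, sigma, r) {
  x <- seq(-r, r)
  k <- dnorm(x, sd = sigma)
  k <- k / sum(k)
  n1 <- nrow(m)
  n2 <- ncol(m)
  ri <- c(rep(1L, r), seq_len(n1), rep(n1, r))
  ci <- c(rep(1L, r), seq_len(n2), rep(n2, r))
  m2 <- m[ri, ci, drop = FALSE]
  out <- matrix(0, n1, ncol(m2))
  for (s in seq_along(k)) out <- out + k[s] * m2[s:(s + n1 - 1L), , drop = FALSE]
  res <- matrix(0, n1, n2)
  for (s in seq_along(k)) res <- res + k[s] * out[, s:(s + n2 - 1L), drop = FALSE]
  res
}

#' Gaussian fit of a 1-D intensity profile and its FWHM
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - center)^2 /
#' (2 sigma^2))`; the full width at half maximum is `2 sqrt(2 ln 2) sigma
#' (about 2.355 sigma)`.
#'
#' @param positions sample positions (nm).
#' @param intensities measured intensities.
#' @return object of class `gaussian_fit`: `amplitude`, `center`, `sigma`,
#'   `offset`, `fwhm` (all nm where applicable).
#' @export
fwhm_from_profile <- function(positions, intensities) {
  stopifnot(length(positions) == length(intensities),
            length(positions) >= 4)
  if (diff(range(intensities)) == 0)
    stop("constant profile: Gaussian fit undefined")
  x <- as.numeric(positions)
  y <- as.numeric(intensities)
  off0 <- min(y)
  a0 <- max(y) - off0
  c0 <- x[which.max(y)]
  above <- x[y >= off0 + a0 / 2]
  s0 <- max(diff(range(above)) / 2.355, diff(range(x)) / 50)
  fit <- try(nls(y ~ off + a * exp(-(x - ctr)^2 / (2 * s^2)),
                 start = list(off = off0, a = a0, ctr = c0, s = s0),
                 control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                              scaleOffset = 1)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    obj <- function(p) sum((y - (p[1] + p[2] *
                                   exp(-(x - p[3])^2 / (2 * p[4]^2))))^2)
    op <- optim(c(off0, a0, c0, s0), obj, control = list(maxit = 2000))
    if (op$convergence != 0) stop("Gaussian fit did not converge")
    cf <- op$par
  } else {
    cf <- coef(fit)
  }
  sigma <- abs(unname(cf[4]))
  structure(list(amplitude = unname(cf[2]), center = unname(cf[3]),
                 sigma = sigma, offset = unname(cf[1]),
                 fwhm = 2 * sqrt(2 * log(2)) * sigma),
            class = "gaussian_fit")
}

#' Fourier ring correlation resolution
#'
#' Splits the localizations randomly in half, renders both halves as
#' histograms on a common grid, correlates their Fourier transforms ring by
#' ring, smooths the curve with a short moving average and reads the
#' resolution at the first crossing of the fixed 1/7 threshold.
#'
#' @param locs localization data.frame with `x_nm`, `y_nm`.
#' @param pixel rendering pixel size (nm).
#' @param seed seed for the random half-split.
#' @param smooth_width moving-average width in rings (default 3).
#' @return list with `resolution_nm` (Inf-safe; clamped at the Nyquist
#'   length `2 * pixel` when the curve never crosses), `frequency`
#'   (1/nm), `frc` (smoothed curve) and `crossed` (logical).
#' @export
frc_resolution <- function(locs, pixel = 10, seed = NULL,
                           smooth_width = 3L) {
  stopifnot(nrow(locs) >= 2)
  .with_seed(seed, {
    n <- nrow(locs)
    half <- sample.int(n, floor(n / 2))
    ex <- c(min(locs$x_nm), max(locs$x_nm), min(locs$y_nm), max(locs$y_nm))
    side <- max(ex[2] - ex[1], ex[4] - ex[3]) + 2 * pixel
    N <- 2^ceiling(log2(side / pixel))
    ext <- c(ex[1], ex[1] + N * pixel, ex[3], ex[3] + N * pixel)
    h1 <- render_localizations(locs[half, , drop = FALSE], pixel,
                               blur_sigma = 0, extent = ext)
    h2 <- render_localizations(locs[-half, , drop = FALSE], pixel,
                               blur_sigma = 0, extent = ext)
    F1 <- fft(h1)
    F2 <- fft(h2)
    fx <- c(0:(N / 2), -(N / 2 - 1):-1) / N
    R <- sqrt(outer(fx^2, fx^2, "+")) * N  # ring index in pixels
    ring <- pmin(round(R), N %/% 2)
    num <- Re(F1 * Conj(F2))
    d1 <- Mod(F1)^2
    d2 <- Mod(F2)^2
    rs <- function(v) tapply(as.vector(v), as.vector(ring), sum)
    frc <- rs(num) / sqrt(rs(d1) * rs(d2))
    frc[!is.finite(frc)] <- 0
    rr <- as.integer(names(frc))
    frc <- frc[order(rr)]
    rr <- sort(rr)
    keep <- rr >= 1 & rr <= N %/% 2 - 1
    frc <- frc[keep]
    rr <- rr[keep]
    if (smooth_width > 1) {
      k <- rep(1 / smooth_width, smooth_width)
      sm <- stats::filter(frc, k, sides = 2)
      frc_s <- ifelse(is.na(sm), frc, as.numeric(sm))
    } else frc_s <- frc
    freq <- rr / (N * pixel)  # cycles per nm
    below <- which(frc_s < 1 / 7)
    if (!length(below)) {
      list(resolution_nm = 2 * pixel, frequency = freq, frc = frc_s,
           crossed = FALSE)
    } else {
      i <- below[1]
      if (i == 1) {
        fc <- freq[1]
      } else {
        # linear interpolation of the crossing
        f0 <- freq[i - 1]; f1 <- freq[i]
        y0 <- frc_s[i - 1]; y1 <- frc_s[i]
        fc <- f0 + (y0 - 1 / 7) / (y0 - y1) * (f1 - f0)
      }
      list(resolution_nm = 1 / fc, frequency = freq, frc = frc_s,
           crossed = TRUE)
    }
  })
}
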