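#' Linear spectral calibration
#'
#' In sSMLM the first-order spectral trace of an emitter is displaced from
#' its zeroth-order (spatial) position by a distance proportional to the
#' emission wavelength. Calibration images of known laser lines (e.g. 405,
#' 488, 532, 552 and 637 nm) provide peak pixel positions that are fitted by
#' a straight line `lambda = slope * pixel + intercept`.
#'
#' @name calibration
NULL

new_spectral_calibration <- function(slope, intercept, reference_offset = 0,
                                     fit_residual_rms = 0) {
  if (!is.finite(slope) || slope == 0) stop("slope must be nonzero")
  if (fit_residual_rms < 0) stop("fit_residual_rms must be >= 0")
  structure(list(slope = slope, intercept = intercept,
                 reference_offset = reference_offset,
                 fit_residual_rms = fit_residual_rms),
            class = "spectral_calibration")
}

#' Fit a linear pixel-to-wavelength calibration
#'
#' Least-squares fit of `wavelength = slope * pixel + intercept` through the
#' measured peak pixel positions of known spectral lines.
#'
#' @param peak_pixels measured peak pixel positions (displacement relative to
#'   the zeroth-order reference, px).
#' @param known_wavelengths the corresponding emission wavelengths (nm).
#' @param reference_offset pixel distance between a zeroth-order position and
#'   the origin of its spectral trace, stored for later use by
#'   [pixel_to_wavelength()].
#' @return a `spectral_calibration` with `slope` (nm/px), `intercept` (nm),
#'   `reference_offset` (px) and `fit_residual_rms` (nm).
#' @export
fit_calibration <- function(peak_pixels, known_wavelengths,
                            reference_offset = 0) {
  if (length(peak_pixels) != length(known_wavelengths))
    stop("peak_pixels and known_wavelengths must have equal length")
  if (length(peak_pixels) < 2L)
    stop("calibration needs at least two points")
  if (diff(range(peak_pixels)) == 0)
    stop("calibration failure: all peak pixels identical")
  x <- as.numeric(peak_pixels)
  y <- as.numeric(known_wavelengths)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - (slope * x + intercept)
  new_spectral_calibration(slope, intercept, reference_offset,
                           sqrt(mean(res^2)))
}

#' @export
print.spectral_calibration <- function(x, ...) {
  cat(sprintf(
    "spectral calibration: lambda = %.6g nm/px * displacement + %.6g nm\n",
    x$slope, x$intercept))
  cat(sprintf("  reference offset %.3g px | fit residual RMS %.3g nm\n",
              x$reference_offset, x$fit_residual_rms))
  invisible(x)
}

#' Map a spectral-image pixel to an emission wavelength
#'
#' Uses the spatial (zeroth-order) localization as reference point:
#' `lambda = slope * (spectral_x - spatial_x - reference_offset) + intercept`.
#'
#' @param cal a `spectral_calibration`.
#' @param spatial_x zeroth-order x position (px).
#' @param spectral_x spectral-image x position (px).
#' @return wavelength in nm (vectorized).
#' @export
pixel_to_wavelength <- function(cal, spatial_x, spectral_x) {
  stopifnot(inherits(cal, "spectral_calibration"))
  cal$slope * (spectral_x - spatial_x - cal$reference_offset) + cal$intercept
}

#' Inverse of [pixel_to_wavelength()]
#' @inheritParams pixel_to_wavelength
#' @param wavelength emission wavelength (nm).
#' @return spectral-image x position (px).
#' @export
wavelength_to_pixel <- function(cal, spatial_x, wavelength) {
  stopifnot(inherits(cal, "spectral_calibration"))
  spatial_x + cal$reference_offset + (wavelength - cal$intercept) / cal$slope
}

#' Locate spectral lines on a calibration image
#'
#' Sums the calibration image over rows, detects the `n_lines` strongest
#' local maxima of the column profile and refines each to sub-pixel accuracy
#' with a 1-D Gaussian fit in a small window.
#'
#' @param image calibration image (matrix, rows = y).
#' @param n_lines number of lines expected.
#' @param min_separation minimum distance between detected lines (px).
#' @param window half-width of the Gaussian-fit window (px).
#' @return numeric vector of sub-pixel column positions (0-based), sorted.
#' @export
find_calibration_peaks <- function(image, n_lines, min_separation = 5,
                                   window = 4) {
  prof <- colSums(image)
  n <- length(prof)
  cand <- which(diff(sign(diff(prof))) == -2) + 1L  # interior local maxima
  if (!length(cand)) stop("no local maxima in calibration profile")
  cand <- cand[order(prof[cand], decreasing = TRUE)]
  keep <- integer()
  for (c0 in cand) {
    if (!length(keep) || all(abs(keep - c0) >= min_separation))
      keep <- c(keep, c0)
    if (length(keep) == n_lines) break
  }
  if (length(keep) < n_lines)
    stop("found only ", length(keep), " of ", n_lines, " lines")
  refined <- vapply(sort(keep), function(c0) {
    i <- max(1L, c0 - window):min(n, c0 + window)
    y <- prof[i]
    base <- min(y)
    a <- max(y) - base
    fit <- try(suppressWarnings(
      nls(y ~ base0 + amp * exp(-(i - mu)^2 / (2 * s2^2)),
          start = list(base0 = base, amp = a, mu = c0, s2 = 1.5),
          control = stats::nls.control(warnOnly = TRUE, scaleOffset = 1))),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(c0 - 1)  # fall back: integer peak
    unname(coef(fit)["mu"]) - 1  # 0-based
  }, numeric(1))
  refined
}

#' Read/write a spectral calibration as JSON
#' @param cal a `spectral_calibration`.
#' @param path file path.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "spectral_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_spectral_calibration(x$slope, x$intercept, x$reference_offset,
                           x$fit_residual_rms)
}
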