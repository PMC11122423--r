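#' Collapse a spectral ROI into a 1-D emission spectrum
#'
#' Takes the mean pixel value of each ROI column (mean over y), normalizes
#' the profile to a maximum of 1, and maps each column to a wavelength via
#' the calibration, using the ROI's spatial anchor as reference point.
#'
#' @param roi a `spectral_roi` (see [crop_spectral_roi()]).
#' @param cal a `spectral_calibration`.
#' @param optics [optics_config()] supplying the camera pixel size.
#' @return object of class `spectrum_1d`: `wavelengths` (nm, one per
#'   column), `intensities` (max 1), `peak_wavelength` (nm; `NA` when the
#'   profile is flat) and `valid`.
#' @export
extract_spectrum <- function(roi, cal, optics) {
  stopifnot(inherits(roi, "spectral_roi"))
  prof <- colMeans(roi$pixels)
  x_px <- roi$anchor[["x"]] / optics$camera_pixel_size
  cols0 <- roi$roi_origin[["col"]] + seq_along(prof) - 1
  wl <- pixel_to_wavelength(cal, x_px, cols0)
  rng <- max(prof) - min(prof)
  valid <- is.finite(rng) && rng > 0 && max(prof) > 0
  if (valid) {
    prof <- prof / max(prof)
  } else {
    prof <- rep(1, length(prof))
  }
  structure(list(wavelengths = wl, intensities = prof,
                 peak_wavelength = if (valid) wl[which.max(prof)] else NA_real_,
                 valid = valid),
            class = "spectrum_1d")
}

#' Spectral peak of a 1-D spectrum
#'
#' Wavelength of the global maximum of the profile; ties break toward the
#' lower wavelength. Optionally refines the peak with a 3-point parabola.
#'
#' @param spec a `spectrum_1d`.
#' @param refine if `TRUE`, apply 3-point parabolic sub-bin refinement.
#' @return peak wavelength (nm).
#' @export
find_peak <- function(spec, refine = FALSE) {
  stopifnot(inherits(spec, "spectrum_1d"))
  if (!spec$valid) stop("no peak: flat or invalid spectrum")
  ord <- order(spec$wavelengths)
  wl <- spec$wavelengths[ord]
  y <- spec$intensities[ord]
  i <- which.max(y)  # first maximum = lowest wavelength on ties
  if (!refine || i == 1L || i == length(y)) return(wl[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(wl[i])
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  wl[i] + delta * mean(diff(wl[(i - 1):(i + 1)]))
}

#' Filter localizations by a spectral window
#'
#' Retains localizations whose wavelength lies inside `[window[1],
#' window[2]]` (bounds inclusive); input order is preserved. Typical window:
#' 640-700 nm for AF647, 670-730 nm for CF680.
#'
#' @param locs localization data.frame with a `wavelength_nm` column.
#' @param window `c(lambda_min, lambda_max)` in nm.
#' @return the filtered data.frame.
#' @export
filter_by_window <- function(locs, window) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(lambda_min, lambda_max) with lambda_min < lambda_max")
  keep <- !is.na(locs$wavelength_nm) &
    locs$wavelength_nm >= window[1] & locs$wavelength_nm <= window[2]
  locs[keep, , drop = FALSE]
}

#' Spectral channel definition for multicolor imaging
#'
#' @param name dye/channel identifier.
#' @param window `c(lambda_min, lambda_max)` nm. The two-color defaults used
#'   for ATTO 542 / ATTO 655 nanoruler imaging are 550-610 nm and
#'   650-710 nm.
#' @return object of class `channel_spec`.
#' @export
channel_spec <- function(name, window) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(lambda_min, lambda_max) with lambda_min < lambda_max")
  structure(list(name = name, window = as.numeric(window)),
            class = "channel_spec")
}

#' Assign localizations to spectral channels
#'
#' Each localization goes to the unique channel whose window contains its
#' wavelength, or to `"unassigned"`. Channel windows must be pairwise
#' disjoint.
#'
#' @param locs localization data.frame with `wavelength_nm`.
#' @param channels list of [channel_spec()].
#' @return named list of data.frames, one per channel plus `unassigned`;
#'   the input also gains a `channel` column in each piece.
#' @export
assign_channels <- function(locs, channels) {
  stopifnot(length(channels) >= 1,
            all(vapply(channels, inherits, logical(1), "channel_spec")))
  nms <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate channel names")
  wins <- t(vapply(channels, `[[`, numeric(2), "window"))
  if (length(channels) > 1) {
    ord <- order(wins[, 1])
    if (any(wins[ord, 2][-length(ord)] >= wins[ord, 1][-1]))
      stop("channel windows overlap")
  }
  lab <- rep("unassigned", nrow(locs))
  for (k in seq_along(channels)) {
    inside <- !is.na(locs$wavelength_nm) &
      locs$wavelength_nm >= wins[k, 1] & locs$wavelength_nm <= wins[k, 2]
    lab[inside] <- nms[k]
  }
  locs$channel <- lab
  out <- lapply(c(nms, "unassigned"), function(ch)
    locs[lab == ch, , drop = FALSE])
  names(out) <- c(nms, "unassigned")
  out
}
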