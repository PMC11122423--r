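#' Optical and camera configuration for the sSMLM simulator
#'
#' Collects the physical parameters of a single-camera sSMLM instrument in
#' which a transmission grating splits each emission into a zeroth-order
#' (spatial) and a first-order (spectrally dispersed) image.
#'
#' @param camera_pixel_size camera pixel size in the sample plane (nm/px).
#' @param psf_sigma standard deviation of the 2-D Gaussian PSF (nm).
#' @param spectral_dispersion linear dispersion along the x axis (nm/px).
#' @param split_ratio fraction of detected photons routed to the spectral
#'   (first-order) channel; the grating used here splits roughly 1:3
#'   between zeroth and first order, i.e. `0.75`.
#' @param background_rate mean background level (photons/px/frame).
#' @param read_noise_sd Gaussian camera read noise (photoelectrons).
#' @param fov field of view `c(width, height)` in micrometers.
#' @param mode `"labeled"` (dye-stained samples, 5x50 px spectral ROIs) or
#'   `"label-free"` (intrinsic-contrast imaging, 9x95 px ROIs and a much
#'   lower photon budget).
#' @param photon_mean,photon_sd mean and sd of the per-event photon count;
#'   events are drawn from a lognormal with these moments. Defaults depend
#'   on `mode`: 2300 +/- 690 photons for labeled samples (calibrated, with
#'   the default background of 1 photon/px, so that raw spectral ROIs show
#'   the noisy-versus-clean structural similarity characteristic of real
#'   dye-labeled sSMLM acquisitions, about 0.59) and 300 +/- 100 for
#'   label-free imaging.
#' @param spectral_intercept wavelength (nm) mapped to zero pixel
#'   displacement between an emitter and its spectral trace.
#' @param reference_offset pixel offset between the zeroth-order position
#'   and the origin of the first-order trace (px).
#' @param dispersion_sign +1 if wavelength increases with +x (default).
#'
#' @return an object of class `optics_config`.
#' @export
optics_config <- function(camera_pixel_size = 110,
                          psf_sigma = 1.3 * camera_pixel_size,
                          spectral_dispersion = if (mode == "labeled") 2.0 else 1.6,
                          split_ratio = 0.75,
                          background_rate = 1,
                          read_noise_sd = 1.5,
                          fov = c(7.04, 7.04),
                          mode = c("labeled", "label-free"),
                          photon_mean = if (mode == "labeled") 2300 else 300,
                          photon_sd = if (mode == "labeled") 690 else 100,
                          spectral_intercept = if (mode == "labeled") 550 else 450,
                          reference_offset = 0,
                          dispersion_sign = 1) {
  mode <- match.arg(mode)
  .assert_scalar_pos(camera_pixel_size, "camera_pixel_size")
  .assert_scalar_pos(psf_sigma, "psf_sigma")
  .assert_scalar_pos(spectral_dispersion, "spectral_dispersion")
  .assert_scalar_pos(photon_mean, "photon_mean")
  .assert_scalar_pos(photon_sd, "photon_sd")
  if (!(split_ratio > 0 && split_ratio < 1))
    stop("split_ratio must lie strictly between 0 and 1")
  if (background_rate < 0 || read_noise_sd < 0)
    stop("background_rate and read_noise_sd must be non-negative")
  if (length(fov) != 2L || any(fov <= 0))
    stop("fov must be two positive lengths (micrometers)")
  if (!dispersion_sign %in% c(-1, 1))
    stop("dispersion_sign must be +1 or -1")
  # the FOV must hold at least one PSF (+/- 3 sigma)
  if (any(fov * 1000 < 6 * psf_sigma))
    stop("field of view too small to contain a single PSF")
  structure(list(
    camera_pixel_size = camera_pixel_size, psf_sigma = psf_sigma,
    spectral_dispersion = spectral_dispersion, split_ratio = split_ratio,
    background_rate = background_rate, read_noise_sd = read_noise_sd,
    fov = fov, mode = mode, photon_mean = photon_mean, photon_sd = photon_sd,
    spectral_intercept = spectral_intercept,
    reference_offset = reference_offset,
    dispersion_sign = dispersion_sign
  ), class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("sSMLM optics configuration (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  pixel %g nm | PSF sigma %g nm | dispersion %g nm/px\n",
              x$camera_pixel_size, x$psf_sigma, x$spectral_dispersion))
  cat(sprintf("  split %g to spectral | background %g ph/px | read noise %g e-\n",
              x$split_ratio, x$background_rate, x$read_noise_sd))
  cat(sprintf("  FOV %g x %g um | photons %g +/- %g\n",
              x$fov[1], x$fov[2], x$photon_mean, x$photon_sd))
  invisible(x)
}

# frame geometry implied by an optics_config
.frame_dims <- function(optics, dyes = NULL) {
  nx <- max(8L, round(optics$fov[1] * 1000 / optics$camera_pixel_size))
  ny <- max(8L, round(optics$fov[2] * 1000 / optics$camera_pixel_size))
  pad <- 0L
  if (!is.null(dyes)) {
    lmax <- max(vapply(dyes, function(d) max(d$wavelengths), numeric(1)))
    pad <- ceiling(optics$reference_offset +
                     (lmax - optics$spectral_intercept) /
                       optics$spectral_dispersion +
                     4 * optics$psf_sigma / optics$camera_pixel_size) + 2L
    pad <- max(0L, as.integer(pad))
  }
  list(nx = as.integer(nx), ny = as.integer(ny),
       nx_spec = as.integer(nx + pad))
}

#' Fluorophore emission spectrum
#'
#' @param name dye identifier.
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param intensities non-negative relative emission values; rescaled so the
#'   maximum equals 1.
#' @return object of class `dye_spectrum` with fields `name`, `wavelengths`,
#'   `intensities` and `peak_wavelength` (grid point of maximal intensity).
#' @export
dye_spectrum <- function(name, wavelengths, intensities) {
  stopifnot(length(wavelengths) == length(intensities),
            length(wavelengths) >= 2L)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(intensities < 0) || max(intensities) <= 0)
    stop("intensities must be non-negative with a positive maximum")
  intensities <- intensities / max(intensities)
  structure(list(name = name,
                 wavelengths = as.numeric(wavelengths),
                 intensities = as.numeric(intensities),
                 peak_wavelength = wavelengths[which.max(intensities)]),
            class = "dye_spectrum")
}

# Asymmetric (two-sided Gaussian) emission profile: fluorophore emission
# rises steeply on the blue side and tails off to the red.
.synthetic_emission <- function(name, peak, sigma_blue, sigma_red, range) {
  wl <- seq(range[1], range[2], by = 1)
  s <- ifelse(wl <= peak,
              exp(-(wl - peak)^2 / (2 * sigma_blue^2)),
              exp(-(wl - peak)^2 / (2 * sigma_red^2)))
  dye_spectrum(name, wl, s)
}

#' Built-in synthetic dye emission spectra
#'
#' Smooth two-sided-Gaussian stand-ins for the emission spectra of the dyes
#' commonly used in sSMLM, parameterized by their published emission maxima
#' (AF647 ~671 nm, CF680 ~699 nm, ATTO 542 ~560 nm, ATTO 655 ~681 nm) plus a
#' generic intrinsic ssDNA emission profile for label-free imaging. These are
#' synthetic curves, not measured reference spectra.
#'
#' @param name one of `"AF647"`, `"CF680"`, `"ATTO542"`, `"ATTO655"`,
#'   `"ssDNA"`; with no argument, the full library is returned.
#' @return a `dye_spectrum`, or a named list of them.
#' @export
dye_library <- function(name = NULL) {
  lib <- list(
    AF647   = .synthetic_emission("AF647",   671, 12, 30, c(620, 800)),
    CF680   = .synthetic_emission("CF680",   699, 13, 32, c(640, 830)),
    ATTO542 = .synthetic_emission("ATTO542", 560, 11, 28, c(520, 700)),
    ATTO655 = .synthetic_emission("ATTO655", 681, 12, 30, c(630, 810)),
    ssDNA   = .synthetic_emission("ssDNA",   575, 20, 45, c(500, 720))
  )
  if (is.null(name)) return(lib)
  if (!name %in% names(lib)) stop("unknown dye: ", name)
  lib[[name]]
}
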