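#' Assemble a pipeline configuration
#'
#' Bundles everything the end-to-end reconstruction needs. All arguments
#' have working defaults except the optics.
#'
#' @param optics an [optics_config()].
#' @param mode imaging mode; defaults to the optics mode.
#' @param channels optional list of [channel_spec()] for multicolor output.
#' @param filter_window optional `c(min, max)` nm spectral filter applied to
#'   all localizations (e.g. `c(640, 700)` for AF647).
#' @param drift list with `n_bins`, `render_pixel` (nm), `upsample`.
#' @param regression list with `radius_nm`, `spectral_tol_nm`, `max_gap`.
#' @param render list with `pixel_nm`, `blur_sigma_nm`.
#' @param localize list with `threshold`, `min_separation`.
#' @param seed integer.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(optics, mode = optics$mode, channels = NULL,
                            filter_window = NULL,
                            drift = list(n_bins = 10L, render_pixel = 10,
                                         upsample = 1L),
                            regression = list(radius_nm = 50,
                                              spectral_tol_nm = 10,
                                              max_gap = 5L),
                            render = list(pixel_nm = 10, blur_sigma_nm = 10),
                            localize = list(threshold = 0.1,
                                            min_separation = NULL),
                            seed = 1L) {
  stopifnot(inherits(optics, "optics_config"))
  if (!is.null(filter_window) &&
      (length(filter_window) != 2 || filter_window[1] >= filter_window[2]))
    stop("invalid filter_window")
  structure(list(optics = optics, mode = mode, channels = channels,
                 filter_window = filter_window, drift = drift,
                 regression = regression, render = render,
                 localize = localize, seed = seed),
            class = "pipeline_config")
}

#' Run the full sSMLM reconstruction chain
#'
#' For every frame: U-Net localization on the spatial image, spectral-ROI
#' cropping at each localization, DCNN enhancement, 1-D spectrum extraction
#' and peak finding. The pooled localization list is then spectrally
#' filtered, drift corrected, merged by spectral regression, optionally
#' split into color channels, and rendered.
#'
#' @param cfg a [pipeline_config()].
#' @param frames list of `frame_pair` (e.g. from [simulate_stack()] or
#'   [read_stack()]).
#' @param loc_model trained `localizer_model`.
#' @param enh_model trained `enhancer_model`, or `NULL` to skip enhancement
#'   (conventional reconstruction).
#' @param cal a `spectral_calibration`.
#' @param out_dir optional output directory; when given, writes
#'   `localizations.csv`, `drift.csv`, rendered TIFF(s) and `report.json`.
#' @param verbose log one line per stage.
#' @return list with `locs` (final localization table), `channel_locs`
#'   (if channels configured), `image` (composite render), `channel_images`,
#'   `drift`, and `report` (per-stage record counts).
#' @export
run_pipeline <- function(cfg, frames, loc_model, enh_model = NULL, cal,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  optics <- cfg$optics
  px <- optics$camera_pixel_size
  t0 <- proc.time()[["elapsed"]]
  report <- list()
  log_stage <- function(stage, n_in, n_out) {
    report[[stage]] <<- list(n_in = n_in, n_out = n_out,
                             elapsed_s = round(proc.time()[["elapsed"]] - t0,
                                               2))
    if (verbose)
      message(sprintf("[%s] in=%d out=%d (%.1fs)", stage, n_in, n_out,
                      report[[stage]]$elapsed_s))
  }

  min_sep <- cfg$localize$min_separation %||% loc_model$spec$upsampling
  locs <- list()
  n_roi_skipped <- 0L
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    det <- predict_localizations(loc_model, fr$spatial_image, px,
                                 threshold = cfg$localize$threshold,
                                 min_separation = min_sep)
    if (!nrow(det)) next
    det$frame <- fr$frame_index %||% f
    det$wavelength_nm <- NA_real_
    for (i in seq_len(nrow(det))) {
      roi <- withCallingHandlers(
        crop_spectral_roi(fr, c(det$x_nm[i], det$y_nm[i]), cal,
                          mode = cfg$mode, optics = optics),
        dssmlm_roi_oob = function(w) invokeRestart("muffleWarning"))
      if (is.null(roi)) { n_roi_skipped <- n_roi_skipped + 1L; next }
      if (!is.null(enh_model)) roi <- enhance_roi(enh_model, roi)
      sp <- extract_spectrum(roi, cal, optics)
      if (sp$valid) det$wavelength_nm[i] <- find_peak(sp)
    }
    locs[[length(locs) + 1L]] <- det
  }
  locs <- if (length(locs)) do.call(rbind, locs) else
    data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
               intensity = numeric(), wavelength_nm = numeric())
  locs$photons <- locs$intensity %||% rep(NA_real_, nrow(locs))
  n_localized <- nrow(locs)
  log_stage("localize", length(frames), n_localized)

  with_spec <- locs[!is.na(locs$wavelength_nm), , drop = FALSE]
  log_stage("spectral_extraction", n_localized, nrow(with_spec))

  filt <- if (!is.null(cfg$filter_window))
    filter_by_window(with_spec, cfg$filter_window) else with_spec
  log_stage("spectral_filter", nrow(with_spec), nrow(filt))

  drift <- NULL
  if (nrow(filt) > 20 && length(unique(filt$frame)) >= 2 * cfg$drift$n_bins) {
    dc <- correct_drift(filt, n_bins = cfg$drift$n_bins,
                        render_pixel = cfg$drift$render_pixel,
                        upsample = cfg$drift$upsample %||% 1L)
    filt <- dc$locs
    drift <- dc$model
  }
  log_stage("drift_correction", nrow(filt), nrow(filt))

  merged <- spectral_regression(filt, radius = cfg$regression$radius_nm,
                                spectral_tol = cfg$regression$spectral_tol_nm,
                                max_gap = cfg$regression$max_gap)
  log_stage("spectral_regression", nrow(filt), nrow(merged))

  channel_locs <- NULL
  channel_images <- NULL
  if (!is.null(cfg$channels)) {
    channel_locs <- assign_channels(merged, cfg$channels)
    n_in <- nrow(merged)
    merged <- do.call(rbind, unname(channel_locs))
    rownames(merged) <- NULL
    log_stage("channel_assignment", n_in, nrow(merged))
  }

  ext <- NULL
  image <- render_localizations(merged, pixel = cfg$render$pixel_nm,
                                blur_sigma = cfg$render$blur_sigma_nm,
                                extent = ext)
  if (!is.null(channel_locs)) {
    channel_images <- lapply(channel_locs, function(cl)
      render_localizations(cl, pixel = cfg$render$pixel_nm,
                           blur_sigma = cfg$render$blur_sigma_nm,
                           extent = attr(image, "extent")))
  }
  log_stage("render", nrow(merged), nrow(merged))
  report$roi_skipped <- n_roi_skipped

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_localizations(merged, file.path(out_dir, "localizations.csv"))
    if (!is.null(drift))
      write.csv(drift$per_frame, file.path(out_dir, "drift.csv"),
                row.names = FALSE)
    write_tiff_stack(list(unclass(image)), file.path(out_dir, "render.tif"))
    if (!is.null(channel_images)) {
      for (nm in names(channel_images))
        write_tiff_stack(list(unclass(channel_images[[nm]])),
                         file.path(out_dir, paste0("render_", nm, ".tif")))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(locs = merged, channel_locs = channel_locs, image = image,
       channel_images = channel_images, drift = drift, report = report)
}
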