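#' Simulate an sSMLM acquisition with ground truth
#'
#' Generates a stack of paired spatial/spectral frames. Per frame, the number
#' of emitters is Poisson with mean `density * FOV area`; each emitter is a
#' 2-D Gaussian PSF (pixel-integrated) carrying `(1 - split_ratio)` of its
#' photons in the spatial image. Its spectral trace carries `split_ratio` of
#' the photons: the dye emission spectrum is resampled onto the pixel grid
#' through the linear dispersion, convolved along x with the PSF profile, and
#' spread in y by the PSF profile. Shot noise is Poisson on expected counts
#' (signal + background) and Gaussian read noise is added on top.
#'
#' @param optics an [optics_config()].
#' @param dyes list of [dye_spectrum()] objects (or a single one); each
#'   emitter is assigned one dye uniformly at random.
#' @param n_frames number of frames (>= 1).
#' @param density emitters per square micrometer per frame (default 0.1,
#'   sparse enough to avoid overlapping PSFs).
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @param keep_clean if `TRUE`, each frame also carries `spatial_clean` and
#'   `spectral_clean`: the noise- and background-free expected signal.
#' @param add_noise disable to obtain expected-count (noise-free) frames.
#' @param render_spectral set to `FALSE` to skip the spectral channel (the
#'   truth list is unchanged; useful when only spatial training data is
#'   needed).
#'
#' @return list with `frames` (list of `frame_pair`: `spatial_image`,
#'   `spectral_image`, `frame_index`) and `truth`, a data.frame with columns
#'   `frame`, `x_nm`, `y_nm`, `photons`, `dye` (positions are continuous,
#'   measured from the center of the top-left pixel, x rightward along the
#'   dispersion axis, y downward).
#' @export
simulate_stack <- function(optics, dyes, n_frames, density = 0.1,
                           seed = NULL, keep_clean = FALSE,
                           add_noise = TRUE, render_spectral = TRUE) {
  stopifnot(inherits(optics, "optics_config"))
  if (inherits(dyes, "dye_spectrum")) dyes <- list(dyes)
  if (!length(dyes) || !all(vapply(dyes, inherits, logical(1), "dye_spectrum")))
    stop("'dyes' must be dye_spectrum objects")
  .assert_scalar_pos(density, "density")
  stopifnot(n_frames >= 1)
  dye_names <- vapply(dyes, `[[`, character(1), "name")
  names(dyes) <- dye_names

  .with_seed(seed, {
    dims <- .frame_dims(optics, dyes)
    area <- prod(optics$fov)
    mu <- density * area
    # draw the full ground truth first so that the truth list is invariant
    # to the noise settings under a fixed seed
    truth <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      k <- rpois(1, mu)
      if (k > 0) {
        sdl <- sqrt(log(1 + (optics$photon_sd / optics$photon_mean)^2))
        mul <- log(optics$photon_mean) - sdl^2 / 2
        truth[[f]] <- data.frame(
          frame = f,
          x_nm = runif(k, 0, optics$fov[1] * 1000),
          y_nm = runif(k, 0, optics$fov[2] * 1000),
          photons = rlnorm(k, mul, sdl),
          dye = sample(dye_names, k, replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
    if (is.null(truth))
      truth <- data.frame(frame = integer(), x_nm = numeric(),
                          y_nm = numeric(), photons = numeric(),
                          dye = character(), stringsAsFactors = FALSE)

    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      tf <- truth[truth$frame == f, , drop = FALSE]
      ex <- .render_expected(tf, optics, dyes, dims,
                             spectral = render_spectral)
      sp <- ex$spatial
      sc <- ex$spectral
      if (add_noise) {
        sp <- matrix(rpois(length(sp), sp + optics$background_rate),
                     nrow(sp), ncol(sp)) +
          matrix(rnorm(length(sp), 0, optics$read_noise_sd),
                 nrow(sp), ncol(sp))
        sc <- matrix(rpois(length(sc), sc + optics$background_rate),
                     nrow(sc), ncol(sc)) +
          matrix(rnorm(length(sc), 0, optics$read_noise_sd),
                 nrow(sc), ncol(sc))
      }
      fr <- list(spatial_image = sp, spectral_image = sc, frame_index = f)
      if (keep_clean) {
        fr$spatial_clean <- ex$spatial
        fr$spectral_clean <- ex$spectral
      }
      class(fr) <- "frame_pair"
      frames[[f]] <- fr
    }
    list(frames = frames, truth = truth)
  })
}

# Expected (noise-free, background-free) photon counts for one frame.
.render_expected <- function(truth_frame, optics, dyes, dims,
                             spectral = TRUE) {
  px <- optics$camera_pixel_size
  sig <- optics$psf_sigma / px
  do_spec <- isTRUE(spectral)
  spatial <- matrix(0, dims$ny, dims$nx)
  spectral <- matrix(0, dims$ny, if (do_spec) dims$nx_spec else 1L)
  if (nrow(truth_frame)) {
    for (i in seq_len(nrow(truth_frame))) {
      xpx <- truth_frame$x_nm[i] / px
      ypx <- truth_frame$y_nm[i] / px
      ph <- truth_frame$photons[i]
      dye <- dyes[[truth_frame$dye[i]]]
      if (is.null(dye)) stop("unknown dye: ", truth_frame$dye[i])
      # spatial PSF
      r <- ceiling(5 * sig)
      ix <- max(0, floor(xpx) - r):min(dims$nx - 1, ceiling(xpx) + r)
      iy <- max(0, floor(ypx) - r):min(dims$ny - 1, ceiling(ypx) + r)
      gx <- .pix_gauss(ix, xpx, sig)
      gy <- .pix_gauss(iy, ypx, sig)
      spatial[iy + 1, ix + 1] <- spatial[iy + 1, ix + 1] +
        (1 - optics$split_ratio) * ph * outer(gy, gx)
      # spectral trace
      if (!do_spec) next
      tr <- .spectral_trace(xpx, dye, optics, dims$nx_spec)
      if (length(tr$cols)) {
        spectral[iy + 1, tr$cols + 1] <- spectral[iy + 1, tr$cols + 1] +
          optics$split_ratio * ph * outer(gy, tr$w)
      }
    }
  }
  list(spatial = spatial, spectral = spectral)
}

# Column weights (summing to 1 before clipping) of the spectral trace of an
# emitter at spatial column `xpx`: dye spectrum mapped through the dispersion
# and convolved along x with the pixel-integrated PSF profile.
.spectral_trace <- function(xpx, dye, optics, nx_spec) {
  disp <- optics$spectral_dispersion * optics$dispersion_sign
  c_of_lambda <- function(l) {
    xpx + optics$reference_offset + (l - optics$spectral_intercept) / disp
  }
  rng <- range(c_of_lambda(range(dye$wavelengths)))
  sig <- optics$psf_sigma / optics$camera_pixel_size
  r <- ceiling(4 * sig)
  c0 <- floor(rng[1]) - r
  c1 <- ceiling(rng[2]) + r
  cols <- c0:c1
  lam <- (cols - xpx - optics$reference_offset) * disp +
    optics$spectral_intercept
  w <- approx(dye$wavelengths, dye$intensities, xout = lam,
              yleft = 0, yright = 0)$y
  s <- sum(w)
  if (s <= 0) return(list(cols = integer(), w = numeric()))
  w <- w / s
  # convolve with the PSF x-profile (pixel-integrated, zero-phase)
  k <- .pix_gauss(seq(-r, r), 0, sig)
  k <- k / sum(k)
  wf <- stats::convolve(c(rep(0, r), w, rep(0, r)), rev(k), type = "filter")
  wf <- pmax(wf, 0)  # FFT convolution can leave ~1e-17 negative ringing
  keep <- cols >= 0 & cols <= nx_spec - 1
  list(cols = cols[keep], w = wf[keep])
}

#' Training patches for the emitter-localization network
#'
#' Tiles every frame with overlapping patches (stride `patch_size / 2`),
#' discards candidates with fewer than `min_emitters` ground-truth emitters,
#' and pairs each surviving noisy spatial patch with the spike locations of
#' its emitters on a grid upsampled by `upsampling`: an emitter at continuous
#' patch position `(x, y)` px produces a unit spike at index
#' `round(x * upsampling)`, `round(y * upsampling)`.
#'
#' @param stack,truths output of [simulate_stack()].
#' @param optics the [optics_config()] used for the simulation.
#' @param patch_size patch side (camera px).
#' @param upsampling integer grid factor (>= 1).
#' @param n_pairs number of training pairs requested.
#' @param seed integer seed controlling patch sampling.
#' @param min_emitters minimum emitters per patch (default 3).
#' @return list of `training_pair_spatial`: `input_patch` (matrix),
#'   `spikes` (m x 2 matrix of 0-based fine-grid `(row, col)` indices),
#'   `emitter_count`, `upsampling`. Use [spatial_target_grid()] to
#'   materialize the spike image. Warns on shortfall.
#' @export
make_spatial_training_set <- function(stack, truths, optics,
                                      patch_size = 208L, upsampling = 4L,
                                      n_pairs = 1000L, seed = NULL,
                                      min_emitters = 3L) {
  stopifnot(upsampling >= 1, patch_size >= 4)
  frames <- stack$frames %||% stack
  ny <- nrow(frames[[1]]$spatial_image)
  nx <- ncol(frames[[1]]$spatial_image)
  if (patch_size > min(nx, ny))
    stop("patch_size exceeds frame size")
  px <- optics$camera_pixel_size
  stride <- max(1L, patch_size %/% 2L)
  x0s <- unique(c(seq(0L, nx - patch_size, by = stride), nx - patch_size))
  y0s <- unique(c(seq(0L, ny - patch_size, by = stride), ny - patch_size))

  .with_seed(seed, {
    # integral-image count of (pixel-rounded) emitters per candidate patch,
    # so that scanning thousands of frames stays cheap
    cand <- list()
    truth_by_frame <- split(seq_len(nrow(truths)), truths$frame)
    for (f in seq_along(frames)) {
      rows <- truth_by_frame[[as.character(f)]]
      if (length(rows) < min_emitters) next
      tf <- truths[rows, , drop = FALSE]
      xs <- tf$x_nm / px
      ys <- tf$y_nm / px
      rx <- pmin(pmax(round(xs), 0), nx - 1L)
      ry <- pmin(pmax(round(ys), 0), ny - 1L)
      H <- matrix(0L, ny, nx)
      ij <- cbind(ry + 1L, rx + 1L)
      for (k in seq_len(nrow(ij))) H[ij[k, 1], ij[k, 2]] <-
        H[ij[k, 1], ij[k, 2]] + 1L
      S <- rbind(0L, cbind(0L, t(apply(apply(H, 2, cumsum), 1, cumsum))))
      counts <- S[y0s + patch_size + 1L, x0s + patch_size + 1L,
                  drop = FALSE] -
        S[y0s + 1L, x0s + patch_size + 1L, drop = FALSE] -
        S[y0s + patch_size + 1L, x0s + 1L, drop = FALSE] +
        S[y0s + 1L, x0s + 1L, drop = FALSE]
      hits <- which(counts >= min_emitters, arr.ind = TRUE)
      if (!nrow(hits)) next
      for (h in seq_len(nrow(hits))) {
        y0 <- y0s[hits[h, 1]]
        x0 <- x0s[hits[h, 2]]
        inside <- rx >= x0 & rx <= x0 + patch_size - 1L &
          ry >= y0 & ry <= y0 + patch_size - 1L
        cand[[length(cand) + 1L]] <- list(f = f, x0 = x0, y0 = y0,
                                          idx = rows[inside])
      }
    }
    if (!length(cand)) {
      warning("no patches with >= ", min_emitters, " emitters found")
      return(list())
    }
    ord <- sample.int(length(cand))
    if (length(cand) < n_pairs) {
      warning(sprintf("requested %d pairs but only %d valid patches found",
                      n_pairs, length(cand)))
    }
    take <- ord[seq_len(min(n_pairs, length(cand)))]
    lapply(take, function(ci) {
      cc <- cand[[ci]]
      tf <- truths[cc$idx, , drop = FALSE]
      gpx <- tf$x_nm / px - cc$x0
      gpy <- tf$y_nm / px - cc$y0
      n_up <- patch_size * upsampling
      spikes <- cbind(
        row = pmin(pmax(round(gpy * upsampling), 0), n_up - 1L),
        col = pmin(pmax(round(gpx * upsampling), 0), n_up - 1L))
      structure(list(
        input_patch = frames[[cc$f]]$spatial_image[
          cc$y0 + seq_len(patch_size), cc$x0 + seq_len(patch_size)],
        spikes = spikes,
        emitter_count = nrow(spikes),
        upsampling = as.integer(upsampling)),
        class = "training_pair_spatial")
    })
  })
}

#' Materialize the upsampled spike target of a spatial training pair
#'
#' @param pair a `training_pair_spatial`.
#' @param spike_mass mass deposited per emitter (default 1).
#' @return matrix of size `patch * upsampling` squared whose sum equals
#'   `emitter_count * spike_mass`.
#' @export
spatial_target_grid <- function(pair, spike_mass = 1) {
  n <- nrow(pair$input_patch) * pair$upsampling
  g <- matrix(0, n, n)
  if (nrow(pair$spikes)) {
    # accumulate, so that coincident spikes stack their mass
    idx <- pair$spikes[, "row"] + 1L + pair$spikes[, "col"] * n
    agg <- tapply(rep(spike_mass, length(idx)), idx, sum)
    g[as.integer(names(agg))] <- agg
  }
  g
}

#' Paired noisy/clean spectral-PSF training crops for the enhancer
#'
#' Crops, for every sampled ground-truth emitter, the spectral-PSF region of
#' interest from a noisy spectral image and from its noise-free counterpart
#' (same truths, same seed; noise applied only to the noisy stack). The ROI
#' geometry follows [crop_spectral_roi()]: 9x95 px in label-free mode and
#' 5x50 px in labeled mode. Emitters whose ROI leaves the spectral image are
#' skipped.
#'
#' @param stack_noisy,stack_clean frame lists rendered from identical truths
#'   (e.g. `simulate_stack(..., keep_clean = TRUE)` supplies both in one
#'   pass: pass `stack$frames` and set `use_clean_slot = TRUE`).
#' @param truths ground-truth table.
#' @param optics the [optics_config()].
#' @param mode `"label-free"` or `"labeled"`.
#' @param n_pairs number of pairs requested.
#' @param seed sampling seed.
#' @param cal optional [fit_calibration()] result; defaults to the exact
#'   calibration implied by `optics` ([sim_calibration()]).
#' @param use_clean_slot if `TRUE`, `stack_noisy` frames carry their clean
#'   counterpart in `$spectral_clean` and `stack_clean` is ignored.
#' @return list of `training_pair_spectral`: `noisy_roi`, `clean_roi`,
#'   `roi_shape`, `dye`, `truth` (row of the source emitter).
#' @export
make_spectral_training_set <- function(stack_noisy, stack_clean = NULL,
                                       truths, optics,
                                       mode = optics$mode,
                                       n_pairs = 1000L, seed = NULL,
                                       cal = sim_calibration(optics),
                                       use_clean_slot = FALSE) {
  frames_n <- stack_noisy$frames %||% stack_noisy
  frames_c <- if (use_clean_slot) NULL else (stack_clean$frames %||% stack_clean)
  if (!use_clean_slot && length(frames_n) != length(frames_c))
    stop("noisy and clean stacks must have the same number of frames")
  px <- optics$camera_pixel_size
  .with_seed(seed, {
    ord <- sample.int(nrow(truths))
    out <- vector("list", min(n_pairs, nrow(truths)))
    got <- 0L
    skipped <- 0L
    for (i in ord) {
      if (got >= n_pairs) break
      f <- truths$frame[i]
      loc <- c(x = truths$x_nm[i], y = truths$y_nm[i])
      roi_n <- suppressWarnings(crop_spectral_roi(
        frames_n[[f]], loc, cal, mode = mode, optics = optics))
      if (is.null(roi_n)) { skipped <- skipped + 1L; next }
      clean_img <- if (use_clean_slot) frames_n[[f]]$spectral_clean
        else frames_c[[f]]$spectral_image
      roi_c <- roi_n
      roi_c$pixels <- clean_img[roi_n$rows, roi_n$cols, drop = FALSE]
      got <- got + 1L
      out[[got]] <- structure(list(
        noisy_roi = roi_n$pixels, clean_roi = roi_c$pixels,
        roi_shape = dim(roi_n$pixels), dye = truths$dye[i],
        truth = truths[i, , drop = FALSE]),
        class = "training_pair_spectral")
    }
    if (got < n_pairs)
      warning(sprintf(
        "requested %d spectral pairs, produced %d (%d ROIs out of bounds)",
        n_pairs, got, skipped))
    out[seq_len(got)]
  })
}

#' Exact spectral calibration implied by a simulator configuration
#'
#' The simulator places wavelength lambda of an emitter at spatial column x
#' at spectral column `x + reference_offset + (lambda - intercept)/slope`;
#' this returns the corresponding `spectral_calibration` object.
#' @param optics an [optics_config()].
#' @return a `spectral_calibration`.
#' @export
sim_calibration <- function(optics) {
  new_spectral_calibration(
    slope = optics$spectral_dispersion * optics$dispersion_sign,
    intercept = optics$spectral_intercept,
    reference_offset = optics$reference_offset,
    fit_residual_rms = 0)
}
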