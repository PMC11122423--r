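#' Cross-correlation drift correction
#'
#' Splits the acquisition into `n_bins` equal frame blocks, renders a 2-D
#' localization histogram per block, cross-correlates every block against
#' the first via FFT, refines the correlation peak with a 3-point parabola
#' per axis, interpolates the per-block shifts linearly over frames, and
#' subtracts them from the positions. The first block defines zero drift.
#'
#' @param locs localization data.frame with `frame`, `x_nm`, `y_nm`.
#' @param n_bins number of temporal blocks (default 10).
#' @param render_pixel histogram pixel size (nm, default 10).
#' @param upsample integer histogram refinement factor: histograms are
#'   rendered at `render_pixel / upsample` nm.
#' @return list with `locs` (drift-corrected copy) and `model` of class
#'   `drift_model`: `bin_frames` (bin-center frames), `dx`, `dy` (nm),
#'   `per_frame` (data.frame `frame`, `dx_nm`, `dy_nm`).
#' @export
correct_drift <- function(locs, n_bins = 10L, render_pixel = 10,
                          upsample = 1L) {
  stopifnot(nrow(locs) > 0, n_bins >= 2)
  px <- render_pixel / upsample
  fr <- range(locs$frame)
  edges <- seq(fr[1], fr[2] + 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(locs$frame, edges), n_bins)
  xr <- range(locs$x_nm)
  yr <- range(locs$y_nm)
  n2 <- max(8L, 2^ceiling(log2((xr[2] - xr[1]) / px + 4)))
  n1 <- max(8L, 2^ceiling(log2((yr[2] - yr[1]) / px + 4)))
  hist_bin <- function(sel) {
    h <- matrix(0, n1, n2)
    if (!any(sel)) return(h)
    i <- pmin(pmax(floor((locs$y_nm[sel] - yr[1]) / px), 0), n1 - 1) + 1
    j <- pmin(pmax(floor((locs$x_nm[sel] - xr[1]) / px), 0), n2 - 1) + 1
    for (k in seq_along(i)) h[i[k], j[k]] <- h[i[k], j[k]] + 1
    .gauss_blur2d(h, 1)
  }
  ref <- hist_bin(bin == 1L)
  Fref <- fft(ref)
  dx <- numeric(n_bins)
  dy <- numeric(n_bins)
  ok <- logical(n_bins)
  ok[1] <- TRUE
  for (b in 2:n_bins) {
    sel <- bin == b
    if (sum(sel) < 5) next
    cc <- Re(fft(Fref * Conj(fft(hist_bin(sel))), inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    sub <- function(mat, i, j, di, dj) {
      mat[(i - 1 + di) %% n1 + 1, (j - 1 + dj) %% n2 + 1]
    }
    para <- function(m1, m0, p1) {
      den <- m1 - 2 * m0 + p1
      if (den >= 0) 0 else 0.5 * (m1 - p1) / den
    }
    i0 <- pk[1]; j0 <- pk[2]
    fi <- para(sub(cc, i0, j0, -1, 0), cc[i0, j0], sub(cc, i0, j0, 1, 0))
    fj <- para(sub(cc, i0, j0, 0, -1), cc[i0, j0], sub(cc, i0, j0, 0, 1))
    si <- i0 - 1 + fi
    sj <- j0 - 1 + fj
    if (si > n1 / 2) si <- si - n1
    if (sj > n2 / 2) sj <- sj - n2
    # correlation peak sits at minus the ref -> shifted displacement
    dy[b] <- -si * px
    dx[b] <- -sj * px
    ok[b] <- TRUE
  }
  # interpolate across empty bins (linear over bin index)
  if (!all(ok)) {
    warning("empty drift bins interpolated")
    ib <- seq_len(n_bins)
    dx[!ok] <- approx(ib[ok], dx[ok], xout = ib[!ok], rule = 2)$y
    dy[!ok] <- approx(ib[ok], dy[ok], xout = ib[!ok], rule = 2)$y
  }
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  pf <- data.frame(frame = seq(fr[1], fr[2]))
  pf$dx_nm <- approx(centers, dx, xout = pf$frame, rule = 2)$y
  pf$dy_nm <- approx(centers, dy, xout = pf$frame, rule = 2)$y
  m <- match(locs$frame, pf$frame)
  out <- locs
  out$x_nm <- locs$x_nm - pf$dx_nm[m]
  out$y_nm <- locs$y_nm - pf$dy_nm[m]
  model <- structure(list(bin_frames = centers, dx = dx, dy = dy,
                          per_frame = pf),
                     class = "drift_model")
  list(locs = out, model = model)
}

#' Merge repeated emissions of the same fluorophore (spectral regression)
#'
#' Greedy frame-ordered chaining: a blinking event is merged into an open
#' group when it lies within `radius` nm of the group's running
#' photon-weighted centroid, within `spectral_tol` nm of its photon-weighted
#' mean wavelength, and within `max_gap` frames of the group's last event.
#' Merged records accumulate all photons of their members, sharpening the
#' localization precision roughly as 1/sqrt(N blinks).
#'
#' @param locs localization data.frame with `frame`, `x_nm`, `y_nm`,
#'   `wavelength_nm` and (optionally) `photons`.
#' @param radius spatial merge radius (nm, default 50).
#' @param spectral_tol wavelength tolerance (nm, default 10).
#' @param max_gap maximum frame gap within a group (default 5).
#' @return data.frame of merged localizations: photon-weighted centroid
#'   positions and wavelengths, summed `photons`, `merged_count`, and
#'   `frame` = first member frame.
#' @export
spectral_regression <- function(locs, radius = 50, spectral_tol = 10,
                                max_gap = 5L) {
  if (!nrow(locs)) return(locs)
  if (is.null(locs$photons)) locs$photons <- 1
  if (is.null(locs$wavelength_nm)) locs$wavelength_nm <- NA_real_
  ord <- order(locs$frame)
  l <- locs[ord, , drop = FALSE]
  gx <- gy <- gl <- gph <- gn <- glast <- gfirst <- numeric(0)
  member_of <- integer(nrow(l))
  open <- integer(0)  # indices into group vectors
  for (i in seq_len(nrow(l))) {
    f <- l$frame[i]
    if (length(open)) open <- open[f - glast[open] <= max_gap]
    best <- 0L
    bestd <- Inf
    for (gI in open) {
      d <- sqrt((l$x_nm[i] - gx[gI])^2 + (l$y_nm[i] - gy[gI])^2)
      dl <- abs(l$wavelength_nm[i] - gl[gI])
      if (is.na(dl)) dl <- 0
      if (d <= radius && dl <= spectral_tol && d < bestd) {
        best <- gI
        bestd <- d
      }
    }
    w <- l$photons[i]
    if (best > 0L) {
      tot <- gph[best] + w
      gx[best] <- (gx[best] * gph[best] + l$x_nm[i] * w) / tot
      gy[best] <- (gy[best] * gph[best] + l$y_nm[i] * w) / tot
      if (!is.na(l$wavelength_nm[i]))
        gl[best] <- (gl[best] * gph[best] + l$wavelength_nm[i] * w) / tot
      gph[best] <- tot
      gn[best] <- gn[best] + 1
      glast[best] <- f
      member_of[i] <- best
    } else {
      gx <- c(gx, l$x_nm[i]); gy <- c(gy, l$y_nm[i])
      gl <- c(gl, l$wavelength_nm[i]); gph <- c(gph, w)
      gn <- c(gn, 1); glast <- c(glast, f); gfirst <- c(gfirst, f)
      member_of[i] <- length(gx)
      open <- c(open, length(gx))
    }
  }
  data.frame(frame = gfirst, x_nm = gx, y_nm = gy, wavelength_nm = gl,
             photons = gph, merged_count = as.integer(gn))
}

#' Render a super-resolution image from localizations
#'
#' 2-D histogram of the positions at the requested pixel size, optionally
#' Gaussian-blurred. Total mass equals the localization count (or the total
#' photons with `weight = "photons"`).
#'
#' @param locs localization data.frame with `x_nm`, `y_nm`.
#' @param pixel rendering pixel size (nm).
#' @param blur_sigma Gaussian blur sd in nm (0 = none).
#' @param weight `"count"` or `"photons"`.
#' @param extent optional `c(xmin, xmax, ymin, ymax)` nm; computed from the
#'   data (padded by 3 blur sigmas) when missing.
#' @return numeric matrix (rows = y); attributes `extent` and `pixel`.
#' @export
render_localizations <- function(locs, pixel = 10, blur_sigma = 0,
                                 weight = c("count", "photons"),
                                 extent = NULL) {
  weight <- match.arg(weight)
  .assert_scalar_pos(pixel, "pixel")
  if (is.null(extent)) {
    pad <- max(3 * blur_sigma, pixel)
    if (nrow(locs)) {
      extent <- c(min(locs$x_nm) - pad, max(locs$x_nm) + pad,
                  min(locs$y_nm) - pad, max(locs$y_nm) + pad)
    } else extent <- c(0, pixel * 8, 0, pixel * 8)
  }
  n2 <- max(1L, ceiling((extent[2] - extent[1]) / pixel))
  n1 <- max(1L, ceiling((extent[4] - extent[3]) / pixel))
  img <- matrix(0, n1, n2)
  if (nrow(locs)) {
    w <- if (weight == "photons") locs$photons %||% rep(1, nrow(locs))
      else rep(1, nrow(locs))
    i <- floor((locs$y_nm - extent[3]) / pixel) + 1
    j <- floor((locs$x_nm - extent[1]) / pixel) + 1
    ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2
    for (k in which(ok)) img[i[k], j[k]] <- img[i[k], j[k]] + w[k]
  }
  if (blur_sigma > 0) img <- .gauss_blur2d(img, blur_sigma / pixel)
  attr(img, "extent") <- extent
  attr(img, "pixel") <- pixel
  img
}
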