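#' Specification of the spectral-PSF enhancement network
#'
#' A plain residual DCNN: `n_layers` 3x3 convolutions with `filters` feature
#' maps and ReLU activations, a final single-filter linear 3x3 layer, and an
#' additive skip connection from input to output (the network learns the
#' residual between the noisy and the clean spectral PSF).
#'
#' @param n_layers number of weighted convolution layers (default 7).
#' @param filters feature maps per hidden layer (default 64).
#' @return object of class `enhancer_spec`.
#' @export
enhancer_spec <- function(n_layers = 7L, filters = 64L) {
  stopifnot(n_layers >= 2, filters >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 filters = as.integer(filters), kernel = 3L,
                 activation = "relu", skip = "additive"),
            class = "enhancer_spec")
}

.init_enhancer_params <- function(spec, seed = NULL) {
  .with_seed(seed, {
    P <- list()
    he <- function(cin, cout) {
      matrix(rnorm(9L * cin * cout, sd = sqrt(2 / (9L * cin))),
             9L * cin, cout)
    }
    for (l in seq_len(spec$n_layers)) {
      cin <- if (l == 1L) 1L else spec$filters
      cout <- if (l == spec$n_layers) 1L else spec$filters
      P[[sprintf("l%d_W", l)]] <- he(cin, cout)
      P[[sprintf("l%d_b", l)]] <- numeric(cout)
    }
    P
  })
}

#' Spectral ROI geometry and cropping
#'
#' Crops the spectral point-spread function of one localization from the
#' spectral image. The crop is centered vertically on the localization's row
#' and spans horizontally from the pixel onto which the mode's spectral
#' window start maps (via the calibration) with a fixed width: 9x95 px for
#' label-free data, 5x50 px for labeled data. ROIs that would leave the
#' spectral image raise a warning of class `dssmlm_roi_oob` and return
#' `NULL`.
#'
#' @param frame a `frame_pair` (or any list with `$spectral_image`).
#' @param loc localization as `c(x, y)` in nm.
#' @param cal a `spectral_calibration`.
#' @param mode `"label-free"` or `"labeled"`.
#' @param optics [optics_config()] supplying the camera pixel size.
#' @param lambda_start wavelength at the left edge of the ROI; defaults to
#'   500 nm (label-free) or 620 nm (labeled).
#' @return object of class `spectral_roi` with fields `pixels`, `anchor`
#'   (nm), `roi_origin` (0-based `c(row, col)`), `rows`/`cols` (1-based index
#'   vectors into the spectral image) and `mode`; or `NULL` if out of bounds.
#' @export
crop_spectral_roi <- function(frame, loc, cal, mode = c("labeled", "label-free"),
                              optics,
                              lambda_start = if (mode == "labeled") 620 else 500) {
  mode <- match.arg(mode)
  img <- frame$spectral_image %||% frame
  shape <- if (mode == "labeled") c(5L, 50L) else c(9L, 95L)
  px <- optics$camera_pixel_size
  x_px <- loc[[1]] / px
  y_px <- loc[[2]] / px
  row_c <- round(y_px)
  row0 <- row_c - (shape[1] - 1L) %/% 2L
  col0 <- round(wavelength_to_pixel(cal, x_px, lambda_start))
  rows <- row0:(row0 + shape[1] - 1L)
  cols <- col0:(col0 + shape[2] - 1L)
  if (row0 < 0 || col0 < 0 || max(rows) > nrow(img) - 1L ||
      max(cols) > ncol(img) - 1L) {
    warning(warningCondition(
      sprintf("spectral ROI out of bounds for localization (%.1f, %.1f) nm",
              loc[[1]], loc[[2]]),
      class = "dssmlm_roi_oob"))
    return(NULL)
  }
  structure(list(pixels = img[rows + 1L, cols + 1L, drop = FALSE],
                 anchor = c(x = loc[[1]], y = loc[[2]]),
                 roi_origin = c(row = row0, col = col0),
                 rows = rows + 1L, cols = cols + 1L, mode = mode),
            class = "spectral_roi")
}

#' Enhancement loss (mean squared error)
#'
#' @param pred_roi,clean_roi same-shape matrices (or 3-D arrays treated as a
#'   batch over the third dimension).
#' @return scalar: MSE over pixels, averaged over the batch.
#' @export
loss_enh <- function(pred_roi, clean_roi) {
  if (!all(dim(pred_roi) == dim(clean_roi)))
    stop("prediction and target must have the same shape")
  if (length(dim(pred_roi)) == 3L) {
    mean(apply((pred_roi - clean_roi)^2, 3, mean))
  } else {
    mean((pred_roi - clean_roi)^2)
  }
}

#' Train the spectral-PSF enhancer
#'
#' Adam-trained residual DCNN minimizing [loss_enh()] between restored and
#' clean spectral ROIs. Each pair is normalized by the maximum of its noisy
#' crop before entering the network. The training pairs are split 90:10 into
#' training/validation and the best-validation parameters are kept.
#'
#' @param pairs list of `training_pair_spectral`
#'   (see [make_spectral_training_set()]).
#' @param spec an [enhancer_spec()].
#' @param epochs training epochs; 0 returns the untrained model.
#' @param val_fraction validation fraction.
#' @param seed seed for initialization and shuffling.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (default 64).
#' @param verbose print one line per epoch.
#' @return object of class `enhancer_model` (`params`, `spec`, `history`).
#' @export
train_enhancer <- function(pairs, spec = enhancer_spec(), epochs = 30L,
                           val_fraction = 0.1, seed = NULL, lr = 1e-3,
                           batch_size = 64L, verbose = FALSE) {
  if (!length(pairs)) stop("no training pairs")
  shp <- pairs[[1]]$roi_shape
  .with_seed(seed, {
    params <- .init_enhancer_params(spec)
    n <- length(pairs)
    idx <- sample.int(n)
    n_val <- if (n >= 10) max(1L, round(val_fraction * n)) else 0L
    val_idx <- head(idx, n_val)
    tr_idx <- setdiff(idx, val_idx)

    make_batch <- function(ids) {
      xb <- array(0, c(shp[1], shp[2], length(ids)))
      tb <- array(0, c(shp[1], shp[2], length(ids)))
      for (k in seq_along(ids)) {
        p <- pairs[[ids[k]]]
        f <- max(p$noisy_roi)
        if (f <= 0) f <- 1
        xb[, , k] <- p$noisy_roi / f
        tb[, , k] <- p$clean_roi / f
      }
      list(x = xb, t = tb)
    }

    eval_loss <- function(ids) {
      if (!length(ids)) return(NA_real_)
      tot <- 0
      for (ch in split(ids, ceiling(seq_along(ids) / batch_size))) {
        b <- make_batch(ch)
        pr <- cpp_dcnn_predict(params, spec$n_layers, b$x)
        tot <- tot + sum(apply((pr - b$t)^2, 3, mean))
      }
      tot / length(ids)
    }

    state <- .adam_init(params)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    best <- list(params = params, val = Inf)
    if (epochs > 0) {
      for (ep in seq_len(epochs)) {
        ord <- sample(tr_idx)
        ep_loss <- 0
        nb <- 0L
        for (ch in split(ord, ceiling(seq_along(ord) / batch_size))) {
          b <- make_batch(ch)
          lg <- cpp_dcnn_loss_grad(params, spec$n_layers, b$x, b$t)
          if (!is.finite(lg$loss))
            stop("training diverged (non-finite loss) at epoch ", ep)
          st <- .adam_step(params, lg$grads, state, lr = lr)
          params <- st$params
          state <- st$state
          ep_loss <- ep_loss + lg$loss
          nb <- nb + 1L
        }
        vl <- eval_loss(val_idx)
        hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                       val_loss = vl))
        if (is.finite(vl) && vl < best$val)
          best <- list(params = params, val = vl)
        if (verbose)
          message(sprintf("epoch %3d  train %.6f  val %.6f", ep,
                          ep_loss / nb, vl))
      }
    }
    final <- if (is.finite(best$val)) best$params else params
    structure(list(params = final, spec = spec, history = hist,
                   roi_shape = shp),
              class = "enhancer_model")
  })
}

#' @export
print.enhancer_model <- function(x, ...) {
  cat(sprintf("residual DCNN enhancer: %d layers, %d filters, ROI %dx%d\n",
              x$spec$n_layers, x$spec$filters, x$roi_shape[1],
              x$roi_shape[2]))
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs, best val MSE %.6f\n",
                max(x$history$epoch), min(x$history$val_loss, na.rm = TRUE)))
  else cat("  untrained (random initialization)\n")
  invisible(x)
}

#' Restore a spectral ROI with the trained enhancer
#'
#' @param model an `enhancer_model`.
#' @param roi a `spectral_roi`, a plain matrix, or a 3-D array batch.
#' @return the restored object of the same kind; negative outputs are
#'   clamped to zero.
#' @export
enhance_roi <- function(model, roi) {
  pix <- if (inherits(roi, "spectral_roi")) roi$pixels else roi
  batched <- length(dim(pix)) == 3L
  xb <- if (batched) pix else array(pix, c(dim(pix), 1L))
  if (!all(dim(xb)[1:2] == model$roi_shape))
    stop("ROI shape does not match the model's trained shape")
  out <- array(0, dim(xb))
  for (k in seq_len(dim(xb)[3])) {
    f <- max(xb[, , k])
    if (f <= 0) f <- 1
    y <- cpp_dcnn_predict(model$params, model$spec$n_layers,
                          array(xb[, , k] / f, c(dim(xb)[1:2], 1L)))[, , 1]
    out[, , k] <- pmax(y * f, 0)
  }
  if (inherits(roi, "spectral_roi")) {
    roi$pixels <- out[, , 1]
    roi
  } else if (batched) out else out[, , 1]
}
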