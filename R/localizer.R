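#' Specification of the U-Net emitter localizer
#'
#' The localizer maps a diffraction-limited spatial image (bilinearly
#' resampled onto a grid upsampled by `upsampling`) to a same-size prediction
#' grid carrying a spike per emitter. Encoder levels apply two 3x3
#' convolutions (ELU) followed by 2x2 max pooling; the decoder mirrors them
#' with 2x2 transposed convolutions and concatenating skips; a final 1x1
#' linear convolution produces the pixelwise prediction.
#'
#' @param depth number of pooling levels (>= 1).
#' @param base_filters filters at the first level; doubled per level.
#' @param upsampling integer prediction-grid factor.
#' @param loss_kernel_sigma sd (in upsampled px) of the Gaussian kernel `g`
#'   used in the training loss.
#' @param l1_weight weight of the L1 sparsity term of the loss.
#' @param spike_mass target mass deposited per emitter on the upsampled
#'   grid. With the unweighted L1 term of the loss, unit-mass spikes make
#'   the all-zero prediction a near-optimal basin that gradient training
#'   cannot leave; large-amplitude spikes (default 100) let the
#'   squared-error term dominate, which is how this loss is used in
#'   practice.
#' @return object of class `localizer_spec`.
#' @export
localizer_spec <- function(depth = 3L, base_filters = 16L, upsampling = 4L,
                           loss_kernel_sigma = 1, l1_weight = 1,
                           spike_mass = 100) {
  stopifnot(depth >= 1, base_filters >= 1, upsampling >= 1,
            loss_kernel_sigma > 0, l1_weight >= 0, spike_mass > 0)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 conv_kernel = 3L, pool_kernel = 2L, activation = "elu",
                 upsampling = as.integer(upsampling),
                 loss_kernel_sigma = loss_kernel_sigma,
                 l1_weight = l1_weight, spike_mass = spike_mass),
            class = "localizer_spec")
}

# He-normal initialization of all U-Net parameters, named for the C++ core.
.init_localizer_params <- function(spec, seed = NULL) {
  .with_seed(seed, {
    P <- list()
    he <- function(kk, cin, cout) {
      matrix(rnorm(kk * cin * cout, sd = sqrt(2 / (kk * cin))),
             kk * cin, cout)
    }
    f <- spec$base_filters * 2^(seq_len(spec$depth) - 1L)
    fb <- spec$base_filters * 2^spec$depth
    cin <- 1L
    for (d in seq_len(spec$depth)) {
      P[[sprintf("enc%d_c1_W", d)]] <- he(9L, cin, f[d])
      P[[sprintf("enc%d_c1_b", d)]] <- numeric(f[d])
      P[[sprintf("enc%d_c2_W", d)]] <- he(9L, f[d], f[d])
      P[[sprintf("enc%d_c2_b", d)]] <- numeric(f[d])
      cin <- f[d]
    }
    P[["bot_c1_W"]] <- he(9L, f[spec$depth], fb)
    P[["bot_c1_b"]] <- numeric(fb)
    P[["bot_c2_W"]] <- he(9L, fb, fb)
    P[["bot_c2_b"]] <- numeric(fb)
    prev <- fb
    for (d in rev(seq_len(spec$depth))) {
      P[[sprintf("dec%d_up_W", d)]] <- he(4L, prev, f[d])
      P[[sprintf("dec%d_up_b", d)]] <- numeric(f[d])
      P[[sprintf("dec%d_c1_W", d)]] <- he(9L, 2L * f[d], f[d])
      P[[sprintf("dec%d_c1_b", d)]] <- numeric(f[d])
      P[[sprintf("dec%d_c2_W", d)]] <- he(9L, f[d], f[d])
      P[[sprintf("dec%d_c2_b", d)]] <- numeric(f[d])
      prev <- f[d]
    }
    # near-zero output head: the initial prediction then starts at the
    # all-zero collapse point and spikes grow where the blurred-MSE reward
    # beats the L1 cost (no normalization layers exist to tame a He-scaled
    # head, whose huge initial output would dominate early training)
    P[["out_W"]] <- 0.01 * he(1L, f[1], 1L)
    P[["out_b"]] <- numeric(1L)
    P
  })
}

# Bilinear resampling onto the fine grid: fine index fi (0-based) samples the
# coarse image at coordinate fi / U, matching the spike convention
# round(position_px * U).
.upsample_bilinear <- function(m, U) {
  wmat <- function(n) {
    fine <- (seq_len(n * U) - 1) / U
    lo <- pmin(floor(fine), n - 1)
    hi <- pmin(lo + 1, n - 1)
    t <- fine - lo
    W <- matrix(0, n * U, n_coarse <- n)
    idx <- seq_len(n * U)
    W[cbind(idx, lo + 1)] <- W[cbind(idx, lo + 1)] + (1 - t)
    W[cbind(idx, hi + 1)] <- W[cbind(idx, hi + 1)] + t
    W
  }
  Wr <- wmat(nrow(m))
  Wc <- wmat(ncol(m))
  Wr %*% m %*% t(Wc)
}

# Background-robust normalization: subtract the image median (~background)
# and divide by a fixed scale. The scale is estimated once from the training
# set and stored in the model, so that training patches and full test frames
# (whose emitter densities per pixel differ) are normalized consistently.
.normalize_patch <- function(m, scale = NULL) {
  c0 <- m - median(m)
  if (is.null(scale)) scale <- sd(c0) + 1e-6
  c0 / scale
}

#' Localization training loss
#'
#' Combined loss for the localizer: squared error between the
#' Gaussian-blurred prediction and the Gaussian-blurred spike target, plus an
#' L1 sparsity penalty on the raw prediction:
#' `sum((g * (pred - target))^2) + l1_weight * sum(|pred|)`.
#'
#' The kernel `g` is normalized to unit peak (not unit mass): with unit
#' target spikes this keeps the squared-error reward for emitting a spike
#' (`sum(g^2)`, about `pi * sigma^2`) above its L1 cost, so the all-zero
#' prediction is not a minimizer.
#'
#' @param pred_grid,target_grid same-shape matrices on the upsampled grid.
#' @param g_sigma sd of the Gaussian kernel `g` (upsampled px).
#' @param l1_weight weight of the L1 term (default 1).
#' @return scalar loss.
#' @export
loss_loc <- function(pred_grid, target_grid, g_sigma = 1, l1_weight = 1) {
  if (!all(dim(pred_grid) == dim(target_grid)))
    stop("prediction and target grids must have the same shape")
  g <- .loss_kernel(g_sigma)
  cpp_loss_loc(pred_grid, target_grid, g, l1_weight)
}

# Gaussian loss kernel, unit peak.
.loss_kernel <- function(sigma) {
  g <- gauss_kernel2d(sigma)
  g / max(g)
}

# ---------------------------------------------------------------- Adam

.adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    dim(g) <- dim(state$m[[nm]])
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    d <- dim(params[[nm]])
    p <- params[[nm]] - as.vector(upd)
    dim(p) <- d
    params[[nm]] <- p
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------- training

#' Train the U-Net localizer on simulated patches
#'
#' Minimizes [loss_loc()] with Adam. The training pairs are split 90:10 into
#' training and validation sets; the parameters with the best validation
#' loss are retained.
#'
#' @param pairs list of `training_pair_spatial`
#'   (see [make_spatial_training_set()]).
#' @param spec a [localizer_spec()].
#' @param epochs training epochs; `0` returns the randomly initialized model.
#' @param val_fraction validation fraction (default 0.1).
#' @param seed seed for initialization and shuffling.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param verbose print one line per epoch.
#' @return object of class `localizer_model` with fields `params`, `spec`,
#'   `history` (data.frame epoch/train_loss/val_loss).
#' @export
train_localizer <- function(pairs, spec = localizer_spec(), epochs = 30L,
                            val_fraction = 0.1, seed = NULL, lr = 1e-3,
                            batch_size = 16L, verbose = FALSE) {
  if (!length(pairs)) stop("no training pairs")
  U <- spec$upsampling
  if (any(vapply(pairs, `[[`, integer(1), "upsampling") != U))
    stop("pairs were built with a different upsampling factor than the spec")
  g <- .loss_kernel(spec$loss_kernel_sigma)

  .with_seed(seed, {
    params <- .init_localizer_params(spec)
    n <- length(pairs)
    idx <- sample.int(n)
    n_val <- if (n >= 10) max(1L, round(val_fraction * n)) else 0L
    val_idx <- head(idx, n_val)
    tr_idx <- setdiff(idx, val_idx)

    # one global normalization scale for the whole model
    sub <- pairs[seq_len(min(500L, n))]
    norm_scale <- sd(unlist(lapply(sub, function(p)
      p$input_patch - median(p$input_patch)))) + 1e-6

    make_batch <- function(ids) {
      ps <- nrow(pairs[[ids[1]]]$input_patch)
      nf <- ps * U
      xb <- array(0, c(nf, nf, length(ids)))
      tb <- array(0, c(nf, nf, length(ids)))
      for (k in seq_along(ids)) {
        p <- pairs[[ids[k]]]
        xb[, , k] <- .upsample_bilinear(
          .normalize_patch(p$input_patch, norm_scale), U)
        tb[, , k] <- spatial_target_grid(p, spike_mass = spec$spike_mass %||% 1)
      }
      list(x = xb, t = tb)
    }

    eval_loss <- function(ids) {
      if (!length(ids)) return(NA_real_)
      tot <- 0
      for (ch in split(ids, ceiling(seq_along(ids) / batch_size))) {
        b <- make_batch(ch)
        pr <- cpp_unet_predict(params, spec$depth, b$x)
        for (k in seq_along(ch))
          tot <- tot + cpp_loss_loc(pr[, , k], b$t[, , k], g, spec$l1_weight)
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
          lg <- cpp_unet_loss_grad(params, spec$depth, b$x, b$t, g,
                                   spec$l1_weight)
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
          message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                          ep_loss / nb, vl))
      }
    }
    final <- if (is.finite(best$val)) best$params else params
    structure(list(params = final, spec = spec, history = hist,
                   norm_scale = norm_scale),
              class = "localizer_model")
  })
}

#' @export
print.localizer_model <- function(x, ...) {
  cat(sprintf("U-Net localizer: depth %d, base %d filters, upsampling %dx\n",
              x$spec$depth, x$spec$base_filters, x$spec$upsampling))
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs, best val loss %.4f\n",
                max(x$history$epoch), min(x$history$val_loss, na.rm = TRUE)))
  else cat("  untrained (random initialization)\n")
  invisible(x)
}

# Run the network on one spatial frame; returns the clamped prediction grid
# cropped to frame_size * U.
.predict_grid <- function(model, frame) {
  spec <- model$spec
  U <- spec$upsampling
  ny <- nrow(frame)
  nx <- ncol(frame)
  div <- 2^spec$depth
  pad_y <- (div - (ny * U) %% div) %% div
  pad_x <- (div - (nx * U) %% div) %% div
  up <- .upsample_bilinear(.normalize_patch(frame, model$norm_scale %||% NULL),
                           U)
  if (pad_y || pad_x) {
    padded <- matrix(0, nrow(up) + pad_y, ncol(up) + pad_x)
    padded[seq_len(nrow(up)), seq_len(ncol(up))] <- up
    up <- padded
  }
  xb <- array(up, c(nrow(up), ncol(up), 1L))
  pr <- cpp_unet_predict(model$params, spec$depth, xb)[, , 1]
  pr <- pr[seq_len(ny * U), seq_len(nx * U), drop = FALSE]
  pmax(pr, 0)
}

#' Localize emitters on a spatial frame
#'
#' Runs the trained U-Net on the (internally upsampled) frame and extracts
#' local maxima of the prediction grid: pixels that dominate their
#' 8-neighborhood and exceed `threshold * max(grid)`. Maxima closer than
#' `min_separation` (upsampled px) are merged into the brighter one.
#' Grid indices convert to nm through `camera_pixel_size / upsampling`.
#'
#' @param model a `localizer_model`.
#' @param frame spatial image (matrix).
#' @param camera_pixel_size camera pixel size (nm).
#' @param threshold fraction of the grid maximum (default 0.1).
#' @param min_separation minimum separation in upsampled px
#'   (default: the upsampling factor).
#' @param min_value absolute floor on the prediction value, as a fraction
#'   of the model's per-emitter spike mass, below which maxima are ignored;
#'   keeps background-only frames from producing detections.
#' @return data.frame with `x_nm`, `y_nm`, `intensity` (possibly 0 rows).
#' @export
predict_localizations <- function(model, frame, camera_pixel_size,
                                  threshold = 0.1,
                                  min_separation = model$spec$upsampling,
                                  min_value = 0.05) {
  min_value <- min_value * (model$spec$spike_mass %||% 1)
  grid <- .predict_grid(model, frame)
  pk <- find_local_maxima(grid, threshold = threshold,
                          min_separation = min_separation,
                          min_value = min_value)
  U <- model$spec$upsampling
  data.frame(x_nm = pk$col / U * camera_pixel_size,
             y_nm = pk$row / U * camera_pixel_size,
             intensity = pk$value)
}

#' 8-connected local maxima of an image
#'
#' @param grid numeric matrix (values >= 0 expected).
#' @param threshold fraction of the global maximum below which maxima are
#'   ignored.
#' @param min_separation merge radius (px, Euclidean); among maxima closer
#'   than this, only the brightest survives.
#' @param min_value absolute value floor (default 0: purely relative).
#' @return data.frame with 0-based `row`, `col` and `value`.
#' @export
find_local_maxima <- function(grid, threshold = 0.1, min_separation = 0,
                              min_value = 0) {
  mx <- max(grid)
  if (!is.finite(mx) || mx <= 0)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  thr <- max(threshold * mx, min_value)
  n1 <- nrow(grid)
  n2 <- ncol(grid)
  shift <- function(dr, dc) {
    out <- matrix(-Inf, n1, n2)
    r1 <- max(1, 1 + dr):min(n1, n1 + dr)
    c1 <- max(1, 1 + dc):min(n2, n2 + dc)
    out[r1, c1] <- grid[r1 - dr, c1 - dc]
    out
  }
  is_max <- grid > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (grid >= shift(dr, dc))
  }
  w <- which(is_max, arr.ind = TRUE)
  if (!nrow(w))
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  v <- grid[w]
  ord <- order(v, decreasing = TRUE)
  w <- w[ord, , drop = FALSE]
  v <- v[ord]
  keep <- logical(length(v))
  for (i in seq_along(v)) {
    if (min_separation > 0 && any(keep)) {
      d2 <- (w[keep, 1] - w[i, 1])^2 + (w[keep, 2] - w[i, 2])^2
      if (any(d2 < min_separation^2)) next
    }
    keep[i] <- TRUE
  }
  data.frame(row = w[keep, 1] - 1L, col = w[keep, 2] - 1L, value = v[keep])
}
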