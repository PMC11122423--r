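# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pixel-integrated 1-D Gaussian profile
#'
#' Integral of a normal density with mean `mu` and sd `sigma` over unit
#' pixels centered at integer indices `idx` (0-based centers).
#' @noRd
.pix_gauss <- function(idx, mu, sigma) {
  pnorm(idx + 0.5, mu, sigma) - pnorm(idx - 0.5, mu, sigma)
}

#' Normalized 2-D Gaussian kernel on an odd-sized grid
#' @param sigma standard deviation in pixels
#' @param radius half-width; defaults to `ceiling(3 * sigma)`
#' @return matrix of odd dimension summing to 1
#' @export
gauss_kernel2d <- function(sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0)
  x <- seq(-radius, radius)
  k1 <- dnorm(x, sd = sigma)
  k <- outer(k1, k1)
  k / sum(k)
}

# Separable Gaussian blur with symmetric (reflect) edge padding.
.gauss_blur2d <- function(m, sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- dnorm(x, sd = sigma)
  k <- k / sum(k)
  .sepconv2(m, k, k)
}

# Separable convolution with reflect padding; kr filters rows, kc columns.
.sepconv2 <- function(m, kr, kc) {
  pr <- (length(kr) - 1L) / 2L
  pc <- (length(kc) - 1L) / 2L
  m2 <- .pad_reflect(m, pr, pc)
  # band matrix approach: rows
  n1 <- nrow(m)
  n2 <- ncol(m)
  out <- matrix(0, n1, ncol(m2))
  for (s in seq_along(kr)) {
    out <- out + kr[s] * m2[s:(s + n1 - 1L), , drop = FALSE]
  }
  res <- matrix(0, n1, n2)
  for (s in seq_along(kc)) {
    res <- res + kc[s] * out[, s:(s + n2 - 1L), drop = FALSE]
  }
  res
}

.pad_reflect <- function(m, pr, pc) {
  n1 <- nrow(m)
  n2 <- ncol(m)
  ri <- c(rev(seq_len(min(pr, n1))), seq_len(n1),
          n1 + 1L - seq_len(min(pr, n1)))
  ri <- ri[seq_len(n1 + 2L * pr)]
  ci <- c(rev(seq_len(min(pc, n2))), seq_len(n2),
          n2 + 1L - seq_len(min(pc, n2)))
  ci <- ci[seq_len(n2 + 2L * pc)]
  m[ri, ci, drop = FALSE]
}

# Deterministic local RNG scope: runs `expr` under `seed` (if non-NULL) and
# restores the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assert_scalar_pos <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", nm),
         call. = FALSE)
  invisible(x)
}
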