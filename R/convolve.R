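#' Value of the 3D Gaussian kernel
#'
#' Evaluates the isotropic three-dimensional Gaussian
#' \deqn{G(v, \sigma) = (2\pi)^{-3/2} \sigma^{-3}
#'   \exp\left(-\|v\|^2 / (2\sigma^2)\right)}
#' used as the smoothing kernel of the scale-space filter bank. `sigma` is
#' the standard deviation in millimetres, i.e. the scale at which texture is
#' examined.
#'
#' @param v Numeric 3-vector (offset in mm), or an n-by-3 matrix of offsets.
#' @param sigma Positive scalar standard deviation in mm.
#' @return Kernel value(s); a scalar for a single offset.
#' @examples
#' gaussian_kernel_value(c(0, 0, 0), 1)  # (2*pi)^(-3/2)
#' @export
gaussian_kernel_value <- function(v, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stopf("sigma must be a positive scalar")
  if (is.matrix(v)) {
    if (ncol(v) != 3L) stopf("v must have 3 columns")
    nrm2 <- rowSums(v^2)
  } else {
    if (length(v) != 3L) stopf("v must be a 3-vector")
    nrm2 <- sum(v^2)
  }
  (2 * pi)^(-1.5) * sigma^(-3) * exp(-nrm2 / (2 * sigma^2))
}

# Sampled 1D Gaussian (derivative) kernel for separable convolution.
# order 0/1/2; sigma and spacing in mm; truncated at 4 sigma. Discrete moment
# corrections make the order-0 kernel sum to 1, the order-1 kernel reproduce
# the exact derivative of a linear ramp, and the order-2 kernel reproduce the
# exact second derivative of a quadratic.
gauss_kernel_1d <- function(sigma_mm, spacing_mm, order = 0L) {
  if (sigma_mm <= 0) stopf("sigma must be positive")
  sig_vox <- sigma_mm / spacing_mm
  if (sig_vox < 0.3)
    stopf("sigma of %.3g mm is under 0.3 voxels at %.3g mm spacing; kernel undersampled",
          sigma_mm, spacing_mm)
  r <- max(1L, ceiling(4 * sig_vox))
  k <- (-r):r
  t <- k * spacing_mm
  g <- exp(-t^2 / (2 * sigma_mm^2))
  if (order == 0L) {
    w <- g / sum(g)
  } else if (order == 1L) {
    w <- t / sigma_mm^2 * g           # +t: correlation form, see below
    w <- w / sum(w * t)               # exact on f(x) = x
  } else if (order == 2L) {
    w <- (t^2 - sigma_mm^2) / sigma_mm^4 * g
    w <- w - mean(w)                  # zero response to constants
    w <- w * 2 / sum(w * t^2)         # exact on f(x) = x^2 (f'' = 2)
  } else stopf("order must be 0, 1 or 2")
  w
}

# Banded correlation matrix: (B %*% f)[i] = sum_k w[k] f[i + k], zero-padded.
conv_band_matrix <- function(n, w) {
  r <- (length(w) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (k in -r:r) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1L & j <= n
    B[cbind(i[ok], j[ok])] <- w[k + r + 1L]
  }
  B
}

# Correlate a 3D array along one axis with a 1D kernel, zero-padded outside
# the volume. Implemented as banded matrix products so BLAS does the work;
# the middle axis is handled slice-by-slice to avoid aperm copies.
conv_axis <- function(a, w, axis) {
  d <- dim(a)
  n <- d[axis]
  B <- conv_band_matrix(n, w)
  if (axis == 1L) {
    out <- B %*% matrix(a, n, d[2] * d[3])
  } else if (axis == 3L) {
    out <- matrix(a, d[1] * d[2], n) %*% t(B)
  } else {
    out <- array(0, d)
    tB <- t(B)
    for (k in seq_len(d[3])) out[, , k] <- a[, , k] %*% tB
  }
  dim(out) <- d
  out
}

# Separable 3D Gaussian(-derivative) correlation. orders = c(ox, oy, oz).
conv_separable <- function(a, sigma_mm, spacing_mm, orders = c(0L, 0L, 0L)) {
  spacing_mm <- rep_len(spacing_mm, 3L)
  for (ax in 1:3) {
    w <- gauss_kernel_1d(sigma_mm, spacing_mm[ax], orders[ax])
    a <- conv_axis(a, w, ax)
  }
  a
}

# Full second-order Gaussian jet of a volume: the 10 separable correlations
# up to total derivative order 2, sharing partial passes (19 axis passes
# instead of 30). Returns a named list s, dx, dy, dz, dxx, dyy, dzz, dxy,
# dxz, dyz.
gauss_jet <- function(a, sigma_mm, spacing_mm) {
  spacing_mm <- rep_len(spacing_mm, 3L)
  ker <- lapply(1:3, function(ax)
    lapply(0:2, function(o) gauss_kernel_1d(sigma_mm, spacing_mm[ax], o)))
  cx <- function(v, o) conv_axis(v, ker[[1]][[o + 1L]], 1L)
  cy <- function(v, o) conv_axis(v, ker[[2]][[o + 1L]], 2L)
  cz <- function(v, o) conv_axis(v, ker[[3]][[o + 1L]], 3L)
  x0 <- cx(a, 0L); x1 <- cx(a, 1L); x2 <- cx(a, 2L)
  x0y0 <- cy(x0, 0L); x0y1 <- cy(x0, 1L); x0y2 <- cy(x0, 2L)
  x1y0 <- cy(x1, 0L); x1y1 <- cy(x1, 1L)
  x2y0 <- cy(x2, 0L)
  list(s   = cz(x0y0, 0L),
       dx  = cz(x1y0, 0L), dy  = cz(x0y1, 0L), dz  = cz(x0y0, 1L),
       dxx = cz(x2y0, 0L), dyy = cz(x0y2, 0L), dzz = cz(x0y0, 2L),
       dxy = cz(x1y1, 0L), dxz = cz(x1y0, 1L), dyz = cz(x0y1, 1L))
}
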