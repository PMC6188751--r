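#' Configuration for the Gaussian filter-bank features
#'
#' Eight rotation-invariant filters (Gaussian-smoothed intensity, gradient
#' magnitude, Laplacian of Gaussian, the three Hessian eigenvalues sorted in
#' descending signed order, Gaussian curvature `det(H)` and eigen magnitude
#' `sqrt(sum(lambda^2))`) computed at each scale, with in-mask responses
#' summarized by 10-bin adaptive histograms. Defaults: scales 0.6, 1.2, 2.4
#' and 4.8 mm; 10 bins. 8 filters x 4 scales x 10 bins = 320 features.
#'
#' @param scales_mm Gaussian standard deviations in mm.
#' @param n_bins Histogram bins per (filter, scale) channel.
#' @return An object of class `gauss_config`.
#' @export
gauss_config <- function(scales_mm = c(0.6, 1.2, 2.4, 4.8), n_bins = 10L) {
  stopifnot(all(scales_mm > 0), is_count(n_bins), n_bins >= 2)
  structure(list(scales_mm = as.numeric(scales_mm),
                 filters = gauss_filter_names(),
                 n_bins = as.integer(n_bins)),
            class = "gauss_config")
}

gauss_filter_names <- function() {
  c("smoothed", "gradmag", "laplacian", "hess1", "hess2", "hess3",
    "gausscurv", "eigmag")
}

#' Gaussian scale-space filter bank with normalized convolution
#'
#' Smooths and differentiates a 3D volume at scale `sigma_mm` restricted to
#' a mask: outside-mask voxels carry zero weight, so responses near the mask
#' boundary are renormalized rather than contaminated (normalized
#' convolution). Derivatives are Gaussian-derivative correlations of the
#' masked volume divided by the smoothed mask; a constant volume therefore
#' smooths to that constant everywhere inside the mask.
#'
#' @param volume 3D numeric array (HU).
#' @param mask Logical/0-1 array of the same shape; responses are defined
#'   only inside it.
#' @param sigma_mm Scale (Gaussian standard deviation) in mm; must be at
#'   least 0.3 voxels at the given spacing.
#' @param spacing_mm Voxel size per axis in mm (recycled to length 3).
#' @return Named list of 8 response arrays (NA outside the mask), in the
#'   order of `gauss_filter_names()`.
#' @export
filter_bank <- function(volume, mask, sigma_mm, spacing_mm = c(1, 1, 1)) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L) stopf("volume must be a 3D array")
  m <- array(as.numeric(mask != 0), d)
  if (sum(m) == 0) stopf("mask is empty")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  vm <- volume * m

  wden <- conv_separable(m, sigma_mm, spacing_mm, c(0L, 0L, 0L))
  wden[wden < 1e-10] <- NA_real_
  jet <- gauss_jet(vm, sigma_mm, spacing_mm)
  jet <- lapply(jet, function(r) r / wden)
  s <- jet$s
  gx <- jet$dx; gy <- jet$dy; gz <- jet$dz
  hxx <- jet$dxx; hyy <- jet$dyy; hzz <- jet$dzz
  hxy <- jet$dxy; hxz <- jet$dxz; hyz <- jet$dyz

  gradmag <- sqrt(gx^2 + gy^2 + gz^2)
  laplacian <- hxx + hyy + hzz
  eig <- sym3_eigenvalues(hxx, hyy, hzz, hxy, hxz, hyz)
  gausscurv <- hxx * (hyy * hzz - hyz^2) - hxy * (hxy * hzz - hyz * hxz) +
    hxz * (hxy * hyz - hyy * hxz)
  eigmag <- sqrt(hxx^2 + hyy^2 + hzz^2 + 2 * (hxy^2 + hxz^2 + hyz^2))

  out <- list(smoothed = s, gradmag = gradmag, laplacian = laplacian,
              hess1 = eig$l1, hess2 = eig$l2, hess3 = eig$l3,
              gausscurv = gausscurv, eigmag = eigmag)
  outside <- m == 0
  lapply(out, function(r) { r[outside] <- NA_real_; array(r, d) })
}

# Vectorized eigenvalues of symmetric 3x3 matrices (trigonometric method),
# sorted descending (l1 >= l2 >= l3).
sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detb <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- detb / 2 / pmax(p, .Machine$double.xmin)^3
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  zero <- !is.na(p) & p < 1e-300
  l1[zero] <- q[zero]; l2[zero] <- q[zero]; l3[zero] <- q[zero]
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Fit adaptive histogram bins from reference responses
#'
#' Adaptive binning places the interior bin edges at the empirical
#' `j/n_bins` quantiles (j = 1, ..., n_bins - 1) of reference filter
#' responses pooled over an independent reference set, so every bin captures
#' an equal share of reference mass; the outer edges are -Inf and +Inf.
#'
#' @param responses Named list with one numeric vector of reference samples
#'   per (filter, scale) channel; names like `"s1.2_hess1"`.
#' @param n_bins Number of bins.
#' @return Object of class `binning_model`: list of numeric edge vectors of
#'   length `n_bins + 1`.
#' @export
fit_adaptive_bins <- function(responses, n_bins = 10L) {
  stopifnot(is.list(responses), length(responses) > 0, n_bins >= 2)
  edges <- lapply(responses, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 10L * n_bins)
      stopf("need at least %d reference samples per channel, got %d",
            10L * n_bins, length(x))
    inner <- stats::quantile(x, probs = seq_len(n_bins - 1L) / n_bins,
                             names = FALSE, type = 7)
    if (any(diff(inner) <= 0))
      stopf("degenerate reference responses: non-increasing quantile edges")
    c(-Inf, inner, Inf)
  })
  structure(list(edges = edges, n_bins = as.integer(n_bins)),
            class = "binning_model")
}

#' Gaussian filter-bank feature vector of a masked patch
#'
#' Runs the 8-filter bank at every configured scale and summarizes each
#' response channel by a histogram over the fixed adaptive bins, normalized
#' to sum to one. Channels are concatenated scale-major then filter; default
#' configuration gives 8 x 4 x 10 = 320 features.
#'
#' @param patch 3D numeric array in HU.
#' @param mask Same-shape binary mask (in-lung voxels).
#' @param config A [gauss_config()].
#' @param binning A `binning_model` from [fit_adaptive_bins()] whose channel
#'   names cover `scale x filter` combinations (`"s<scale>_<filter>"`).
#' @param spacing_mm Voxel spacing in mm.
#' @return Named numeric feature vector.
#' @export
gauss_features <- function(patch, mask = NULL, config = gauss_config(),
                           binning = NULL, spacing_mm = c(1, 1, 1)) {
  if (is.null(mask)) mask <- array(1, dim(patch))
  if (sum(mask != 0) == 0L) stopf("empty in-mask patch region")
  if (is.null(binning)) stopf("a fitted binning_model is required")
  out <- numeric(0)
  for (sig in config$scales_mm) {
    bank <- filter_bank(patch, mask, sig, spacing_mm)
    for (f in config$filters) {
      ch <- sprintf("s%g_%s", sig, f)
      e <- binning$edges[[ch]]
      if (is.null(e)) stopf("binning model has no channel '%s'", ch)
      v <- bank[[f]][mask != 0]
      v <- v[is.finite(v)]
      h <- hist_fixed(v, e)
      names(h) <- sprintf("gauss_s%g_%s_bin%02d", sig, f, seq_along(h))
      out <- c(out, h)
    }
  }
  out
}

# Normalized histogram over fixed edges (first/last edge infinite).
hist_fixed <- function(x, edges) {
  n_bins <- length(edges) - 1L
  if (length(x) == 0L) stopf("no finite response samples to histogram")
  b <- findInterval(x, edges, left.open = FALSE)
  b <- pmin(pmax(b, 1L), n_bins)
  counts <- tabulate(b, nbins = n_bins)
  counts / sum(counts)
}

# Channel names used by fit_adaptive_bins / gauss_features.
gauss_channel_names <- function(config = gauss_config()) {
  as.vector(t(outer(config$scales_mm, config$filters,
                    function(s, f) sprintf("s%g_%s", s, f))))
}

#' Serialize / read a binning model as plain text
#'
#' One row per channel, tab-separated interior edges.
#' @param binning A `binning_model`.
#' @param path Output file path.
#' @export
write_binning <- function(binning, path) {
  lines <- vapply(names(binning$edges), function(ch) {
    inner <- binning$edges[[ch]]
    inner <- inner[is.finite(inner)]
    paste(c(ch, format(inner, digits = 17)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_binning
#' @export
read_binning <- function(path) {
  lines <- readLines(path)
  edges <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    edges[[parts[1]]] <- c(-Inf, as.numeric(parts[-1]), Inf)
  }
  nb <- length(edges[[1]]) - 1L
  structure(list(edges = edges, n_bins = nb), class = "binning_model")
}
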