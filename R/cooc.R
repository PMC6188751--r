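#' Configuration for 3D co-occurrence features
#'
#' Defines quantization and co-occurrence geometry for the Haralick texture
#' representation: HU values are clamped to `hu_window` and linearly binned
#' into `n_levels` gray levels; co-occurrence is evaluated along the 13
#' unique (pairwise non-antiparallel) 3D neighbor directions at each of the
#' given voxel `distances`.
#'
#' @param n_levels Number of gray levels (default 32).
#' @param distances Integer voxel distances (default 1:5).
#' @param symmetric Accumulate each pair in both orders (default TRUE).
#' @param hu_window Length-2 numeric, HU clamp `(low, high)`
#'   (default c(-1024, 0)).
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(n_levels = 32L, distances = 1:5, symmetric = TRUE,
                        hu_window = c(-1024, 0)) {
  stopifnot(is_count(n_levels), n_levels >= 2,
            all(distances >= 1), all(distances == round(distances)),
            is_flag(symmetric), length(hu_window) == 2L)
  if (hu_window[1] >= hu_window[2]) stopf("hu_window must satisfy low < high")
  structure(list(n_levels = as.integer(n_levels),
                 distances = as.integer(distances),
                 directions = glcm_directions(),
                 symmetric = symmetric,
                 hu_window = as.numeric(hu_window)),
            class = "glcm_config")
}

#' The 13 unique 3D co-occurrence directions
#'
#' The 26 face/edge/corner neighbors of a voxel come in antiparallel pairs;
#' one representative per pair gives 13 directions, returned as a 13-by-3
#' integer matrix in a fixed documented order (lexicographic over
#' offsets with positive leading nonzero component).
#'
#' @return 13-by-3 integer matrix of offsets.
#' @export
glcm_directions <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  # keep one of each antiparallel pair: first nonzero component positive
  keep <- apply(off, 1L, function(v) v[which(v != 0)[1L]] > 0)
  off <- off[keep, , drop = FALSE]
  off <- off[order(off[, 1], off[, 2], off[, 3]), , drop = FALSE]
  dimnames(off) <- list(NULL, c("dx", "dy", "dz"))
  storage.mode(off) <- "integer"
  off
}

#' Quantize an HU patch to discrete gray levels
#'
#' Clamps to the configured HU window and linearly bins into
#' `config$n_levels` equal-width bins; values at the upper clamp map to the
#' top level.
#'
#' @param patch 3D numeric array in HU.
#' @param config A [glcm_config()].
#' @return Integer array of the same shape with values in
#'   `0:(n_levels - 1)`.
#' @export
quantize_hu <- function(patch, config = glcm_config()) {
  if (length(patch) == 0L) stopf("empty patch")
  lo <- config$hu_window[1]; hi <- config$hu_window[2]
  x <- pmin(pmax(patch, lo), hi)
  q <- floor((x - lo) / (hi - lo) * config$n_levels)
  q <- pmin(q, config$n_levels - 1L)
  storage.mode(q) <- "integer"
  if (!is.null(dim(patch))) dim(q) <- dim(patch)
  q
}

#' Gray-level co-occurrence matrix of a quantized 3D patch
#'
#' Counts ordered voxel pairs `(v, v + distance * direction)` with both ends
#' inside the patch; with `symmetric = TRUE` the transpose is accumulated as
#' well. The matrix is normalized to sum to one.
#'
#' @param quantized Integer 3D array with values in `0:(n_levels - 1)`.
#' @param direction Integer 3-vector offset (one of [glcm_directions()]).
#' @param distance Positive integer voxel distance.
#' @param n_levels Number of gray levels.
#' @param symmetric Accumulate both pair orders.
#' @return `n_levels`-by-`n_levels` matrix of joint probabilities.
#' @export
glcm <- function(quantized, direction, distance = 1L,
                 n_levels = max(quantized) + 1L, symmetric = TRUE) {
  d <- dim(quantized)
  if (is.null(d) || length(d) != 3L) stopf("quantized must be a 3D array")
  stopifnot(length(direction) == 3L, distance >= 1)
  off <- as.integer(direction) * as.integer(distance)
  idx <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax])
    j <- i + off[ax]
    ok <- j >= 1L & j <= d[ax]
    list(src = i[ok], dst = j[ok])
  })
  if (any(vapply(idx, function(z) length(z$src) == 0L, logical(1))))
    stopf("distance %d along direction (%s) leaves no voxel pairs",
          distance, paste(direction, collapse = ","))
  a <- quantized[idx[[1]]$src, idx[[2]]$src, idx[[3]]$src, drop = FALSE]
  b <- quantized[idx[[1]]$dst, idx[[2]]$dst, idx[[3]]$dst, drop = FALSE]
  counts <- tabulate(as.vector(a) + n_levels * as.vector(b) + 1L,
                     nbins = n_levels^2)
  m <- matrix(counts, n_levels, n_levels)
  if (symmetric) m <- m + t(m)
  m / sum(m)
}

#' The 12 Haralick statistics of a normalized GLCM
#'
#' Computes, in this fixed order: energy, entropy, correlation, contrast,
#' homogeneity, variance, sum mean, inverse difference moment, inertia,
#' cluster shade, cluster tendency, max probability. Gray levels enter the
#' formulas as their 0-based indices. Entropy is in bits (log base 2) with
#' zero-probability terms contributing zero; correlation is defined as 0
#' when a marginal variance vanishes. With the formulations used here
#' contrast and inertia coincide (both are \eqn{\sum (i-j)^2 p_{ij}}); both
#' are reported as named.
#'
#' @param p Normalized GLCM matrix (entries sum to 1).
#' @return Named numeric vector of length 12.
#' @export
haralick <- function(p) {
  if (abs(sum(p) - 1) > 1e-8) stopf("GLCM must be normalized to sum 1")
  L <- nrow(p)
  i <- matrix(0:(L - 1L), L, L)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  lev <- 0:(L - 1L)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  energy <- sum(p^2)
  entropy <- -sum(ifelse(p > 0, p * log2(p), 0))
  correlation <- if (sx > 0 && sy > 0)
    (sum(i * j * p) - mux * muy) / (sx * sy) else 0
  contrast <- sum((i - j)^2 * p)
  homogeneity <- sum(p / (1 + abs(i - j)))
  variance <- sum((i - mux)^2 * p)
  sum_mean <- sum((i + j) / 2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  inertia <- contrast
  dev <- i + j - mux - muy
  cluster_shade <- sum(dev^3 * p)
  cluster_tendency <- sum(dev^2 * p)
  max_probability <- max(p)
  c(energy = energy, entropy = entropy, correlation = correlation,
    contrast = contrast, homogeneity = homogeneity, variance = variance,
    sum_mean = sum_mean, inverse_difference_moment = idm, inertia = inertia,
    cluster_shade = cluster_shade, cluster_tendency = cluster_tendency,
    max_probability = max_probability)
}

#' Co-occurrence (Haralick) feature vector of a 3D patch
#'
#' For each of the 13 directions and each configured distance, builds the
#' GLCM and computes the 12 Haralick statistics, concatenated
#' direction-major (direction, then distance, then statistic). The default
#' configuration yields 13 x 5 x 12 = 780 features.
#'
#' @param patch 3D numeric array in HU.
#' @param config A [glcm_config()].
#' @return Named numeric feature vector.
#' @export
cooc_features <- function(patch, config = glcm_config()) {
  q <- quantize_hu(patch, config)
  dirs <- config$directions
  out <- numeric(0)
  for (di in seq_len(nrow(dirs))) {
    for (dist in config$distances) {
      p <- glcm(q, dirs[di, ], dist, config$n_levels, config$symmetric)
      h <- haralick(p)
      names(h) <- sprintf("cooc_d%d_dir(%d,%d,%d)_%s", dist,
                          dirs[di, 1], dirs[di, 2], dirs[di, 3], names(h))
      out <- c(out, h)
    }
  }
  out
}
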