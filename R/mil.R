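#' Construct a bag of instances
#'
#' A bag is one subject's set of instances: feature vectors of the patches
#' sampled from that subject's scan. The bag carries the weak label derived
#' from a pulmonary function test: `+1` (diseased / low DLCO) or `-1`,
#' or `NA` when unknown.
#'
#' @param features Numeric matrix, one row per instance.
#' @param label Bag label: +1, -1 or NA.
#' @param subject_id Identifier shared by all instances of the bag.
#' @param centers Optional matrix of patch-center voxel coordinates.
#' @param label_channel Optional tag, e.g. "copd" or "dlco".
#' @return An object of class `mil_bag`.
#' @export
mil_bag <- function(features, label = NA, subject_id = NULL, centers = NULL,
                    label_channel = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 1L) stopf("a bag needs at least one instance")
  if (any(!is.finite(features))) stopf("instance features must be finite")
  if (!is.na(label) && !label %in% c(-1, 1))
    stopf("bag label must be +1, -1 or NA")
  structure(list(features = features, label = label,
                 subject_id = subject_id, centers = centers,
                 label_channel = label_channel),
            class = "mil_bag")
}

#' Labels of a list of bags
#' @param bags List of [mil_bag()]s.
#' @return Numeric vector of +1/-1/NA labels.
#' @export
bag_labels <- function(bags) vapply(bags, function(b) as.numeric(b$label), numeric(1))

bag_matrix <- function(bags) do.call(rbind, lapply(bags, `[[`, "features"))

bag_index <- function(bags) {
  rep(seq_along(bags), vapply(bags, function(b) nrow(b$features), integer(1)))
}

#' Kernel specification
#'
#' Either an inhomogeneous polynomial kernel \eqn{(x \cdot z + 1)^p} with
#' degree 1 or 2, or a radial basis kernel
#' \eqn{\exp(-\|x - z\|^2 / (2 b^2))} with bandwidth `b`. Bandwidths are
#' meant for z-scored features (see [misvm_q()]), where the grid
#' 8, 10, 12, 14, 16, 20 is sensible for a few hundred dimensions.
#'
#' @param family "polynomial" or "rbf".
#' @param degree Polynomial degree (1 or 2).
#' @param bandwidth RBF bandwidth (> 0).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("rbf", "polynomial"), degree = 1L,
                        bandwidth = 12) {
  family <- match.arg(family)
  if (family == "polynomial" && !degree %in% c(1L, 2L))
    stopf("polynomial degree must be 1 or 2")
  if (family == "rbf" && bandwidth <= 0) stopf("bandwidth must be positive")
  structure(list(family = family, degree = as.integer(degree),
                 bandwidth = as.numeric(bandwidth)),
            class = "kernel_spec")
}

#' Evaluate a kernel between instance sets
#'
#' @param x,z Numeric matrices (rows = instances) or vectors.
#' @param spec A [kernel_spec()].
#' @return The kernel matrix `nrow(x)` by `nrow(z)`.
#' @export
mil_kernel <- function(x, z, spec = kernel_spec()) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(z)) z <- matrix(z, nrow = 1L)
  if (ncol(x) != ncol(z)) stopf("kernel inputs have mismatched dimension")
  if (spec$family == "polynomial") {
    (x %*% t(z) + 1)^spec$degree
  } else {
    d2 <- outer(rowSums(x^2), rowSums(z^2), `+`) - 2 * x %*% t(z)
    exp(-pmax(d2, 0) / (2 * spec$bandwidth^2))
  }
}

#' Upper nearest-rank quantile aggregation
#'
#' The bag-level aggregate behind the quantile relaxation of the MIL max
#' assumption: returns the k-th largest of `values` with
#' `k = ceiling((1 - q) * n)` clamped to `[1, n]`. `q = 1` returns the
#' maximum (the classic witness assumption); `q = 0.5` over +/-1 instance
#' labels is positive exactly when at least half the instances are positive.
#' No interpolation is performed, so the rule is meaningful on discrete
#' labels.
#'
#' @param values Nonempty numeric vector.
#' @param q Quantile in (0, 1].
#' @return The aggregated value.
#' @export
quantile_agg <- function(values, q) {
  n <- length(values)
  if (n == 0L) stopf("quantile_agg on empty value set")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 1)
    stopf("q must lie in (0, 1]")
  k <- min(max(ceiling((1 - q) * n), 1L), n)
  unname(sort(values, decreasing = TRUE)[k])
}

# Number of instances that must be positive for a bag of size n to satisfy
# the quantile constraint quantile_agg(labels, q) == +1.
quantile_k <- function(n, q) min(max(ceiling((1 - q) * n), 1L), n)

#' Hyper-parameters of a MIL classifier
#'
#' @param kernel A [kernel_spec()].
#' @param C Regularization parameter (> 0); the study grid is
#'   0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1.
#' @param q Quantile in (0, 1]; the study grid is 0.25, 0.5, 0.75, 0.9, 1.
#' @return An object of class `mil_params`.
#' @export
mil_params <- function(kernel = kernel_spec(), C = 1, q = 1) {
  stopifnot(inherits(kernel, "kernel_spec"), C > 0, q > 0, q <= 1)
  structure(list(kernel = kernel, C = as.numeric(C), q = as.numeric(q)),
            class = "mil_params")
}

#' The full study parameter grid
#'
#' Polynomial degrees 1 and 2, RBF bandwidths 8-20, C from 0.001 to 1, q
#' from 0.25 to 1; subsets can be requested for desk-scale runs.
#'
#' @param kernels List of [kernel_spec()] objects.
#' @param C Numeric vector of regularization values.
#' @param q Numeric vector of quantiles.
#' @return List of [mil_params()] combinations.
#' @export
mil_param_grid <- function(kernels = c(lapply(c(1L, 2L), function(p)
                             kernel_spec("polynomial", degree = p)),
                           lapply(c(8, 10, 12, 14, 16, 20), function(b)
                             kernel_spec("rbf", bandwidth = b))),
                           C = c(0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1),
                           q = c(0.25, 0.5, 0.75, 0.9, 1)) {
  grid <- list()
  for (k in kernels) for (cc in C) for (qq in q)
    grid[[length(grid) + 1L]] <- mil_params(k, cc, qq)
  grid
}

# Feature standardization on training data; applied before any kernel.
fit_standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(x, std) {
  sweep(sweep(x, 2L, std$center, `-`), 2L, std$scale, `/`)
}

# Platt-style sigmoid calibration of decision values to posteriors.
# Targets are prior-smoothed as in Platt (1999); fitted by IRLS via glm.
fit_platt <- function(decision, y) {
  y <- as.numeric(y)
  np <- sum(y > 0); nn <- sum(y < 0)
  t <- ifelse(y > 0, (np + 1) / (np + 2), 1 / (nn + 2))
  fit <- suppressWarnings(
    stats::glm(t ~ decision, family = stats::quasibinomial()))
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (!is.finite(a) || a <= 0) {  # enforce monotone nondecreasing map
    a <- max(a, 1e-3, na.rm = TRUE); if (!is.finite(b)) b <- 0
  }
  list(slope = a, intercept = b)
}

apply_platt <- function(platt, decision) {
  stats::plogis(platt$intercept + platt$slope * decision)
}
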