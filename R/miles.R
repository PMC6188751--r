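#' Quantile bag-to-prototype similarity embedding
#'
#' Represents a bag by its similarity to each prototype instance:
#' `s[m] = quantile_agg({k(x_ij, x_m)}_j, q)`. At `q = 1` this is the
#' classic MILES max-similarity embedding; smaller `q` demands that several
#' instances resemble a prototype before the bag counts as similar to it.
#'
#' @param bag A [mil_bag()] (features already on the standardized scale used
#'   for the prototypes).
#' @param prototypes Numeric matrix of prototype instances (rows).
#' @param spec A [kernel_spec()].
#' @param q Quantile in (0, 1].
#' @return Numeric similarity vector, one entry per prototype.
#' @export
miles_embed <- function(bag, prototypes, spec = kernel_spec(), q = 1) {
  feats <- if (inherits(bag, "mil_bag")) bag$features else as.matrix(bag)
  if (nrow(feats) == 0L) stopf("empty bag")
  K <- mil_kernel(feats, prototypes, spec)   # n_i x M
  apply(K, 2L, quantile_agg, q = q)
}

#' Fit a quantile-relaxed MILES classifier (MILES-Q)
#'
#' Embeds every training bag by its quantile similarity to all training
#' instances (the candidate prototypes) and fits an L1-regularized linear
#' classifier on the embedded space, realized as sparse (lasso) logistic
#' regression; prototypes with nonzero weight are retained. The lasso
#' penalty plays the role of the 1-norm SVM in the original MILES
#' formulation: `C` is mapped to the penalty as `lambda = 1 / (n_bags * C)`,
#' so larger `C` means weaker regularization and more retained prototypes.
#' Bag decision values are calibrated to posteriors with a Platt-style
#' sigmoid.
#'
#' @param bags List of labeled [mil_bag()] objects (both classes present).
#' @param params A [mil_params()].
#' @return An object of class `c("miles_q", "mil_model")` with the retained
#'   `prototypes`, their `weights`, the `intercept`, `params`,
#'   `standardization` and `posterior_map`.
#' @seealso [predict.miles_q()], [misvm_q()]
#' @export
miles_q <- function(bags, params = mil_params()) {
  y <- bag_labels(bags)
  if (any(is.na(y))) stopf("all training bags must be labeled")
  if (length(unique(y)) < 2L) stopf("training bags must contain both classes")
  x <- bag_matrix(bags)
  std <- fit_standardizer(x)
  protos <- apply_standardizer(x, std)

  emb <- t(vapply(bags, function(b) {
    bs <- apply_standardizer(b$features, std)
    miles_embed(bs, protos, params$kernel, params$q)
  }, numeric(nrow(protos))))

  lambda <- 1 / (length(bags) * params$C)
  y01 <- as.numeric(y > 0)
  # fit along a short decreasing path ending at the target penalty; glmnet
  # warm-starts are more reliable than a single-lambda fit
  lams <- lambda * c(16, 8, 4, 2, 1)
  fit <- suppressWarnings(
    glmnet::glmnet(emb, y01, family = "binomial", alpha = 1,
                   standardize = FALSE, lambda = lams))
  w <- as.numeric(fit$beta[, ncol(fit$beta)])
  b0 <- as.numeric(fit$a0[length(fit$a0)])
  keep <- which(w != 0)

  dec <- b0 + as.numeric(emb %*% w)
  platt <- fit_platt(dec, y)

  structure(list(prototypes = protos[keep, , drop = FALSE],
                 weights = w[keep], intercept = b0,
                 prototype_index = keep,
                 params = params, standardization = std,
                 posterior_map = platt, n_bags = length(bags),
                 dim = ncol(x)),
            class = c("miles_q", "mil_model"))
}

miles_bag_decision <- function(object, feats_std) {
  if (length(object$weights) == 0L) return(object$intercept)
  s <- miles_embed(feats_std, object$prototypes, object$params$kernel,
                   object$params$q)
  object$intercept + sum(object$weights * s)
}

#' Predict from a fitted MILES-Q model
#'
#' Bag posteriors apply the sparse linear classifier to the bag's quantile
#' similarity embedding against the retained prototypes. Instance
#' posteriors credit each instance with the weighted similarity of the
#' prototypes for which it belongs to the top-k set attaining the bag-level
#' aggregate (ties included): instance j scores
#' `intercept + sum over such prototypes m of weight_m * k(x_ij, x_m)`,
#' mapped through the posterior calibration. In a bag of identical
#' instances every instance attains every aggregate, so instance and bag
#' posteriors coincide.
#'
#' @param object A fitted [miles_q()] model.
#' @param bags A single [mil_bag()] or a list of them.
#' @param type "bag" or "instance".
#' @param ... Unused.
#' @return As in [predict.misvm_q()].
#' @export
predict.miles_q <- function(object, bags, type = c("bag", "instance"), ...) {
  type <- match.arg(type)
  single <- inherits(bags, "mil_bag")
  if (single) bags <- list(bags)
  res <- lapply(bags, function(b) {
    if (nrow(b$features) == 0L) stopf("empty bag")
    if (ncol(b$features) != object$dim)
      stopf("bag instance dimension %d does not match model dimension %d",
            ncol(b$features), object$dim)
    bs <- apply_standardizer(b$features, object$standardization)
    if (type == "bag") {
      apply_platt(object$posterior_map, miles_bag_decision(object, bs))
    } else {
      miles_instance_posteriors(object, bs)
    }
  })
  if (type == "bag") return(vapply(res, identity, numeric(1)))
  if (single) res[[1]] else res
}

miles_instance_posteriors <- function(object, feats_std, tol = 1e-9) {
  n <- nrow(feats_std)
  if (length(object$weights) == 0L)
    return(rep(apply_platt(object$posterior_map, object$intercept), n))
  K <- mil_kernel(feats_std, object$prototypes, object$params$kernel) # n x M
  agg <- apply(K, 2L, quantile_agg, q = object$params$q)
  member <- sweep(K, 2L, agg - tol, `>=`)   # j attains prototype m's aggregate
  dec <- object$intercept + as.numeric((member * K) %*% object$weights)
  apply_platt(object$posterior_map, dec)
}

#' @export
print.miles_q <- function(x, ...) {
  k <- x$params$kernel
  cat("MILES-Q multiple-instance classifier\n")
  cat(sprintf("  kernel: %s (%s), C = %g, q = %g\n", k$family,
              if (k$family == "rbf") paste0("bandwidth ", k$bandwidth)
              else paste0("degree ", k$degree),
              x$params$C, x$params$q))
  cat(sprintf("  trained on %d bags; %d prototype(s) retained\n",
              x$n_bags, length(x$weights)))
  invisible(x)
}

#' @export
summary.miles_q <- function(object, ...) {
  print(object)
  if (length(object$weights)) {
    cat(sprintf("  prototype weights: %d positive, %d negative\n",
                sum(object$weights > 0), sum(object$weights < 0)))
  }
  invisible(object)
}
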