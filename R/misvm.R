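#' Fit a quantile-relaxed instance-level MIL SVM (miSVM-Q)
#'
#' Trains an instance-level support vector machine from weakly labeled bags
#' by iterative label imputation. All instances start with their bag's
#' label; at each iteration a kernel SVM is trained on the imputed labels
#' and the labels are re-imputed: instances of negative bags stay negative,
#' while in each positive bag instances take the classifier's sign subject
#' to the quantile constraint - at least `k = ceiling((1 - q) * n_i)`
#' (clamped to at least one) of the highest-scoring instances are forced
#' positive, so that the upper nearest-rank q-quantile of the bag's imputed
#' labels equals the bag label. At `q = 1` this is the classic miSVM witness
#' scheme (at least the single most positive instance per positive bag);
#' at `q = 0.5` at least half of each positive bag must be positive.
#' Iteration stops when the imputed labels are unchanged or `max_iter` is
#' reached. Decision values are calibrated to posteriors with a Platt-style
#' sigmoid fitted on the final imputed labels.
#'
#' Features are z-scored with training statistics before kernel evaluation;
#' the RBF bandwidth grid is interpreted on that standardized scale.
#'
#' @param bags List of labeled [mil_bag()] objects (both classes present).
#' @param params A [mil_params()] (kernel, C, q).
#' @param max_iter Maximum imputation iterations (default 20).
#' @param class_weights Optional named weights passed to the SVM to
#'   counter class imbalance (default NULL: unweighted).
#' @return An object of class `c("misvm_q", "mil_model")` with elements
#'   `svm` (the fitted instance SVM), `params`, `standardization`,
#'   `posterior_map`, `converged`, `n_iterations`, and the final
#'   `imputed_labels`.
#' @seealso [predict.misvm_q()], [miles_q()]
#' @export
misvm_q <- function(bags, params = mil_params(), max_iter = 20L,
                    class_weights = NULL) {
  y <- bag_labels(bags)
  if (any(is.na(y))) stopf("all training bags must be labeled")
  if (length(unique(y)) < 2L) stopf("training bags must contain both classes")

  x <- bag_matrix(bags)
  idx <- bag_index(bags)
  std <- fit_standardizer(x)
  xs <- apply_standardizer(x, std)

  q <- params$q
  lab <- y[idx]                       # init: bag label for every instance
  converged <- FALSE
  iter <- 0L
  svm_fit <- NULL
  dec <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    svm_fit <- svm_train(xs, lab, params, class_weights)
    dec <- svm_decision(svm_fit, xs)
    new_lab <- lab
    for (b in which(y > 0)) {
      sel <- which(idx == b)
      db <- dec[sel]
      imput <- ifelse(db > 0, 1, -1)
      k <- quantile_k(length(sel), q)
      # force the top-k instances positive (stable order: index tie-break)
      top <- sel[order(-db, seq_along(db))[seq_len(k)]]
      imput[match(top, sel)] <- 1
      new_lab[sel] <- imput
    }
    if (all(new_lab == lab)) { converged <- TRUE; break }
    lab <- new_lab
  }

  platt <- fit_platt(dec, lab)
  structure(list(svm = svm_fit, params = params, standardization = std,
                 posterior_map = platt, converged = converged,
                 n_iterations = iter, imputed_labels = lab,
                 n_bags = length(bags), dim = ncol(x)),
            class = c("misvm_q", "mil_model"))
}

# e1071 backend; labels +/-1. Returns fit with a decision-value orientation
# already resolved (positive decision = positive class).
svm_train <- function(xs, lab, params, class_weights = NULL) {
  yf <- factor(lab, levels = c(1, -1))
  k <- params$kernel
  args <- list(x = xs, y = yf, scale = FALSE, cost = params$C,
               fitted = FALSE)
  if (!is.null(class_weights)) args$class.weights <- class_weights
  if (k$family == "polynomial") {
    args <- c(args, list(kernel = "polynomial", degree = k$degree,
                         gamma = 1, coef0 = 1))
  } else {
    args <- c(args, list(kernel = "radial", gamma = 1 / (2 * k$bandwidth^2)))
  }
  fit <- do.call(e1071::svm, args)
  # e1071 signs decision values for the first factor level it encountered;
  # record the orientation so higher decision always means positive.
  fit$lungmil_flip <- !identical(colnames(attr(
    stats::predict(fit, xs[1, , drop = FALSE], decision.values = TRUE),
    "decision.values")), "1/-1")
  fit
}

svm_decision <- function(fit, xs) {
  pr <- stats::predict(fit, xs, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  if (isTRUE(fit$lungmil_flip)) dv <- -dv
  dv
}

#' Predict from a fitted miSVM-Q model
#'
#' Instance posteriors are the Platt-calibrated SVM decision values; the bag
#' posterior is the upper nearest-rank q-quantile of its instance posteriors
#' and the bag label is positive when that posterior exceeds 0.5.
#'
#' @param object A fitted [misvm_q()] model.
#' @param bags A single [mil_bag()] or a list of them.
#' @param type "bag" for bag posteriors, "instance" for per-instance
#'   posteriors.
#' @param q Aggregation quantile; defaults to the training value.
#' @param ... Unused.
#' @return For `type = "bag"`, a numeric vector of bag posteriors; for
#'   `type = "instance"`, a list of per-instance posterior vectors.
#' @export
predict.misvm_q <- function(object, bags, type = c("bag", "instance"),
                            q = object$params$q, ...) {
  type <- match.arg(type)
  single <- inherits(bags, "mil_bag")
  if (single) bags <- list(bags)
  post <- lapply(bags, function(b) {
    if (ncol(b$features) != object$dim)
      stopf("bag instance dimension %d does not match model dimension %d",
            ncol(b$features), object$dim)
    xs <- apply_standardizer(b$features, object$standardization)
    apply_platt(object$posterior_map, svm_decision(object$svm, xs))
  })
  if (type == "instance") return(if (single) post[[1]] else post)
  vapply(post, quantile_agg, numeric(1), q = q)
}

#' @export
print.misvm_q <- function(x, ...) {
  k <- x$params$kernel
  cat("miSVM-Q multiple-instance classifier\n")
  cat(sprintf("  kernel: %s (%s), C = %g, q = %g\n", k$family,
              if (k$family == "rbf") paste0("bandwidth ", k$bandwidth)
              else paste0("degree ", k$degree),
              x$params$C, x$params$q))
  cat(sprintf("  trained on %d bags, %d support vectors, %s after %d iteration(s)\n",
              x$n_bags, nrow(x$svm$SV),
              if (x$converged) "converged" else "not converged",
              x$n_iterations))
  invisible(x)
}

#' @export
summary.misvm_q <- function(object, ...) {
  print(object)
  cat(sprintf("  imputed instance labels: %d positive / %d negative\n",
              sum(object$imputed_labels > 0), sum(object$imputed_labels < 0)))
  invisible(object)
}
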