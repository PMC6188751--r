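# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (direct enumeration, classic max-based
# algorithms) so agreement is evidence, not tautology.

# Brute-force GLCM by explicit voxel-pair enumeration.
brute_glcm <- function(quantized, direction, distance, n_levels,
                       symmetric = TRUE) {
  d <- dim(quantized)
  off <- direction * distance
  counts <- matrix(0, n_levels, n_levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    t <- c(x, y, z) + off
    if (all(t >= 1) && all(t <= d)) {
      a <- quantized[x, y, z] + 1L
      b <- quantized[t[1], t[2], t[3]] + 1L
      counts[a, b] <- counts[a, b] + 1
      if (symmetric) counts[b, a] <- counts[b, a] + 1
    }
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

# Classic max-assumption miSVM (Andrews-style), written independently of
# misvm_q(): all positive-bag instances start positive, relabel by classifier
# sign, force the top instance positive when a positive bag loses all
# positives.
reference_misvm_max <- function(bags, params, max_iter = 20L) {
  y <- vapply(bags, function(b) b$label, numeric(1))
  x <- do.call(rbind, lapply(bags, `[[`, "features"))
  idx <- rep(seq_along(bags), vapply(bags, function(b) nrow(b$features),
                                     integer(1)))
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, ctr, `-`), 2, scl, `/`)
  lab <- y[idx]
  fit <- NULL
  for (it in seq_len(max_iter)) {
    k <- params$kernel
    if (k$family == "polynomial") {
      fit <- e1071::svm(xs, factor(lab, levels = c(1, -1)), scale = FALSE,
                        kernel = "polynomial", degree = k$degree, gamma = 1,
                        coef0 = 1, cost = params$C)
    } else {
      fit <- e1071::svm(xs, factor(lab, levels = c(1, -1)), scale = FALSE,
                        kernel = "radial", gamma = 1 / (2 * k$bandwidth^2),
                        cost = params$C)
    }
    pr <- stats::predict(fit, xs, decision.values = TRUE)
    dec <- as.numeric(attr(pr, "decision.values"))
    if (!identical(colnames(attr(pr, "decision.values")), "1/-1")) dec <- -dec
    new_lab <- lab
    for (b in which(y > 0)) {
      sel <- which(idx == b)
      lb <- ifelse(dec[sel] > 0, 1, -1)
      if (all(lb < 0)) lb[which.max(dec[sel])] <- 1
      new_lab[sel] <- lb
    }
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  list(fit = fit, center = ctr, scale = scl,
       decision = function(newx) {
         nxs <- sweep(sweep(newx, 2, ctr, `-`), 2, scl, `/`)
         pr <- stats::predict(fit, nxs, decision.values = TRUE)
         dv <- as.numeric(attr(pr, "decision.values"))
         if (!identical(colnames(attr(pr, "decision.values")), "1/-1")) dv <- -dv
         dv
       })
}

# Max-based reference miSVM bag decision: max instance decision value.
reference_misvm_bag_sign <- function(ref, bags) {
  vapply(bags, function(b) sign(max(ref$decision(b$features))), numeric(1))
}

# Classic MILES: max-similarity embedding + lasso-logistic, independent of
# miles_q() internals.
reference_miles_max <- function(bags, params) {
  y <- vapply(bags, function(b) b$label, numeric(1))
  x <- do.call(rbind, lapply(bags, `[[`, "features"))
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  zs <- function(m) sweep(sweep(m, 2, ctr, `-`), 2, scl, `/`)
  protos <- zs(x)
  embed1 <- function(b) {
    K <- mil_kernel(zs(b$features), protos, params$kernel)
    apply(K, 2, max)
  }
  emb <- t(vapply(bags, embed1, numeric(nrow(protos))))
  lambda <- 1 / (length(bags) * params$C)
  fit <- suppressWarnings(glmnet::glmnet(
    emb, as.numeric(y > 0), family = "binomial", alpha = 1,
    standardize = FALSE, lambda = lambda * c(16, 8, 4, 2, 1)))
  w <- as.numeric(fit$beta[, ncol(fit$beta)])
  b0 <- as.numeric(fit$a0[length(fit$a0)])
  list(decision = function(bag) b0 + sum(w * embed1(bag)))
}

# Exhaustive miSVM oracle at q = 1: over all feasible instance-label
# assignments (negative bags all -1, each positive bag at least one +1),
# train a supervised SVM and keep the assignment with the lowest primal
# objective; report its training-bag predictions under the max rule.
brute_misvm_q1 <- function(bags, params) {
  y <- vapply(bags, function(b) b$label, numeric(1))
  x <- do.call(rbind, lapply(bags, `[[`, "features"))
  idx <- rep(seq_along(bags), vapply(bags, function(b) nrow(b$features),
                                     integer(1)))
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, ctr, `-`), 2, scl, `/`)
  pos_sets <- lapply(which(y > 0), function(b) which(idx == b))
  choices <- lapply(pos_sets, function(sel) {
    combs <- expand.grid(rep(list(c(-1, 1)), length(sel)))
    combs[rowSums(combs > 0) >= 1, , drop = FALSE]
  })
  best_obj <- Inf; best_sign <- NULL
  grid_idx <- lapply(choices, function(ch) seq_len(nrow(ch)))
  for (combo in split(as.matrix(do.call(expand.grid, grid_idx)),
                      seq_len(prod(vapply(grid_idx, length, integer(1)))))) {
    lab <- y[idx]
    for (p in seq_along(pos_sets))
      lab[pos_sets[[p]]] <- as.numeric(choices[[p]][combo[p], ])
    fit <- e1071::svm(xs, factor(lab, levels = c(1, -1)), scale = FALSE,
                      kernel = "polynomial", degree = params$kernel$degree,
                      gamma = 1, coef0 = 1, cost = params$C)
    pr <- stats::predict(fit, xs, decision.values = TRUE)
    dec <- as.numeric(attr(pr, "decision.values"))
    if (!identical(colnames(attr(pr, "decision.values")), "1/-1")) dec <- -dec
    # primal objective: 0.5 ||w||^2 + C * sum hinge
    sv_coef <- fit$coefs
    Ksv <- (fit$SV %*% t(fit$SV) + 1)^params$kernel$degree
    wnorm2 <- as.numeric(t(sv_coef) %*% Ksv %*% sv_coef)
    hinge <- sum(pmax(0, 1 - lab * dec))
    obj <- 0.5 * wnorm2 + params$C * hinge
    if (obj < best_obj - 1e-9) {
      best_obj <- obj
      best_sign <- vapply(seq_along(bags), function(b)
        sign(max(dec[idx == b])), numeric(1))
    }
  }
  best_sign
}
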