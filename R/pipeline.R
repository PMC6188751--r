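#' Randomly sample patch centers inside the lung
#'
#' Draws `n_patches` centers uniformly (with replacement) among voxels that
#' lie inside the lung mask and whose full patch fits inside the volume;
#' patches may overlap. Deterministic given the seed.
#'
#' @param subject A `synthetic_subject`, or any list with `volume` and
#'   `lung_mask`.
#' @param n_patches Number of patches (default 50).
#' @param patch_size Cubic patch edge in voxels (default 41, odd).
#' @param seed RNG seed.
#' @return Integer matrix `n_patches` by 3 of center voxel coordinates.
#' @export
sample_patches <- function(subject, n_patches = 50L, patch_size = 41L,
                           seed = 1L) {
  stopifnot(n_patches >= 1L, patch_size %% 2L == 1L)
  shape <- dim(subject$volume)
  h <- (patch_size - 1L) %/% 2L
  valid <- array(FALSE, shape)
  lo <- rep(h + 1L, 3L); hi <- shape - h
  if (any(hi < lo)) stopf("volume too small for %d^3 patches", patch_size)
  valid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  valid <- valid & (subject$lung_mask != 0)
  centers <- which(valid)
  if (length(centers) == 0L)
    stopf("no valid patch center inside the lung mask")
  with_seed(seed, {
    picks <- centers[sample.int(length(centers), n_patches, replace = TRUE)]
  })
  ctr <- arrayInd(picks, shape)
  colnames(ctr) <- c("x", "y", "z")
  ctr
}

# Extract the cubic patch (and matching mask patch) around a center.
extract_patch <- function(volume, mask, center, patch_size = 41L) {
  h <- (patch_size - 1L) %/% 2L
  ix <- (center[1] - h):(center[1] + h)
  iy <- (center[2] - h):(center[2] + h)
  iz <- (center[3] - h):(center[3] + h)
  list(volume = volume[ix, iy, iz], mask = mask[ix, iy, iz])
}

#' Fit adaptive bins from reference subjects
#'
#' Pools filter responses of patches sampled from a held-out reference
#' cohort and fits the 10-bin adaptive histogram edges used by
#' [gauss_features()]. Keeping the reference cohort disjoint from the study
#' cohort preserves train/test separation.
#'
#' @param subjects Reference `synthetic_subject`s (or compatible lists).
#' @param config A [gauss_config()].
#' @param n_patches Patches sampled per reference subject.
#' @param patch_size Patch edge in voxels.
#' @param seed Seed for patch sampling.
#' @return A `binning_model`.
#' @export
fit_reference_binning <- function(subjects, config = gauss_config(),
                                  n_patches = 10L, patch_size = 41L,
                                  seed = 99L) {
  chans <- gauss_channel_names(config)
  pool <- stats::setNames(vector("list", length(chans)), chans)
  for (si in seq_along(subjects)) {
    s <- subjects[[si]]
    sp <- if (!is.null(s$spec)) s$spec$spacing_mm else c(1, 1, 1)
    ctrs <- sample_patches(s, n_patches, patch_size,
                           seed = derive_seed(seed, si))
    for (pi in seq_len(nrow(ctrs))) {
      p <- extract_patch(s$volume, s$lung_mask, ctrs[pi, ], patch_size)
      for (sig in config$scales_mm) {
        bank <- filter_bank(p$volume, p$mask, sig, sp)
        for (f in config$filters) {
          ch <- sprintf("s%g_%s", sig, f)
          v <- bank[[f]][p$mask != 0]
          pool[[ch]] <- c(pool[[ch]], v[is.finite(v)])
        }
      }
    }
  }
  fit_adaptive_bins(pool, config$n_bins)
}

#' Build labeled bags from a cohort
#'
#' Samples patches per subject, computes the requested texture features and
#' assembles one [mil_bag()] per subject with the weak label of the chosen
#' channel. Switching the label channel changes only the bag labels, never
#' the features or the sampled patches.
#'
#' @param subjects List of `synthetic_subject`s.
#' @param features "gauss", "cooc" or "both".
#' @param label_channel "copd" (GOLD A-D positive) or "dlco" (DLCO < 60%
#'   predicted positive).
#' @param binning `binning_model` for the Gaussian features (required
#'   unless `features = "cooc"`).
#' @param gauss A [gauss_config()]; `cooc` a [glcm_config()].
#' @param n_patches,patch_size,seed Patch sampling parameters.
#' @return List of [mil_bag()]s.
#' @export
extract_bags <- function(subjects, features = c("gauss", "cooc", "both"),
                         label_channel = c("copd", "dlco"),
                         binning = NULL, gauss = gauss_config(),
                         cooc = glcm_config(), n_patches = 50L,
                         patch_size = 41L, seed = 1L) {
  features <- match.arg(features)
  label_channel <- match.arg(label_channel)
  if (features %in% c("gauss", "both") && is.null(binning))
    stopf("Gaussian features require a fitted binning model")
  lapply(seq_along(subjects), function(si) {
    s <- subjects[[si]]
    sp <- if (!is.null(s$spec)) s$spec$spacing_mm else c(1, 1, 1)
    ctrs <- sample_patches(s, n_patches, patch_size,
                           seed = derive_seed(seed, si))
    feats <- t(vapply(seq_len(nrow(ctrs)), function(pi) {
      p <- extract_patch(s$volume, s$lung_mask, ctrs[pi, ], patch_size)
      v <- numeric(0)
      if (features %in% c("cooc", "both"))
        v <- c(v, cooc_features(p$volume, cooc))
      if (features %in% c("gauss", "both"))
        v <- c(v, gauss_features(p$volume, p$mask, gauss, binning, sp))
      v
    }, FUN.VALUE = numeric(feature_length(features, gauss, cooc))))
    label <- if (label_channel == "copd") s$label_copd else s$label_dlco
    mil_bag(feats, label = label, subject_id = s$subject_id,
            centers = ctrs, label_channel = label_channel)
  })
}

feature_length <- function(features, gauss, cooc) {
  ng <- length(gauss$scales_mm) * length(gauss$filters) * gauss$n_bins
  nc <- 13L * length(cooc$distances) * 12L
  switch(features, gauss = ng, cooc = nc, both = nc + ng)
}

# Stratified subject-level fold assignment; every fold gets both classes
# when counts allow.
stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      i <- sample(which(labels == cl))
      fold[i] <- rep_len(sample(n_folds), length(i))
    }
    fold
  })
}

#' Nested stratified cross-validation of a MIL classifier
#'
#' Outer stratified k-fold cross-validation at the subject level (a
#' subject's patches never span folds). Within each outer training set, an
#' inner stratified cross-validation scores every candidate parameter
#' combination by mean bag AUC (ties broken by larger mean Separability on
#' the inner validation bags); the winning parameters are refit on the full
#' outer training set and evaluated on the held-out fold.
#'
#' @param bags List of labeled [mil_bag()]s.
#' @param classifier "misvm" or "miles".
#' @param grid List of [mil_params()] candidates (see [mil_param_grid()]).
#' @param outer_folds,inner_folds Fold counts (defaults 4 and 3).
#' @param seed Seed controlling fold assignment.
#' @return Object of class `lungmil_cv`: per-fold AUC, Separability (on the
#'   held-out bags), chosen parameters, and aggregate mean/sd.
#' @export
nested_cv <- function(bags, classifier = c("misvm", "miles"),
                      grid = mil_param_grid(), outer_folds = 4L,
                      inner_folds = 3L, seed = 1L) {
  classifier <- match.arg(classifier)
  y <- bag_labels(bags)
  if (any(is.na(y))) stopf("all bags must be labeled")
  fold <- stratified_folds(y, outer_folds, seed)
  if (any(tabulate(fold, outer_folds) == 0L) ||
      any(vapply(seq_len(outer_folds), function(f)
        length(unique(y[fold == f])) < 2L, logical(1))))
    stopf("every outer fold must contain both classes; use fewer folds or more subjects")

  fit_one <- function(train_bags, params) {
    if (classifier == "misvm") misvm_q(train_bags, params)
    else miles_q(train_bags, params)
  }
  eval_one <- function(model, test_bags) {
    post <- predict(model, test_bags, type = "bag")
    inst <- predict(model, test_bags, type = "instance")
    yt <- bag_labels(test_bags)
    list(auc = bag_auc(post, yt),
         sep = separability(inst[yt > 0], inst[yt < 0]))
  }

  res <- lapply(seq_len(outer_folds), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    # inner selection
    scores <- vapply(grid, function(par) {
      ifold <- stratified_folds(y[tr], inner_folds, derive_seed(seed, f))
      vals <- vapply(seq_len(inner_folds), function(g) {
        itr <- tr[ifold != g]; ite <- tr[ifold == g]
        if (length(unique(y[itr])) < 2L || length(unique(y[ite])) < 2L)
          return(c(NA_real_, NA_real_))
        m <- fit_one(bags[itr], par)
        ev <- eval_one(m, bags[ite])
        c(ev$auc, ev$sep)
      }, numeric(2))
      rowMeans(vals, na.rm = TRUE)
    }, numeric(2))
    best <- order(-scores[1, ], -scores[2, ])[1]
    model <- fit_one(bags[tr], grid[[best]])
    ev <- eval_one(model, bags[te])
    list(fold = f, auc = ev$auc, separability = ev$sep,
         params = grid[[best]], model = model, test_idx = te)
  })
  auc <- vapply(res, `[[`, numeric(1), "auc")
  sep <- vapply(res, `[[`, numeric(1), "separability")
  structure(list(folds = res, auc = auc, separability = sep,
                 mean_auc = mean(auc), sd_auc = stats::sd(auc),
                 mean_separability = mean(sep),
                 sd_separability = stats::sd(sep),
                 classifier = classifier, outer_folds = outer_folds,
                 fold_assignment = fold),
            class = "lungmil_cv")
}

#' @export
print.lungmil_cv <- function(x, ...) {
  cat(sprintf("Nested %d-fold cross-validation of %s\n", x$outer_folds,
              switch(x$classifier, misvm = "miSVM-Q", miles = "MILES-Q")))
  cat(sprintf("  bag AUC x100:       %.1f +/- %.1f  (folds: %s)\n",
              100 * x$mean_auc, 100 * x$sd_auc,
              paste(sprintf("%.2f", x$auc), collapse = ", ")))
  cat(sprintf("  Separability x100:  %.1f +/- %.1f  (folds: %s)\n",
              100 * x$mean_separability, 100 * x$sd_separability,
              paste(sprintf("%.2f", x$separability), collapse = ", ")))
  for (f in x$folds) {
    k <- f$params$kernel
    cat(sprintf("  fold %d params: %s %s, C = %g, q = %g\n", f$fold,
                k$family,
                if (k$family == "rbf") paste0("bw ", k$bandwidth)
                else paste0("deg ", k$degree), f$params$C, f$params$q))
  }
  invisible(x)
}

#' Posterior slice map of a subject
#'
#' Applies a fitted instance-capable MIL model on a regular grid of voxels:
#' `n_slices` axial slices spaced `slice_spacing` apart (excluding the top
#' and bottom 10% of lung-bearing slices), and within each slice every
#' `voxel_stride`-th voxel in both in-plane directions, restricted to the
#' lung mask. Each grid point is scored by the instance posterior of the
#' patch centered on it; patches are clipped to the volume and used only if
#' at least half of their voxels are in-mask.
#'
#' @param model A fitted `mil_model` (miSVM-Q or MILES-Q).
#' @param subject A `synthetic_subject` (or compatible list).
#' @param binning `binning_model` used at training time.
#' @param features,gauss,cooc As in [extract_bags()]; must match training.
#' @param n_slices Number of slices (default 10).
#' @param slice_spacing Spacing between slices in voxels (default 25; use a
#'   smaller value on short phantoms).
#' @param voxel_stride In-plane stride (default 10).
#' @param patch_size Patch edge (default 41).
#' @param posterior_threshold Posterior above which a point is called
#'   emphysema (default 0.5, strict).
#' @return Object of class `posterior_slice_map`: data.frame `points`
#'   (slice, x, y, posterior, emphysema, in_lesion when available) and
#'   `pct_emphysema`.
#' @export
slice_posterior_map <- function(model, subject, binning = NULL,
                                features = c("gauss", "cooc", "both"),
                                gauss = gauss_config(), cooc = glcm_config(),
                                n_slices = 10L, slice_spacing = 25L,
                                voxel_stride = 10L, patch_size = 41L,
                                posterior_threshold = 0.5) {
  features <- match.arg(features)
  stopifnot(n_slices >= 1L, voxel_stride >= 1L, slice_spacing >= 1L)
  shape <- dim(subject$volume)
  sp <- if (!is.null(subject$spec)) subject$spec$spacing_mm else c(1, 1, 1)
  lung_per_slice <- apply(subject$lung_mask, 3L, sum)
  zs <- which(lung_per_slice > 0)
  if (length(zs) == 0L) stopf("no lung-bearing slices")
  drop <- floor(0.1 * length(zs))
  zs <- zs[(drop + 1L):(length(zs) - drop)]
  slices <- seq(zs[1], zs[length(zs)], by = slice_spacing)
  slices <- utils::head(slices, n_slices)
  if (length(slices) == 0L) stopf("no eligible slices")

  h <- (patch_size - 1L) %/% 2L
  pts <- list()
  for (z in slices) {
    xg <- seq(1L, shape[1], by = voxel_stride)
    yg <- seq(1L, shape[2], by = voxel_stride)
    for (x in xg) for (y in yg) {
      if (subject$lung_mask[x, y, z] == 0) next
      lo <- c(x, y, z) - h; hi <- c(x, y, z) + h
      clo <- pmax(lo, 1L); chi <- pmin(hi, shape)
      pv <- subject$volume[clo[1]:chi[1], clo[2]:chi[2], clo[3]:chi[3]]
      pm <- subject$lung_mask[clo[1]:chi[1], clo[2]:chi[2], clo[3]:chi[3]]
      if (sum(pm != 0) < 0.5 * length(pm)) next
      pts[[length(pts) + 1L]] <- list(x = x, y = y, z = z, pv = pv, pm = pm)
    }
  }
  if (length(pts) == 0L) stopf("no eligible grid points")

  post <- vapply(pts, function(p) {
    v <- numeric(0)
    if (features %in% c("cooc", "both")) v <- c(v, cooc_features(p$pv, cooc))
    if (features %in% c("gauss", "both"))
      v <- c(v, gauss_features(p$pv, p$pm, gauss, binning, sp))
    bag <- mil_bag(matrix(v, nrow = 1L))
    predict(model, bag, type = "instance")[1]
  }, numeric(1))

  df <- data.frame(slice = vapply(pts, `[[`, numeric(1), "z"),
                   x = vapply(pts, `[[`, numeric(1), "x"),
                   y = vapply(pts, `[[`, numeric(1), "y"),
                   posterior = post)
  df$emphysema <- df$posterior > posterior_threshold
  if (!is.null(subject$lesion_mask))
    df$in_lesion <- subject$lesion_mask[cbind(df$x, df$y, df$slice)] != 0
  structure(list(points = df,
                 pct_emphysema = 100 * mean(df$emphysema),
                 slices = slices, threshold = posterior_threshold),
            class = "posterior_slice_map")
}

#' @export
print.posterior_slice_map <- function(x, ...) {
  cat(sprintf("posterior slice map: %d grid points on %d slice(s); %.1f%% emphysema (posterior > %.2f)\n",
              nrow(x$points), length(x$slices), x$pct_emphysema, x$threshold))
  invisible(x)
}

#' Percentage of emphysema in a posterior slice map
#'
#' Grid points with posterior strictly above the threshold count as
#' emphysema; the denominator is the number of in-mask grid points. A
#' per-slice breakdown is attached.
#'
#' @param map A `posterior_slice_map`.
#' @return List with `pct` and data.frame `per_slice`.
#' @export
quantify_emphysema <- function(map) {
  stopifnot(inherits(map, "posterior_slice_map"))
  df <- map$points
  per <- stats::aggregate(emphysema ~ slice, df, function(e) 100 * mean(e))
  names(per)[2] <- "pct"
  list(pct = 100 * mean(df$emphysema), per_slice = per)
}
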