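#' Specification of a synthetic CT lung phantom
#'
#' Describes a CT-like lung phantom: an ellipsoidal lung embedded in soft
#' tissue, filled with spatially correlated Gaussian parenchyma texture
#' around `background_hu_mean`, optionally seeded with spherical
#' low-attenuation lesion blobs around `lesion_hu_mean` until the realized
#' lesion burden approaches `burden_target`. Defaults place the parenchyma
#' near -850 HU (healthy lung) and lesions near -975 HU so that the
#' classical -950 HU low-attenuation-area baseline can detect them.
#'
#' @param shape Integer 3-vector, voxels per axis.
#' @param spacing_mm Numeric 3-vector, voxel size in mm.
#' @param background_hu_mean,background_hu_sd Parenchyma HU mean and sd.
#' @param lesion_hu_mean,lesion_hu_sd Lesion HU mean and sd; the lesion mean
#'   must be below the background mean (lesions are low-attenuation).
#' @param lesion_count_range Integer interval: lesions are added until the
#'   burden target is met or the upper count is reached.
#' @param lesion_radius_range_mm Real interval of lesion radii in mm.
#' @param burden_target Fraction of lung volume occupied by lesions, in
#'   [0, 1].
#' @param texture_correlation_length_mm Smoothing scale of the parenchyma
#'   noise field (> 0).
#' @param seed Integer RNG seed; generation is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L),
                         spacing_mm = c(1, 1, 1),
                         background_hu_mean = -850, background_hu_sd = 30,
                         lesion_hu_mean = -975, lesion_hu_sd = 12,
                         lesion_count_range = c(1L, 400L),
                         lesion_radius_range_mm = c(4, 10),
                         burden_target = 0.2,
                         texture_correlation_length_mm = 3,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(lesion_count_range) == 2L,
            length(lesion_radius_range_mm) == 2L,
            texture_correlation_length_mm > 0)
  if (lesion_hu_mean >= background_hu_mean)
    stopf("lesions must be low-attenuation: lesion_hu_mean < background_hu_mean")
  if (burden_target < 0 || burden_target > 1)
    stopf("burden_target must lie in [0, 1]")
  structure(list(shape = as.integer(shape),
                 spacing_mm = as.numeric(spacing_mm),
                 background_hu_mean = background_hu_mean,
                 background_hu_sd = background_hu_sd,
                 lesion_hu_mean = lesion_hu_mean,
                 lesion_hu_sd = lesion_hu_sd,
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
                 burden_target = burden_target,
                 texture_correlation_length_mm = texture_correlation_length_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("CT lung phantom spec: %s voxels at %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(x$spacing_mm, collapse = "x")))
  cat(sprintf("  parenchyma %g +/- %g HU; lesions %g +/- %g HU; burden target %.2f\n",
              x$background_hu_mean, x$background_hu_sd,
              x$lesion_hu_mean, x$lesion_hu_sd, x$burden_target))
  invisible(x)
}

# Ellipsoidal lung mask centered in the volume; semi-axes ~76% of half-extent.
lung_ellipsoid <- function(shape) {
  semi <- 0.38 * shape
  ctr <- (shape + 1) / 2
  gx <- ((seq_len(shape[1]) - ctr[1]) / semi[1])^2
  gy <- ((seq_len(shape[2]) - ctr[2]) / semi[2])^2
  gz <- ((seq_len(shape[3]) - ctr[3]) / semi[3])^2
  r2 <- outer(outer(gx, gy, `+`), gz, `+`)
  r2 <= 1
}

# Correlated unit-variance Gaussian field: smoothed white noise rescaled to
# unit empirical sd.
correlated_field <- function(shape, corr_len_mm, spacing_mm) {
  noise <- array(stats::rnorm(prod(shape)), shape)
  f <- conv_separable(noise, corr_len_mm, spacing_mm)
  (f - mean(f)) / stats::sd(f)
}

#' Generate one synthetic subject
#'
#' Builds the phantom volume and, for a diseased subject, plants spherical
#' lesions at uniformly random in-lung centers until the realized burden
#' reaches the spec's target (or the lesion count cap). The pulmonary
#' function covariates are decreasing noisy linear functions of the
#' realized burden: `dlco_pct = 85 - 180 * burden + N(0, 8)` and
#' analogously for `fev1_pct`, so that at zero burden DLCO is centered well
#' above the 60% weak-label threshold and at burden 0.2 well below it.
#' GOLD class is "none" for healthy subjects and A-D from fixed FEV1 bands
#' (>= 65, 50-65, 35-50, < 35 % predicted) otherwise.
#'
#' @param spec A [phantom_spec()].
#' @param diseased Logical: plant lesions and derive impaired covariates?
#' @return An object of class `synthetic_subject` with elements `volume`,
#'   `lung_mask`, `lesion_mask`, `fev1_pct`, `dlco_pct`, `gold_class`,
#'   `label_copd`, `label_dlco`, `burden`, `spec`.
#' @export
generate_subject <- function(spec = phantom_spec(), diseased = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), is_flag(diseased))
  shape <- spec$shape
  if (any(shape < 48L))
    stopf("shape %s too small to host a 41^3 patch inside the lung",
          paste(shape, collapse = "x"))
  with_seed(spec$seed, {
    lung <- lung_ellipsoid(shape)
    n_lung <- sum(lung)
    field <- correlated_field(shape, spec$texture_correlation_length_mm,
                              spec$spacing_mm)
    vol <- array(40, shape)  # soft tissue outside the lung
    vol[lung] <- spec$background_hu_mean +
      spec$background_hu_sd * field[lung]

    lesion <- array(FALSE, shape)
    if (diseased && spec$burden_target > 0) {
      target_vox <- spec$burden_target * n_lung
      if (spec$burden_target > 1) stopf("infeasible burden target")
      centers <- which(lung)
      radii_vox_max <- max(spec$lesion_radius_range_mm) / min(spec$spacing_mm)
      n_placed <- 0L
      while (sum(lesion) < target_vox &&
             n_placed < spec$lesion_count_range[2]) {
        ctr_idx <- centers[sample.int(length(centers), 1L)]
        ctr <- arrayInd(ctr_idx, shape)[1, ]
        r_mm <- stats::runif(1, spec$lesion_radius_range_mm[1],
                             spec$lesion_radius_range_mm[2])
        lesion <- lesion | sphere_mask(shape, ctr, r_mm, spec$spacing_mm)
        n_placed <- n_placed + 1L
      }
      lesion <- lesion & lung
      vol[lesion] <- spec$lesion_hu_mean + spec$lesion_hu_sd * field[lesion]
    }
    burden <- sum(lesion) / n_lung

    dlco <- max(1, 85 - 180 * burden + stats::rnorm(1, 0, 8))
    fev1 <- max(1, 85 - 180 * burden + stats::rnorm(1, 0, 8))
    gold <- if (!diseased) "none" else
      c("A", "B", "C", "D")[findInterval(-fev1, c(-Inf, -65, -50, -35))]
    structure(list(volume = vol, lung_mask = lung, lesion_mask = lesion,
                   fev1_pct = fev1, dlco_pct = dlco, gold_class = gold,
                   label_copd = if (gold == "none") -1 else 1,
                   label_dlco = if (dlco < 60) 1 else -1,
                   burden = burden, spec = spec),
              class = "synthetic_subject")
  })
}

# Sphere of radius r_mm (in mm) centered at voxel ctr; evaluated only on the
# local bounding box for speed.
sphere_mask <- function(shape, ctr, r_mm, spacing_mm) {
  m <- array(FALSE, shape)
  r_vox <- ceiling(r_mm / spacing_mm)
  lo <- pmax(ctr - r_vox, 1L); hi <- pmin(ctr + r_vox, shape)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx2 <- ((ix - ctr[1]) * spacing_mm[1])^2
  dy2 <- ((iy - ctr[2]) * spacing_mm[2])^2
  dz2 <- ((iz - ctr[3]) * spacing_mm[3])^2
  box <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r_mm^2
  m[ix, iy, iz] <- box
  m
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("synthetic subject: %s voxels; lesion burden %.3f\n",
              paste(dim(x$volume), collapse = "x"), x$burden))
  cat(sprintf("  FEV1 %.1f%%, DLCO %.1f%%, GOLD %s (COPD label %+d, DLCO label %+d)\n",
              x$fev1_pct, x$dlco_pct, x$gold_class, x$label_copd,
              x$label_dlco))
  invisible(x)
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject seeds are derived deterministically from `seed`, so the same
#' call always yields the same cohort. Healthy subjects carry zero burden;
#' diseased subjects use the spec's burden target. GOLD classes of the
#' diseased subjects are re-assigned A-D by cohort FEV1 quartile.
#'
#' @param n_healthy,n_diseased Subject counts (total >= 8 for 4-fold CV).
#' @param spec A [phantom_spec()] (its `seed` field is ignored).
#' @param seed Master seed.
#' @return List of `synthetic_subject`s, healthy first.
#' @export
make_cohort <- function(n_healthy, n_diseased, spec = phantom_spec(),
                        seed = 1L) {
  stopifnot(is_count(n_healthy), is_count(n_diseased))
  if (n_healthy + n_diseased < 8L)
    stopf("need at least 8 subjects for 4-fold cross-validation")
  subjects <- vector("list", n_healthy + n_diseased)
  for (i in seq_along(subjects)) {
    s <- spec
    s$seed <- derive_seed(seed, i)
    subjects[[i]] <- generate_subject(s, diseased = i > n_healthy)
    subjects[[i]]$subject_id <- sprintf("S%03d", i)
  }
  dis <- which(vapply(subjects, function(s) s$gold_class != "none", logical(1)))
  if (length(dis) >= 4L) {
    fev <- vapply(subjects[dis], `[[`, numeric(1), "fev1_pct")
    qs <- stats::quantile(fev, c(0.25, 0.5, 0.75))
    cls <- c("D", "C", "B", "A")[findInterval(fev, c(-Inf, qs)) ]
    for (k in seq_along(dis)) subjects[[dis[k]]]$gold_class <- cls[k]
  }
  subjects
}

#' Covariate table of a cohort
#'
#' @param subjects List of `synthetic_subject`s.
#' @return data.frame with subject_id, fev1_pct, dlco_pct, gold_class,
#'   label_copd, label_dlco, burden.
#' @export
cohort_covariates <- function(subjects) {
  data.frame(
    subject_id = vapply(subjects, function(s)
      if (is.null(s$subject_id)) NA_character_ else s$subject_id,
      character(1)),
    fev1_pct = vapply(subjects, `[[`, numeric(1), "fev1_pct"),
    dlco_pct = vapply(subjects, `[[`, numeric(1), "dlco_pct"),
    gold_class = vapply(subjects, `[[`, character(1), "gold_class"),
    label_copd = vapply(subjects, `[[`, numeric(1), "label_copd"),
    label_dlco = vapply(subjects, `[[`, numeric(1), "label_dlco"),
    burden = vapply(subjects, `[[`, numeric(1), "burden"),
    stringsAsFactors = FALSE)
}

#' Write a subject or cohort to disk
#'
#' Volumes, lung masks and lesion masks are written as NIfTI (`.nii.gz`,
#' HU rounded to signed 16-bit); the covariates as a CSV table.
#'
#' @param subjects List of `synthetic_subject`s.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cov <- cohort_covariates(subjects)
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    id <- cov$subject_id[i]
    if (is.na(id)) id <- sprintf("S%03d", i)
    sp <- s$spec$spacing_mm
    wr <- function(a, suffix, dt) {
      img <- RNifti::asNifti(a, datatype = dt,
                             reference = list(pixdim = c(-1, sp, rep(0, 4))))
      RNifti::writeNifti(img, file.path(dir, sprintf("%s_%s.nii.gz", id, suffix)))
    }
    wr(round(s$volume), "volume", "int16")
    wr(s$lung_mask * 1L, "lung_mask", "uint8")
    wr(s$lesion_mask * 1L, "lesion_mask", "uint8")
  }
  utils::write.csv(cov, file.path(dir, "covariates.csv"), row.names = FALSE)
  invisible(dir)
}
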