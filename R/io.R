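#' Serialize bags as a feature table plus subject manifest
#'
#' Writes `features.csv` (subject_id, instance index, one column per
#' feature) and `manifest.csv` (subject_id, label, label_channel), a plain
#' interchange format for trained-elsewhere workflows.
#'
#' @param bags List of [mil_bag()]s.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_bags <- function(bags, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(seq_along(bags), function(i) {
    id <- bags[[i]]$subject_id
    if (is.null(id)) sprintf("S%03d", i) else as.character(id)
  }, character(1))
  feat <- do.call(rbind, lapply(seq_along(bags), function(i) {
    f <- as.data.frame(bags[[i]]$features)
    cbind(data.frame(subject_id = ids[i], instance = seq_len(nrow(f))), f)
  }))
  manifest <- data.frame(
    subject_id = ids,
    label = bag_labels(bags),
    label_channel = vapply(bags, function(b)
      if (is.null(b$label_channel)) NA_character_ else b$label_channel,
      character(1)))
  utils::write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_bags
#' @param dir Directory holding `features.csv` and `manifest.csv`.
#' @export
read_bags <- function(dir) {
  feat <- utils::read.csv(file.path(dir, "features.csv"), check.names = FALSE)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$subject_id[i]
    rows <- feat[feat$subject_id == id, , drop = FALSE]
    mil_bag(as.matrix(rows[, -(1:2), drop = FALSE]),
            label = manifest$label[i], subject_id = id,
            label_channel = if (is.na(manifest$label_channel[i])) NULL
                            else manifest$label_channel[i])
  })
}

#' Export a posterior slice map as a CSV point table
#'
#' One row per classified grid point: slice, x, y, posterior, emphysema
#' label (and lesion ground truth when available).
#'
#' @param map A `posterior_slice_map`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_slice_map <- function(map, path) {
  stopifnot(inherits(map, "posterior_slice_map"))
  utils::write.csv(map$points, path, row.names = FALSE)
  invisible(path)
}

#' Per-fold cross-validation report as a data frame
#'
#' One row per outer fold with the held-out bag AUC, Separability and the
#' selected parameters, suitable for CSV export; the summary row convention
#' (mean +/- sd, x100) is what [print.lungmil_cv()] displays.
#'
#' @param x A `lungmil_cv` object.
#' @param ... Unused.
#' @return data.frame with one row per outer fold.
#' @export
as.data.frame.lungmil_cv <- function(x, ...) {
  do.call(rbind, lapply(x$folds, function(f) {
    k <- f$params$kernel
    data.frame(fold = f$fold, bag_auc = f$auc, separability = f$separability,
               kernel = k$family,
               kernel_param = if (k$family == "rbf") k$bandwidth else k$degree,
               C = f$params$C, q = f$params$q)
  }))
}
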