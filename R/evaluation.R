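#' Separability: instance-level performance without instance labels
#'
#' The difference between the average instance posterior in true positive
#' bags and the average instance posterior in true negative bags:
#' \deqn{S = \frac{\sum_{y_i = +1} f(x_{ij})}{\sum_{y_i = +1} n_i}
#'         - \frac{\sum_{y_i = -1} f(x_{ij})}{\sum_{y_i = -1} n_i}.}
#' A classifier that assigns confident, well-separated instance posteriors
#' scores higher than one that hedges near 0.5, even when both rank the
#' bags perfectly; S ranges over [-1, 1].
#'
#' @param positive List of numeric vectors: instance posteriors of each true
#'   positive bag (or a single vector).
#' @param negative Same for the true negative bags.
#' @return The Separability S.
#' @examples
#' separability(list(c(0.51, 0.49)), list(c(0.49, 0.49)))  # 0.01
#' separability(list(c(0.9, 0.1)), list(c(0.1, 0.1)))      # 0.4
#' @export
separability <- function(positive, negative) {
  if (is.numeric(positive)) positive <- list(positive)
  if (is.numeric(negative)) negative <- list(negative)
  if (length(positive) == 0L || length(negative) == 0L)
    stopf("both a positive and a negative bag are required")
  pos <- unlist(positive); neg <- unlist(negative)
  if (any(pos < 0 | pos > 1) || any(neg < 0 | neg > 1))
    stopf("posteriors must lie in [0, 1]")
  sum(pos) / length(pos) - sum(neg) / length(neg)
}

#' Bag-level area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly drawn positive
#' bag receives a higher posterior than a randomly drawn negative bag, with
#' ties credited 0.5.
#'
#' @param posteriors Numeric vector of bag posteriors.
#' @param labels Vector of true bag labels in \{+1, -1\}.
#' @return AUC in [0, 1].
#' @export
bag_auc <- function(posteriors, labels) {
  stopifnot(length(posteriors) == length(labels))
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("both classes required for AUC")
  r <- rank(posteriors)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Low-attenuation-area percentage (density baseline)
#'
#' The classical density-based emphysema score: the percentage of in-mask
#' voxels with attenuation strictly below the threshold (default -950 HU).
#'
#' @param volume 3D numeric array in HU.
#' @param lung_mask Same-shape binary mask.
#' @param threshold HU threshold (default -950).
#' @return Percentage in [0, 100].
#' @export
laa_percentage <- function(volume, lung_mask, threshold = -950) {
  inside <- lung_mask != 0
  if (!any(inside)) stopf("empty lung mask")
  100 * sum(volume[inside] < threshold) / sum(inside)
}

#' Spearman rank correlation with small-sample exact p-values
#'
#' Rank correlation with average ranks on ties; the two-sided p-value uses
#' the exact small-sample distribution for n < 10 (falling back to the
#' t approximation when ties make the exact distribution unavailable) and
#' the large-sample t approximation otherwise.
#'
#' @param x,y Paired numeric vectors, n >= 5.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5L) stopf("need at least 5 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in one of the variables")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n < 10L))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' \deqn{z = \frac{\mathrm{atanh}(\rho_1) - \mathrm{atanh}(\rho_2)}
#'   {\sqrt{1/(n_1 - 3) + 1/(n_2 - 3)}}}
#' with a two-sided p-value from the standard normal.
#'
#' @param rho1,rho2 Correlations with absolute value < 1.
#' @param n1,n2 Sample sizes (> 3).
#' @return List with `z` and `p`.
#' @export
compare_correlations_fisher <- function(rho1, n1, rho2, n2) {
  if (abs(rho1) >= 1 || abs(rho2) >= 1)
    stopf("correlations must have absolute value < 1")
  if (n1 <= 3 || n2 <= 3) stopf("sample sizes must exceed 3")
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Dice similarity coefficient between binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are in perfect agreement by
#' convention (DSC = 1).
#'
#' @param a,b Binary arrays/vectors of identical shape.
#' @return DSC in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stopf("masks must have identical shape")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
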