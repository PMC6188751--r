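---
title: "Weakly supervised emphysema mapping: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised emphysema mapping: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`lungmil` frames emphysema detection as multiple instance learning. A
subject's scan is a bag $B_i = \{x_{ij}\}_{j=1..n_i}$ of texture feature
vectors computed on randomly sampled $41^3$ parenchymal patches; the bag
label $y_i \in \{+1, -1\}$ comes from a pulmonary function test (COPD
stratification, or DLCO below 60% predicted), never from lesion
annotations. The classic MIL witness assumption, $y_i = \max_j y_{ij}$,
makes a single suspicious patch flip a whole subject; both classifiers here
replace the max with an upper nearest-rank quantile: the aggregate of a
value set at quantile $q$ is its $k$-th largest element with
$k = \lceil (1-q)\,n \rceil$ (clamped to $[1, n]$). At $q = 1$ this is the
maximum; at $q = 0.5$ a bag is positive only when half of its instances
are. The quantile is deliberately uninterpolated, because it is applied to
$\pm 1$ labels during training where interpolation is meaningless.

**miSVM-Q** is an instance-level kernel SVM fitted by iterative label
imputation. All instances inherit their bag label, then repeatedly: an SVM
is trained on the imputed labels; instances in negative bags stay negative;
in each positive bag instances take the classifier's sign, except that the
$k$ highest-scoring instances are forced positive so the bag satisfies the
quantile constraint. Iteration stops at a fixed point or after `max_iter`
(20) rounds; ties in decision values break by stable instance index, and
non-convergence returns the last iterate flagged `converged = FALSE`. Like
every realization of this family, the procedure is a heuristic for a
combinatorial problem: with positive bags dominated by background texture it
can settle in the all-positive initialization's basin rather than the global
assignment (the package's tests compare it against an exhaustive-search
oracle in a regime where the heuristic does reach the optimum). Decision
values are mapped to $[0,1]$ posteriors by a Platt sigmoid fitted on the
final imputed labels with prior-smoothed targets.

**MILES-Q** embeds each bag by its quantile similarity
$s(B_i, x_m) = \mathrm{quantile}_j(\{k(x_{ij}, x_m)\}, q)$ to every
training instance $x_m$ and fits an L1-penalized linear classifier on the
embedding. The penalty is realized as lasso-penalized logistic regression
(glmnet) with $\lambda = 1/(N\,C)$, so the study's $C$ grid maps
monotonically to sparsity; instances with nonzero weight are the retained
prototypes. The original formulation uses a 1-norm hinge-loss SVM; the
logistic surrogate keeps the defining property (sparse prototype selection
by an L1-regularized linear separator) and is the package's frozen choice.
Instance posteriors credit each instance with the weighted similarity of
every prototype whose bag-level aggregate it attains (ties included), plus
the intercept — in a bag of identical instances every instance therefore
reproduces the bag posterior exactly, which the tests assert.

Features are z-scored with training-fold statistics before any kernel is
evaluated; the RBF bandwidth grid (8–20) is interpreted on that
standardized scale, where typical inter-instance distances for a
320-dimensional representation are a few tens. Whether the original
formulation standardized features is unknowable from its description; this
is flagged as an assumption, not a fact.

# Features

*Co-occurrence.* HU values are clamped to $[-1024, 0]$ and quantized to 32
equal-width gray levels (32 keeps a $41^3$-patch GLCM well populated; the
level count is a package choice). GLCMs are accumulated symmetrically for
the 13 unique 3D neighbor directions at voxel distances 1–5, and each is
summarized by 12 Haralick statistics in a frozen documented order. Entropy
uses log base 2; correlation is defined as 0 when a marginal variance
vanishes. With the formulations used, *contrast* and *inertia* coincide
($\sum (i-j)^2 p_{ij}$); both are kept as named features rather than
deduplicated, preserving the advertised 13 × 5 × 12 = 780 layout.

*Gaussian filter bank.* Eight filters — smoothed intensity, gradient
magnitude, Laplacian, the three Hessian eigenvalues sorted descending by
signed value, Gaussian curvature $\det H = \lambda_1\lambda_2\lambda_3$ and
eigen magnitude $\sqrt{\sum \lambda_i^2}$ — at scales 0.6, 1.2, 2.4, 4.8 mm
(σ in mm, converted through the voxel spacing; kernels truncated at 4σ,
with discrete moment corrections so that ramps and quadratics
differentiate exactly). Smoothing is normalized convolution: the masked
volume and the mask are convolved separately and divided, so out-of-mask
voxels carry zero weight and a constant volume smooths to that constant
inside any mask. Derivatives are Gaussian-derivative correlations of the
masked volume divided by the smoothed mask — one defensible reading of
"normalized convolution plus derivatives"; derivative responses within a
scale of the mask boundary respond partly to the boundary itself, which is
shared by training and test features and therefore consistent. Responses
are summarized by 10-bin histograms over fixed edges placed at the deciles
of responses pooled from an *independent* reference cohort (adaptive
binning), which preserves train/test separation; 8 × 4 × 10 = 320 features.

# The pipeline

50 patch centers per subject are drawn uniformly (with replacement) among
in-mask voxels whose full patch fits in the volume. Model selection is a
nested stratified cross-validation: 4 outer subject-level folds; within
each outer training set a 3-fold inner CV scores every parameter candidate
by mean bag AUC, ties broken by larger Separability (the combination rule
when both metrics matter is a package decision). The full study grid —
polynomial degrees {1, 2}, RBF bandwidths {8, 10, 12, 14, 16, 20},
C ∈ {0.001, …, 1}, q ∈ {0.25, 0.5, 0.75, 0.9, 1} — is available via
`mil_param_grid()`; desk-scale runs use documented subsets.

Posterior slice maps follow the slice-grid protocol: 10 axial slices spaced
25 apart (configurable; short phantoms use a smaller spacing so that 10
slices fit), excluding the top and bottom 10% of lung-bearing slices — the
protocol's "top and bottom parts of the lungs" is not quantified anywhere,
so 10% is the package's fixed realization. Within a slice every 10th voxel
in both in-plane directions is classified if it lies in the lung mask;
patches at the volume border are clipped and used only when at least half
their voxels are in-mask, else skipped. A grid point is emphysema when its
posterior strictly exceeds 0.5, and % emphysema is the fraction of positive
grid points (grid points, not all lung voxels — the denominator follows the
sampling protocol).

Separability is defined on training bags but is equally computable on test
bags; `nested_cv()` reports it on the held-out bags of each outer fold and
labels it as such. Averages are taken on the raw scale and only scaled
(×100) for display.

# The synthetic phantoms

The generator emulates exactly what the method needs to see: an ellipsoidal
"lung" (semi-axes 38% of each extent) filled with spatially correlated
Gaussian texture (smoothed white noise, 3 mm correlation length) around
−850 HU (σ = 30 HU), and, in diseased subjects, spherical lesions of radius
4–10 mm around −975 HU (σ = 12 HU) placed at uniform in-lung centers until
the realized burden reaches the target (default 0.2 of lung volume). The
125 HU contrast straddles the −950 HU threshold, so the LAA baseline can
see the lesions — by design, since the density mask is the comparison
method. Covariates follow a fixed decreasing noisy link,
$\mathrm{DLCO\%} = 85 - 180\,b + \varepsilon$, $\varepsilon \sim N(0, 8)$
(FEV1 analogous, independent noise): at zero burden DLCO centers at 85%,
well above the 60% labeling threshold, and at burden 0.2 at 49%, well
below. Any decreasing link would do; this one is frozen so the label
thresholds are meaningful. GOLD classes take "none" for healthy subjects
and A–D by cohort FEV1 quartile for diseased ones — a cohort's true GOLD
distribution is not reproducible synthetically, and the generator only
guarantees both classes are represented. One master seed derives
per-subject streams, so cohorts are bit-reproducible.

What the phantoms do *not* emulate: airways and vessels, respiratory
motion, scanner kernels and dose, inter-scanner intensity shifts, the
spatial preferences of real centrilobular emphysema, or clinically
realistic covariate scatter. Passing the phantom suite therefore shows the
machinery is correct and the signal path works at a favorable
contrast-to-noise ratio; it does not certify performance on clinical HRCT,
where the texture contrast is weaker and the weak labels are noisier.

# Numerical choices and degenerate inputs

- Quantile convention: upper nearest rank, no interpolation (above).
- Entropy log base 2; zero-probability GLCM cells contribute zero.
- GLCM with no valid voxel pair (distance exceeds the patch) is an error,
  not an empty matrix.
- Adaptive binning with non-increasing decile edges (constant reference
  responses) is an error; fitting needs at least 10 samples per bin.
- σ below 0.3 voxels is rejected as undersampled.
- Platt calibration forces a nondecreasing map (slope floor 1e-3) when
  separation makes the logistic fit degenerate.
- Dice of two empty masks is 1 by convention; LAA uses strict `<`;
  % emphysema uses strict `> 0.5`, so an exactly-0.5 posterior is healthy.
- Spearman p-values: exact small-sample distribution for n < 10 (t
  approximation under ties), t approximation otherwise.
- Hessian eigenvalues by the closed-form trigonometric method for symmetric
  3×3 matrices, vectorized over voxels; `p ≈ 0` (isotropic) short-circuits
  to three equal eigenvalues.

# Problem sizes

The validation suite runs, on one CPU: a 10 vs 10 phantom cohort at
$96^3$ voxels with 50 patches of $41^3$ per subject and Gaussian features;
nested 4/3-fold CV over a reduced grid (RBF bandwidths {8, 16},
C ∈ {0.01, 0.1}, q ∈ {0.5, 1}); a posterior slice map at slice spacing 6
(so ten slices fit a 96-slice phantom); the LAA check at $128^3$. These
sizes were chosen as the smallest at which the cohort-level claims are
stable; the full study grid and larger cohorts run unchanged through the
same functions if given more time.

# Known limitations

- The miSVM-Q imputation heuristic has local optima (above); q = 1
  equivalence with the classic witness scheme and agreement with an
  exhaustive oracle on small separable sets are tested, bitwise fidelity to
  any other implementation is not claimed.
- MILES-Q's instance-labeling rule is a construction: the original method
  defines prototype selection but not instance scoring under a quantile
  aggregate; crediting the attaining top-k set is one defensible rule and
  is documented as such.
- Lasso logistic regression stands in for the 1-norm hinge SVM; sparsity
  patterns are qualitatively, not numerically, identical.
- Adaptive bins fitted on synthetic reference subjects tailor the
  histograms to phantom statistics; for clinical use they must be refitted
  on a real, independent dataset.
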