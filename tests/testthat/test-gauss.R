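test_that("the 3D Gaussian kernel has the right closed form and mass", {
  expect_equal(gaussian_kernel_value(c(0, 0, 0), 1), (2 * pi)^(-1.5))
  expect_lt(gaussian_kernel_value(c(100, 0, 0), 1), 1e-300)
  expect_error(gaussian_kernel_value(c(0, 0, 0), 0), "positive")
  # numeric quadrature: integral over +/- 6 sigma is 1
  sigma <- 2
  g <- seq(-6 * sigma, 6 * sigma, by = 0.25)
  pts <- as.matrix(expand.grid(g, g, g))
  mass <- sum(gaussian_kernel_value(pts, sigma)) * 0.25^3
  expect_equal(mass, 1, tolerance = 1e-3)
})

test_that("discrete derivative kernels are exact on polynomials", {
  w1 <- lungmil:::gauss_kernel_1d(2, 1, 1L)
  r <- (length(w1) - 1) / 2
  x <- seq(-r - 5, r + 5)
  expect_equal(sum(w1), 0)
  expect_equal(sum(w1 * (-r:r)), 1)  # derivative of a unit ramp
  w2 <- lungmil:::gauss_kernel_1d(2, 1, 2L)
  expect_equal(sum(w2), 0)
  expect_equal(sum(w2 * (-r:r)^2), 2)  # second derivative of x^2
  expect_error(lungmil:::gauss_kernel_1d(0.2, 1, 0L), "undersampled")
})

test_that("filter bank responds correctly to analytic fields", {
  d <- c(25, 25, 25)
  full <- array(1, d)
  # constant volume: smoothed constant, all derivative filters 0
  fb <- filter_bank(array(-850, d), full, 2)
  ctr <- 13
  expect_equal(fb$smoothed[ctr, ctr, ctr], -850)
  expect_equal(fb$gradmag[ctr, ctr, ctr], 0, tolerance = 1e-9)
  expect_equal(fb$laplacian[ctr, ctr, ctr], 0, tolerance = 1e-9)
  expect_equal(fb$hess1[ctr, ctr, ctr], 0, tolerance = 1e-9)
  # linear ramp I = x: unit gradient, zero curvature, away from borders
  ramp <- array(0, d); for (i in seq_len(d[1])) ramp[i, , ] <- i
  fb2 <- filter_bank(ramp, full, 2)
  expect_equal(fb2$gradmag[ctr, ctr, ctr], 1, tolerance = 1e-6)
  expect_equal(fb2$laplacian[ctr, ctr, ctr], 0, tolerance = 1e-6)
  expect_equal(fb2$gausscurv[ctr, ctr, ctr], 0, tolerance = 1e-9)
  # normalized convolution: constant stays constant inside any mask
  half <- array(0, d); half[1:12, , ] <- 1
  fb3 <- filter_bank(array(5, d), half, 3)
  expect_equal(range(fb3$smoothed[half == 1]), c(5, 5), tolerance = 1e-9)
  expect_true(all(is.na(fb3$smoothed[half == 0])))
  expect_error(filter_bank(array(5, d), array(0, d), 2), "empty")
})

test_that("Hessian eigenvalues are sorted and consistent with eigen()", {
  set.seed(5)
  for (i in 1:20) {
    a <- matrix(rnorm(9), 3); a <- (a + t(a)) / 2
    got <- lungmil:::sym3_eigenvalues(a[1, 1], a[2, 2], a[3, 3],
                                      a[1, 2], a[1, 3], a[2, 3])
    want <- sort(eigen(a, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
    expect_equal(c(got$l1, got$l2, got$l3), want, tolerance = 1e-8)
  }
})

test_that("adaptive binning equalizes reference mass", {
  bm <- fit_adaptive_bins(list(ch = 1:100), n_bins = 10L)
  counts <- table(cut(1:100, bm$edges$ch))
  expect_true(all(counts == 10))
  expect_error(fit_adaptive_bins(list(ch = rep(1, 200)), 10L), "degenerate")
  expect_error(fit_adaptive_bins(list(ch = 1:50), 10L), "at least")
  set.seed(2)
  bm2 <- fit_adaptive_bins(list(ch = rnorm(1e5)), 10L)
  expect_equal(bm2$edges$ch[2:10], qnorm(seq(0.1, 0.9, 0.1)),
               tolerance = 0.05)
})

test_that("binning models round-trip through plain text", {
  set.seed(4)
  bm <- fit_adaptive_bins(list(a = rnorm(500), b = runif(500)), 10L)
  path <- tempfile(fileext = ".tsv")
  write_binning(bm, path)
  bm2 <- read_binning(path)
  expect_equal(bm2$edges, bm$edges)
})

test_that("gauss_features yields 320 normalized histogram blocks", {
  set.seed(9)
  d <- c(41, 41, 41)
  patch <- array(rnorm(prod(d), -850, 40), d)
  mask <- array(1, d)
  cfg <- gauss_config()
  chans <- lungmil:::gauss_channel_names(cfg)
  set.seed(10)
  bm <- fit_adaptive_bins(setNames(lapply(chans, function(ch) rnorm(200, 0, 100)),
                                   chans), 10L)
  v <- gauss_features(patch, mask, cfg, bm)
  expect_length(v, 320L)
  blocks <- matrix(v, nrow = 10)
  expect_true(all(abs(colSums(blocks) - 1) < 1e-9))
  expect_error(gauss_features(patch, array(0, d), cfg, bm), "empty")
  # responses confined to one bin give a one-hot block
  bm1 <- bm
  bm1$edges[["s0.6_smoothed"]] <- c(-Inf, -2000, -1000, seq(0, 600, 100), Inf)
  v1 <- gauss_features(array(-850, d), mask, cfg, bm1)
  block <- v1[grep("^gauss_s0.6_smoothed", names(v1))]
  expect_equal(unname(block), c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0))  # -850 in [-1000, 0)
})

test_that("eigenvalue-derived histograms are invariant to 90-degree rotation", {
  set.seed(21)
  d <- c(20, 20, 20)
  patch <- array(rnorm(prod(d), -850, 40), d)
  rot90 <- function(a) aperm(a, c(2, 1, 3))[, dim(a)[1]:1, ]
  rot <- rot90(patch)
  full <- array(1, d)
  fb1 <- filter_bank(patch, full, 2)
  fb2 <- filter_bank(rot, full, 2)
  for (f in c("gradmag", "laplacian", "hess1", "hess3", "gausscurv", "eigmag")) {
    expect_equal(fb2[[f]], rot90(fb1[[f]]), tolerance = 1e-8)
  }
})
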