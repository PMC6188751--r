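test_that("HU quantization clamps and bins linearly", {
  cfg <- glcm_config(n_levels = 32L, hu_window = c(-1000, -500))
  expect_equal(unique(as.vector(quantize_hu(array(-850, c(3, 3, 3)), cfg))),
               floor((-850 + 1000) / 500 * 32))
  q <- quantize_hu(array(c(-1000, -500), c(1, 1, 2)), cfg)
  expect_equal(as.vector(q), c(0L, 31L))
  # values beyond the window clamp to the extreme levels
  q2 <- quantize_hu(array(c(-2000, 100), c(1, 1, 2)), cfg)
  expect_equal(as.vector(q2), c(0L, 31L))
  expect_error(quantize_hu(numeric(0)), "empty")
  expect_error(glcm_config(hu_window = c(0, -10)), "low < high")
})

test_that("glcm counts ordered pairs and normalizes", {
  q <- array(c(0L, 1L, 0L), c(1, 1, 3))
  g <- glcm(q, c(0, 0, 1), 1, n_levels = 2, symmetric = TRUE)
  expect_equal(g, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  # asymmetric: pairs (0,1) and (1,0) once each
  ga <- glcm(q, c(0, 0, 1), 1, n_levels = 2, symmetric = FALSE)
  expect_equal(ga, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  const <- array(3L, c(4, 4, 4))
  gc <- glcm(const, c(1, 0, 0), 2, n_levels = 8)
  expect_equal(gc[4, 4], 1)
  expect_equal(sum(gc), 1)
  expect_error(glcm(const, c(1, 0, 0), 10, n_levels = 8), "no voxel pairs")
})

test_that("glcm matches brute-force pair enumeration on random volumes", {
  set.seed(42)
  dirs <- glcm_directions()
  expect_equal(nrow(dirs), 13L)
  expect_true(all(rowSums(abs(dirs)) > 0))
  # no two directions antiparallel
  for (i in 1:12) for (j in (i + 1):13)
    expect_false(all(dirs[i, ] == -dirs[j, ]))
  for (rep in 1:5) {
    q <- array(sample(0:3, 64, replace = TRUE), c(4, 4, 4))
    for (di in seq_len(nrow(dirs))) for (dist in 1:3) {
      ref <- brute_glcm(q, dirs[di, ], dist, 4L)
      if (is.null(ref)) {
        expect_error(glcm(q, dirs[di, ], dist, 4L))
      } else {
        expect_equal(glcm(q, dirs[di, ], dist, 4L), ref)
      }
    }
  }
})

test_that("haralick statistics match hand computations", {
  # constant patch: single entry GLCM
  h1 <- haralick(matrix(c(rep(0, 15), 1), 4, 4))
  expect_equal(unname(h1["energy"]), 1)
  expect_equal(unname(h1["entropy"]), 0)
  expect_equal(unname(h1["max_probability"]), 1)
  expect_equal(unname(h1["contrast"]), 0)
  # 2x2 diagonal: energy 0.5, entropy 1 bit
  h2 <- haralick(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(unname(h2["energy"]), 0.5)
  expect_equal(unname(h2["entropy"]), 1)
  # uniform 4x4
  h3 <- haralick(matrix(1 / 16, 4, 4))
  expect_equal(unname(h3["max_probability"]), 1 / 16)
  # contrast and inertia coincide under the formulations used
  set.seed(1)
  m <- matrix(runif(16), 4, 4); m <- m / sum(m)
  h4 <- haralick(m)
  expect_equal(unname(h4["contrast"]), unname(h4["inertia"]))
  # correlation convention: 0 when a marginal variance vanishes
  expect_equal(unname(h1["correlation"]), 0)
  expect_error(haralick(matrix(1, 2, 2)), "normalized")
})

test_that("cooc_features has length 780 with frozen ordering", {
  set.seed(7)
  patch <- array(rnorm(41^3, -850, 40), c(41, 41, 41))
  v <- cooc_features(patch)
  expect_length(v, 780L)
  expect_equal(length(unique(names(v))), 780L)
  # direction-major, then distance, then statistic
  expect_match(names(v)[1], "^cooc_d1_dir\\(0,0,1\\)_energy$")
  expect_match(names(v)[13], "^cooc_d2_dir\\(0,0,1\\)_energy$")
})

test_that("constant patches give degenerate Haralick features", {
  v <- cooc_features(array(-850, c(8, 8, 8)))
  expect_true(all(v[grep("_energy$", names(v))] == 1))
  expect_true(all(v[grep("_entropy$", names(v))] == 0))
})

test_that("rotating a patch permutes direction blocks but keeps per-statistic multisets", {
  set.seed(11)
  patch <- array(rnorm(10^3, -850, 40), c(10, 10, 10))
  rot <- aperm(patch, c(2, 1, 3))[, 10:1, ]  # 90 degrees about z
  v1 <- cooc_features(patch)
  v2 <- cooc_features(rot)
  for (stat in c("entropy", "contrast", "correlation")) {
    b1 <- v1[grep(paste0("_", stat, "$"), names(v1))]
    b2 <- v2[grep(paste0("_", stat, "$"), names(v2))]
    expect_equal(sort(unname(b1)), sort(unname(b2)), tolerance = 1e-12)
  }
})

test_that("adding a zero HU offset leaves quantization unchanged", {
  set.seed(3)
  patch <- array(rnorm(6^3, -700, 50), c(6, 6, 6))
  expect_identical(quantize_hu(patch), quantize_hu(patch + 0))
  # a one-bin-width shift moves interior levels by exactly one
  cfg <- glcm_config(n_levels = 32L, hu_window = c(-1024, 0))
  step <- 1024 / 32
  q1 <- quantize_hu(patch, cfg)
  q2 <- quantize_hu(patch + step, cfg)
  interior <- q1 > 0 & q1 < 31 & q2 > 0 & q2 < 31
  expect_true(all((q2 - q1)[interior] == 1L))
})
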