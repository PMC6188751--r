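test_that("quantile embedding follows the nearest-rank rule", {
  proto <- matrix(c(0, 0), 1, 2)
  spec <- kernel_spec("rbf", bandwidth = 1)
  # bag containing the prototype exactly: max similarity 1
  bag <- mil_bag(rbind(c(0, 0), c(5, 5)))
  expect_equal(miles_embed(bag, proto, spec, q = 1)[1], 1)
  # identical instances: embedding independent of q
  same <- mil_bag(matrix(rep(c(1, 2), 3), 3, 2, byrow = TRUE))
  for (q in c(0.25, 0.5, 1))
    expect_equal(miles_embed(same, proto, spec, q),
                 miles_embed(same, proto, spec, 1))
  # hand-ranked similarities
  sims_of <- function(feats) mil_kernel(feats, proto, spec)[, 1]
  f2 <- rbind(c(0.668, 0), c(1.794, 0))     # similarities ~0.8, ~0.2
  expect_equal(round(sims_of(f2), 1), c(0.8, 0.2))
  expect_equal(miles_embed(mil_bag(f2), proto, spec, 0.5), max(sims_of(f2)))
  f4 <- rbind(c(0.459, 0), c(0.668, 0), c(1.794, 0), c(2.146, 0))
  expect_equal(round(sims_of(f4), 1), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(miles_embed(mil_bag(f4), proto, spec, 0.5),
               sort(sims_of(f4), decreasing = TRUE)[2])  # 0.8: k = 2 of 4
  expect_error(miles_embed(matrix(numeric(0), 0, 2), proto, spec, 1), "empty")
})

test_that("q = 1 embedding equals the max-similarity embedding elementwise", {
  set.seed(41)
  protos <- matrix(rnorm(20), 10, 2)
  spec <- kernel_spec("rbf", bandwidth = 1.5)
  for (i in 1:5) {
    bag <- mil_bag(matrix(rnorm(2 * sample(2:6, 1)), ncol = 2))
    K <- mil_kernel(bag$features, protos, spec)
    expect_equal(miles_embed(bag, protos, spec, 1), apply(K, 2, max))
  }
})

test_that("MILES-Q separates toy concepts and selects discriminative prototypes", {
  bags <- toy_cohort(6, 6, n_inst = 8, pos_frac = 0.25, seed = 42)
  m <- miles_q(bags, mil_params(kernel_spec("rbf", bandwidth = 2), C = 1, q = 1))
  post <- predict(m, bags, type = "bag")
  expect_equal(sign(post - 0.5), bag_labels(bags))
  expect_true(all(post >= 0 & post <= 1))
  # positively weighted prototypes sit in the lesion concept (mean 3 cluster)
  raw <- sweep(sweep(m$prototypes, 2, m$standardization$scale, `*`), 2,
               m$standardization$center, `+`)
  pos_protos <- raw[m$weights > 0, , drop = FALSE]
  expect_true(nrow(pos_protos) >= 1)
  expect_true(all(rowMeans(pos_protos) > 1.5))
})

test_that("regularization controls prototype sparsity monotonically", {
  bags <- toy_cohort(6, 6, n_inst = 8, pos_frac = 0.25, seed = 43)
  Cs <- c(0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1)
  sizes <- vapply(Cs, function(C) {
    m <- miles_q(bags, mil_params(kernel_spec("rbf", bandwidth = 2), C = C, q = 1))
    length(m$weights)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))   # smaller C never keeps more prototypes
  expect_equal(sizes[1], 0)            # near-total sparsity at tiny C
})

test_that("duplicating a training bag barely moves the decision function", {
  bags <- toy_cohort(5, 5, n_inst = 6, pos_frac = 0.5, seed = 44)
  par <- mil_params(kernel_spec("rbf", bandwidth = 2), C = 1, q = 0.5)
  m1 <- miles_q(bags, par)
  m2 <- miles_q(c(bags, bags[1]), par)
  dec <- function(m) vapply(bags, function(b) {
    bs <- lungmil:::apply_standardizer(b$features, m$standardization)
    lungmil:::miles_bag_decision(m, bs)
  }, numeric(1))
  d1 <- dec(m1); d2 <- dec(m2)
  expect_equal(sign(d1), sign(d2))
  expect_lt(max(abs(d1 - d2)), 0.5)
})

test_that("q = 1 MILES matches the reference max-based MILES decision signs", {
  bags <- toy_cohort(5, 5, n_inst = 6, pos_frac = 0.5, seed = 45)
  par <- mil_params(kernel_spec("rbf", bandwidth = 2), C = 1, q = 1)
  m <- miles_q(bags, par)
  ref <- reference_miles_max(bags, par)
  for (b in bags) {
    bs <- lungmil:::apply_standardizer(b$features, m$standardization)
    got <- lungmil:::miles_bag_decision(m, bs)
    expect_equal(sign(got), sign(ref$decision(b)))
  }
})

test_that("instance scoring credits attaining instances and is order-invariant", {
  bags <- toy_cohort(5, 5, n_inst = 6, pos_frac = 0.5, seed = 46)
  par <- mil_params(kernel_spec("rbf", bandwidth = 2), C = 1, q = 1)
  m <- miles_q(bags, par)
  b <- bags[[1]]
  # identical instances: every instance posterior equals the bag posterior
  same <- mil_bag(b$features[c(2, 2, 2), ])
  expect_equal(unique(round(predict(m, same, type = "instance"), 12)),
               round(predict(m, same, type = "bag"), 12))
  # bag posterior invariant under instance permutation
  perm <- mil_bag(b$features[rev(seq_len(nrow(b$features))), ])
  expect_equal(predict(m, perm, type = "bag"), predict(m, b, type = "bag"))
  # hand computation of the contribution rule on a 2-instance bag, q = 1:
  # each instance collects w_m * k(x_j, p_m) over prototypes where it is the max
  feats <- b$features[1:2, ]
  fs <- lungmil:::apply_standardizer(feats, m$standardization)
  K <- mil_kernel(fs, m$prototypes, m$params$kernel)
  attains <- apply(K, 2, which.max)
  dec_hand <- m$intercept +
    vapply(1:2, function(j) sum(m$weights[attains == j] * K[j, attains == j]),
           numeric(1))
  got <- predict(m, mil_bag(feats), type = "instance")
  expect_equal(got, lungmil:::apply_platt(m$posterior_map, dec_hand))
})

test_that("MILES requires both classes and rejects empty bags", {
  bags <- lapply(1:4, function(i) toy_bag(1, 2, -1))
  expect_error(miles_q(bags, mil_params()), "both classes")
})
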