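# Toy data builders shared across tests.

# Bag with n_pos instances near the "lesion" concept (mean mu_pos) and n_neg
# near the background (mean 0), in 2-D feature space.
toy_bag <- function(n_pos, n_neg, label, mu_pos = 3, sd = 0.4) {
  f <- rbind(
    if (n_pos > 0) matrix(stats::rnorm(n_pos * 2, mu_pos, sd), n_pos, 2),
    if (n_neg > 0) matrix(stats::rnorm(n_neg * 2, 0, sd), n_neg, 2))
  mil_bag(f, label)
}

# A separable MIL cohort: positive bags contain pos_frac lesion instances.
toy_cohort <- function(n_pos_bags = 5, n_neg_bags = 5, n_inst = 10,
                       pos_frac = 0.5, seed = 1, sd = 0.4) {
  set.seed(seed)
  k <- round(pos_frac * n_inst)
  c(lapply(seq_len(n_pos_bags), function(i) toy_bag(k, n_inst - k, 1, sd = sd)),
    lapply(seq_len(n_neg_bags), function(i) toy_bag(0, n_inst, -1, sd = sd)))
}

# Small phantom spec used where full 128^3 volumes are unnecessary.
small_spec <- function(seed = 1L, shape = c(64L, 64L, 64L), ...) {
  phantom_spec(shape = shape, seed = seed, ...)
}

# Reference subjects for adaptive binning, disjoint seeds from study cohorts.
reference_subjects <- function(spec, n = 3L, seed = 777L) {
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- lungmil:::derive_seed(seed, i)
    generate_subject(s, diseased = i > 1L)
  })
}
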