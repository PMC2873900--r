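test_that("iterative removal finds disjoint boundaries but only those", {
  # one group of size 2: the two boundaries {X1.1} and {X1.2} are disjoint,
  # so the second pass can find the equivalent member
  b <- build_multiplicity_network(equivalence_group_spec(
    c(2), n_noise_vars = 2, target_noise = 0.1, seed = 7))
  ds <- sample_bn(b$net, 2000, seed = 2)
  res <- iterative_removal(ds, "T", make_base_inducer(), seed = 3)
  expect_identical(res$method, "iterative_removal")
  expect_length(res$signatures, 2)
  expect_true(sets_equal(lapply(res$signatures, function(s) s$variables),
                         b$truth$markov_boundaries))
  # accepted signatures are pairwise disjoint by construction
  vars <- lapply(res$signatures, function(s) s$variables)
  expect_length(intersect(vars[[1]], vars[[2]]), 0)
})

test_that("iterative removal stops cleanly on all-noise data", {
  df <- withr::with_seed(9, {
    d <- as.data.frame(lapply(1:5, function(i) factor(sample(0:1, 300, TRUE))))
    names(d) <- sprintf("V%d", 1:5)
    d$T <- factor(sample(0:1, 300, TRUE))
    d
  })
  res <- iterative_removal(df, "T", make_base_inducer(), seed = 3)
  expect_lte(length(res$signatures), 1)
})

test_that("bootstrap resampling is seeded and deduplicated", {
  f <- pathway_fixture()
  ds <- sample_bn(f$net, 2000, seed = 6)
  ind <- make_base_inducer()
  r1 <- resampling_extraction(ds, "T", ind, n_iter = 10, seed = 42)
  r2 <- resampling_extraction(ds, "T", ind, n_iter = 10, seed = 42)
  expect_identical(sig_sets(r1), sig_sets(r2))
  keys <- vapply(r1$signatures, function(s) paste(s$variables, collapse = ","),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
  # n_iter = 1 is exactly the base inducer on one bootstrap
  r3 <- resampling_extraction(ds, "T", ind, n_iter = 1, seed = 5)
  expect_length(r3$signatures, 1)
})

test_that("resampling multiplicity does not grow with sample size", {
  f <- pathway_fixture()
  ind <- make_base_inducer()
  count_at <- function(n) {
    ds <- sample_bn(f$net, n, seed = 31)
    length(resampling_extraction(ds, "T", ind, n_iter = 30, seed = 17)$signatures)
  }
  expect_lte(count_at(5000), count_at(500))
})

test_that("KIAMB is deterministic at k_rand = 0 and seeded otherwise", {
  f <- pathway_fixture()
  ds <- sample_bn(f$net, 5000, seed = 13)
  s1 <- kiamb(ds, "T", k_rand = 0, seed = 1)
  s2 <- kiamb(ds, "T", k_rand = 0, seed = 99)
  expect_identical(s1$variables, s2$variables)  # IAMB behavior
  s3 <- kiamb(ds, "T", k_rand = 0.8, seed = 4)
  s4 <- kiamb(ds, "T", k_rand = 0.8, seed = 4)
  expect_identical(s3$variables, s4$variables)
})

test_that("KIAMB output survives its own backward check", {
  f <- pathway_fixture()
  ds <- sample_bn(f$net, 5000, seed = 23)
  for (seed in 1:5) {
    s <- kiamb(ds, "T", k_rand = 0.8, seed = seed)
    if (length(s$variables) == 0) next
    for (x in s$variables) {
      res <- g2_test(ds, x, "T", setdiff(s$variables, x))
      expect_true(res$reliable && res$p_value < 0.05)
    }
  }
})

test_that("randomized search reaches both boundaries of the pathway net at large n", {
  f <- pathway_fixture()
  big <- sample_bn(f$net, 50000, seed = 3)
  outs <- lapply(1:60, function(seed)
    kiamb(big, "T", k_rand = 0.8, seed = seed)$variables)
  hit_ac <- any(vapply(outs, function(v) identical(v, c("A", "C")), logical(1)))
  hit_bc <- any(vapply(outs, function(v) identical(v, c("B", "C")), logical(1)))
  expect_true(hit_ac && hit_bc)
})

test_that("conditioning on the whole blanket makes KIAMB sample-inefficient", {
  # three groups (boundary size 3): the forward tests condition on the full
  # blanket estimate, so reliability collapses at small n and no optimal
  # signature is recovered, while large n is unproblematic
  b <- mult222_fixture()
  big <- sample_bn(b$net, 20000, seed = 8)
  big_frac <- mean(vapply(1:30, function(seed) {
    set_in(kiamb(big, "T", k_rand = 0.8, seed = seed)$variables,
           b$truth$markov_boundaries)
  }, logical(1)))
  small <- sample_bn(b$net, 150, seed = 8)
  small_frac <- mean(vapply(1:30, function(seed) {
    set_in(kiamb(small, "T", k_rand = 0.8, seed = seed)$variables,
           b$truth$markov_boundaries)
  }, logical(1)))
  expect_gt(big_frac, 0.5)
  expect_lt(small_frac, 0.2)
})
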