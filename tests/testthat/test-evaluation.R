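# Brute-force AUC over all positive-negative pairs, the oracle for auc_score.
pairwise_auc <- function(labels, scores) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

test_that("AUC equals the exhaustive pair statistic, with ties counted half", {
  expect_identical(auc_score(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_identical(auc_score(c(1, 0, 1, 0), c(0, 1, 0, 1)), 0)
  l <- c(1, 0, 1, 0); s <- c(0.9, 0.8, 0.4, 0.1)
  expect_equal(auc_score(l, s), pairwise_auc(l, s))
  withr::with_seed(14, {
    for (i in 1:20) {
      n <- sample(10:200, 1)
      l <- sample(0:1, n, TRUE)
      if (sum(l) == 0 || sum(l) == n) next
      s <- sample(seq(0, 1, by = 0.1), n, TRUE)  # force ties
      expect_equal(auc_score(l, s), pairwise_auc(l, s), tolerance = 1e-12)
      expect_equal(auc_score(l, -s), 1 - auc_score(l, s), tolerance = 1e-12)
    }
  })
  expect_error(auc_score(rep(1, 5), stats::rnorm(5)), "both classes")
})

test_that("rank-sum p-values match full enumeration on small samples", {
  # oracle: enumerate all assignments of ranks to group A
  enum_p <- function(a, b) {
    obs <- sum(rank(c(a, b))[seq_along(a)])
    combos <- utils::combn(length(a) + length(b), length(a))
    stats_all <- apply(combos, 2, function(idx) sum(idx))
    mean(abs(stats_all - mean(stats_all)) >= abs(obs - mean(stats_all)))
  }
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(wilcoxon_rank_sum(a, b), enum_p(a, b), tolerance = 1e-12)
  a2 <- c(1.2, 3.4, 2.2, 5.1); b2 <- c(2.9, 4.4, 6.3)
  expect_equal(wilcoxon_rank_sum(a2, b2), enum_p(a2, b2), tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 1, 2), c(1, 1, 2)), 1, tolerance = 0.05)
  withr::with_seed(3, {
    expect_lt(wilcoxon_rank_sum(stats::rnorm(40), stats::rnorm(40) + 3), 1e-6)
  })
  expect_error(wilcoxon_rank_sum(1, c(1, 2)), "at least 2")
})

test_that("repeated holdout is seeded and near the exact Bayes AUC on a true boundary", {
  b <- mult222_fixture()
  ds <- mult222_data()
  boundary <- b$truth$markov_boundaries[[1]]
  est <- repeated_holdout_auc(ds, boundary, t = "T", n_splits = 10, seed = 2)
  est2 <- repeated_holdout_auc(ds, boundary, t = "T", n_splits = 10, seed = 2)
  expect_identical(est$per_split_auc, est2$per_split_auc)
  expect_equal(est$mean_auc, mean(est$per_split_auc), tolerance = 1e-12)
  bayes <- bayes_auc_exact(b$net, boundary)
  expect_lt(abs(est$mean_auc - bayes), 0.03)
})

test_that("a pure-noise signature scores at chance", {
  b <- mult222_fixture()
  ds <- mult222_data()
  est <- repeated_holdout_auc(ds, c("N1", "N2"), t = "T", n_splits = 20, seed = 6)
  expect_gt(est$mean_auc, 0.45)
  expect_lt(est$mean_auc, 0.55)
  expect_error(repeated_holdout_auc(ds, character(0), t = "T"), "empty")
})

test_that("maximal predictivity is attained by indistinguishable methods only", {
  good <- method_report("good", list(c("X")),
                        list(predictivity_estimate(c(.9, .91, .89, .9), classifier_spec())),
                        validation_auc = c(0.90, 0.91, 0.89, 0.90, 0.92))
  same <- method_report("same", list(c("Y")),
                        list(predictivity_estimate(c(.9, .9, .9, .9), classifier_spec())),
                        validation_auc = c(0.91, 0.90, 0.89, 0.90, 0.91))
  bad <- method_report("bad", list(c("Z")),
                       list(predictivity_estimate(c(.5, .52, .48, .5), classifier_spec())),
                       validation_auc = c(0.50, 0.52, 0.48, 0.51, 0.49))
  mp <- maximal_predictivity(list(good, same, bad))
  expect_setequal(mp$methods, c("good", "same"))
  expect_equal(mp$value, mean(c(0.90, 0.91, 0.89, 0.90, 0.92)), tolerance = 1e-12)
  solo <- maximal_predictivity(list(bad))
  expect_identical(solo$methods, "bad")
})

test_that("the reproducibility protocol behaves on identical data and empty methods", {
  b <- mult222_fixture()
  ds <- mult222_data()
  methods <- list(
    one_boundary = function(d, t) list(b$truth$markov_boundaries[[1]]),
    nothing = function(d, t) list()
  )
  reports <- reproducibility_protocol(ds, ds, methods, t = "T",
                                      n_splits = 5, seed = 8)
  expect_length(reports, 2)
  # same-data validation cannot be systematically below the holdout estimate
  expect_gte(reports[[1]]$avg_validation_auc,
             reports[[1]]$avg_discovery_auc - 0.02)
  expect_length(reports[[2]]$signatures, 0)
  expect_true(is.na(reports[[2]]$overfitting))
  bad_val <- data.frame(Q = factor(sample(0:1, 50, TRUE)),
                        T = factor(sample(0:1, 50, TRUE)))
  expect_error(reproducibility_protocol(ds[c("X1.1", "T")],
                                        bad_val["Q"], methods, t = "T"),
               "target")
  expect_error(reproducibility_protocol(ds[c("X1.1", "T")],
                                        bad_val, methods, t = "T"),
               "no predictor")
})

test_that("scatter output lists one row per method-signature pair", {
  b <- mult222_fixture()
  ds <- mult222_data()
  reports <- reproducibility_protocol(
    ds, sample_bn(b$net, 1000, seed = 30),
    list(two = function(d, t) b$truth$markov_boundaries[1:2]),
    t = "T", n_splits = 5, seed = 8)
  sc <- reproducibility_scatter(reports)
  expect_identical(nrow(sc), 2L)
  expect_true(all(c("method", "signature", "discovery_auc", "validation_auc")
                  %in% names(sc)))
})
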