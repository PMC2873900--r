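test_that("G2 matches the closed-form likelihood-ratio sum on a hand table", {
  # counts [[30,10],[10,30]] laid out as x rows, t columns
  x <- rep(c(0, 0, 1, 1), times = c(30, 10, 10, 30))
  t <- rep(c(0, 1, 0, 1), times = c(30, 10, 10, 30))
  df <- data.frame(x = factor(x), t = factor(t))
  res <- g2_test(df, "x", "t")
  o <- c(30, 10, 10, 30)
  e <- outer(c(40, 40), c(40, 40)) / 80
  expected <- 2 * sum(o * log(o / as.vector(t(e))))
  expect_equal(res$statistic, expected, tolerance = 1e-12)
  expect_identical(res$dof, 1L)
  expect_true(res$reliable)
})

test_that("G2 detects perfect dependence and handles degenerate columns", {
  x <- factor(rep(0:1, 500))
  df <- data.frame(x = x, t = x)
  res <- g2_test(df, "x", "t")
  expect_lt(res$p_value, 1e-10)
  dg <- data.frame(x = factor(rep(0, 100), levels = "0"),
                   t = factor(rep(0:1, 50)))
  res2 <- g2_test(dg, "x", "t")
  expect_identical(res2$statistic, 0)
  expect_identical(res2$dof, 1L)
  expect_identical(res2$p_value, 1)
})

test_that("G2 and Fisher-z are type-I calibrated under independence", {
  rej_g2 <- withr::with_seed(101, {
    mean(replicate(300, {
      df <- data.frame(x = factor(sample(0:1, 500, TRUE)),
                       t = factor(sample(0:1, 500, TRUE)))
      g2_test(df, "x", "t")$p_value < 0.05
    }))
  })
  expect_gt(rej_g2, 0.05 - 3.5 * sqrt(0.05 * 0.95 / 300))
  expect_lt(rej_g2, 0.05 + 3.5 * sqrt(0.05 * 0.95 / 300))
  rej_fz <- withr::with_seed(202, {
    mean(replicate(300, {
      df <- data.frame(x = stats::rnorm(300), t = stats::rnorm(300))
      fisher_z_test(df, "x", "t")$p_value < 0.05
    }))
  })
  expect_gt(rej_fz, 0.05 - 3.5 * sqrt(0.05 * 0.95 / 300))
  expect_lt(rej_fz, 0.05 + 3.5 * sqrt(0.05 * 0.95 / 300))
})

test_that("Fisher-z handles perfect correlation and the conditional null", {
  df <- data.frame(x = stats::rnorm(100))
  df$t <- df$x
  res <- fisher_z_test(df, "x", "t")
  expect_lt(res$p_value, 1e-12)
  # x <- c -> t: given c the partial correlation is null; p-values uniform
  pvals <- withr::with_seed(33, {
    replicate(300, {
      c_ <- stats::rnorm(300)
      df <- data.frame(x = c_ + stats::rnorm(300),
                       t = 2 * c_ + stats::rnorm(300), c = c_)
      fisher_z_test(df, "x", "t", "c")$p_value
    })
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("power grows with sample size on a fixed dependent configuration", {
  rej <- vapply(c(50, 200, 800), function(n) {
    withr::with_seed(7, {
      mean(replicate(100, {
        a <- sample(0:1, n, TRUE)
        b <- ifelse(stats::runif(n) < 0.65, a, 1 - a)
        g2_test(data.frame(x = factor(a), t = factor(b)), "x", "t")$p_value < 0.05
      }))
    })
  }, numeric(1))
  expect_true(all(diff(rej) >= 0))
  expect_gt(rej[3], rej[1])
})

test_that("reliability heuristic flags sparse conditioning tables", {
  withr::with_seed(11, {
    df <- as.data.frame(lapply(1:5, function(i) factor(sample(0:2, 60, TRUE))))
    names(df) <- c("x", "t", "z1", "z2", "z3")
  })
  res <- g2_test(df, "x", "t", c("z1", "z2", "z3"))
  expect_false(res$reliable)  # 60 samples over 3*3*27 cells
  expect_true(g2_test(df, "x", "t")$reliable)
})

test_that("association ranking puts a true parent first and breaks ties by name", {
  f <- pathway_fixture()
  ds <- sample_bn(f$net, 2000, seed = 15)
  ds$noise <- factor(sample_bn(f$net, 2000, seed = 99)$C)
  rk <- rank_by_association(ds, "T", c("A", "noise"))
  expect_identical(rk$variable[1], "A")
  dup <- data.frame(b = ds$A, a = ds$A, T = ds$T)
  rk2 <- rank_by_association(dup, "T", c("b", "a"))
  expect_identical(rk2$variable, c("a", "b"))
  expect_equal(rk2$p_value[1], rk2$p_value[2])
  expect_error(rank_by_association(ds, "T", character(0)), "candidate")
})

test_that("accept/reject agrees with the exact oracle on sampled group data", {
  b <- mult22_fixture()
  ds <- sample_bn(b$net, 10000, seed = 21)
  oc <- oracle_ci(b$net)
  vars <- setdiff(names(ds), "T")
  configs <- list(
    list(x = "X1.1", z = character(0)),
    list(x = "X1.1", z = "X1.2"),
    list(x = "X1.2", z = c("X1.1", "X2.1")),
    list(x = "X2.1", z = "X1.1"),
    list(x = "N1", z = character(0)),
    list(x = "N1", z = c("X1.1", "X2.2")),
    list(x = "X2.2", z = c("X2.1")),
    list(x = "X1.1", z = c("X2.1", "X2.2"))
  )
  agree <- vapply(configs, function(cf) {
    truth_dep <- oc(cf$x, "T", cf$z)$p_value < 0.5
    test_dep <- g2_test(ds, cf$x, "T", cf$z)$p_value < 0.05
    truth_dep == test_dep
  }, logical(1))
  expect_gte(mean(agree), 7 / 8)
})
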