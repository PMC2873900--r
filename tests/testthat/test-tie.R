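test_that("removal subsets enumerate by size then lexicographically, without repeats", {
  st <- new_subset_state(c("A", "C"))
  expect_identical(generate_next_subset(st), "A")
  expect_identical(generate_next_subset(st), "C")
  expect_identical(generate_next_subset(st), c("A", "C"))
  expect_null(generate_next_subset(st))
})

test_that("dead-end pruning removes all supersets of a failed subset", {
  st <- new_subset_state(c("A", "C"))
  g1 <- generate_next_subset(st)   # {A}
  g2 <- generate_next_subset(st)   # {C}
  note_dead(st, g2)
  expect_null(generate_next_subset(st))  # {A,C} pruned as a superset of {C}
  # and with a grown universe, {C,X} is pruned too
  st2 <- new_subset_state(c("A", "C"))
  invisible(generate_next_subset(st2)); invisible(generate_next_subset(st2))
  note_dead(st2, "C")
  note_signature(st2, c("X", "A"))
  gen <- character(0)
  repeat {
    g <- generate_next_subset(st2)
    if (is.null(g)) break
    gen <- c(gen, paste(g, collapse = "+"))
  }
  expect_true("X" %in% gen)
  expect_true("A+X" %in% gen)
  expect_false(any(grepl("C", gen)))
})

test_that("newly discovered signatures enlarge the enumeration universe", {
  st <- new_subset_state("A")
  expect_identical(generate_next_subset(st), "A")
  expect_null(generate_next_subset(st))
  note_signature(st, "B")
  expect_identical(generate_next_subset(st), "B")
  expect_identical(generate_next_subset(st), c("A", "B"))
  expect_null(generate_next_subset(st))
})

test_that("equivalence accepts true boundary swaps and rejects information loss", {
  f <- pathway_fixture()
  ds <- sample_bn(f$net, 5000, seed = 12)
  cfg <- tie_config()
  expect_true(check_equivalence(ds, "T", c("A", "C"), c("A", "C"), cfg)$equivalent)
  expect_true(check_equivalence(ds, "T", c("B", "C"), c("A", "C"), cfg)$equivalent)
  chk <- check_equivalence(ds, "T", "C", c("A", "C"), cfg)
  expect_false(chk$equivalent)   # A carries information beyond C
  expect_false(check_equivalence(ds, "T", character(0), c("A", "C"), cfg)$equivalent)
  expect_true(check_equivalence(ds, "T", character(0), character(0), cfg)$equivalent)
})

test_that("TIE* on pathway-network samples returns both boundaries", {
  f <- pathway_fixture()
  ds <- sample_bn(f$net, 5000, seed = 1)
  res <- tie_star(ds, "T", make_base_inducer(), tie_config())
  expect_true(sets_equal(lapply(res$signatures, function(s) s$variables),
                         f$truth$markov_boundaries))
  expect_identical(res$terminated, "exhausted")
  # reference first, provenance recorded on the alternates
  expect_identical(res$signatures[[1]]$removed_subset, character(0))
  expect_gt(length(res$signatures[[2]]$removed_subset), 0)
})

test_that("an independent target yields a single empty reference signature", {
  df <- withr::with_seed(2, {
    d <- as.data.frame(lapply(1:6, function(i) factor(sample(0:1, 300, TRUE))))
    names(d) <- sprintf("V%d", 1:6)
    d$T <- factor(sample(0:1, 300, TRUE))
    d
  })
  res <- tie_star(df, "T", make_base_inducer(), tie_config())
  expect_identical(res$terminated, "exhausted")
  expect_identical(res$n_subsets_generated, 0L)
  expect_lte(length(res$signatures), 2)  # empty reference, rarely one fluke
})

test_that("the subset cap terminates runs with an explicit flag", {
  b <- mult22_fixture()
  ds <- sample_bn(b$net, 2000, seed = 4)
  res <- tie_star(ds, "T", make_base_inducer(), tie_config(max_subsets = 2))
  expect_identical(res$terminated, "capped")
  expect_identical(res$n_subsets_generated, 2L)
})

test_that("the non-reducible filter keeps exactly the minimal signatures", {
  sigs <- list(c("A", "B", "C"), c("A", "B", "X"), c("A", "B"))
  expect_identical(filter_non_reducible(sigs), list(c("A", "B")))
  one <- list(c("A", "B"))
  expect_identical(filter_non_reducible(one), one)
  disj <- list(c("A", "B"), c("C", "D"), c("E"))
  expect_identical(filter_non_reducible(disj), disj)
})

test_that("signature sets serialize to JSON and TSV with stable ordering", {
  b <- mult22_fixture()
  ds <- sample_bn(b$net, 2000, seed = 4)
  res <- tie_star(ds, "T", make_base_inducer(), tie_config())
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_signatures_json(res, jp)
  write_signatures_tsv(res, tp)
  back <- jsonlite::fromJSON(jp, simplifyVector = FALSE)
  expect_identical(length(back$signatures), length(res$signatures))
  expect_identical(unlist(back$signatures[[1]]$variables),
                   res$signatures[[1]]$variables)
  tab <- utils::read.table(tp, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_identical(nrow(tab), length(res$signatures))
  expect_identical(tab$variables[1],
                   paste(res$signatures[[1]]$variables, collapse = ","))
})
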