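# Shared fixtures, memoised so expensive simulations are built once per
# test run regardless of which test file asks first.
.fixtures <- new.env(parent = emptyenv())

fix_get <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

pathway_fixture <- function() fix_get("pathway", build_pathway_network)

# The 30-variable design: equivalence groups [1,3,3,2,2,2] (13 signal
# members, 72 boundaries) plus 17 independent noise variables, binary
# phenotype with 10% label noise.
mult30_fixture <- function() fix_get("mult30", function() {
  build_multiplicity_network(equivalence_group_spec(
    c(1, 3, 3, 2, 2, 2), n_noise_vars = 17L, target_noise = 0.1, seed = 1L))
})

mult30_data <- function() fix_get("mult30_data", function() {
  sample_bn(mult30_fixture()$net, 3000L, seed = 1L)
})

mult30_tie <- function() fix_get("mult30_tie", function() {
  tie_star(mult30_data(), "T", make_base_inducer(), tie_config())
})

# Small two-group fixture ([2,2]: 4 boundaries) kept within the exact
# oracle's reach.
mult22_fixture <- function() fix_get("mult22", function() {
  build_multiplicity_network(equivalence_group_spec(
    c(2, 2), n_noise_vars = 1L, target_noise = 0.1, seed = 3L))
})

# Three-group fixture ([2,2,2]: 8 boundaries) used for AUC-based checks.
mult222_fixture <- function() fix_get("mult222", function() {
  build_multiplicity_network(equivalence_group_spec(
    c(2, 2, 2), n_noise_vars = 4L, target_noise = 0.1, seed = 5L))
})

mult222_data <- function() fix_get("mult222_data", function() {
  sample_bn(mult222_fixture()$net, 3000L, seed = 9L)
})

mult222_estimates <- function() fix_get("mult222_est", function() {
  lapply(mult222_fixture()$truth$markov_boundaries, function(b)
    repeated_holdout_auc(mult222_data(), b, t = "T", n_splits = 10L, seed = 4L))
})

sig_sets <- function(x) {
  sigs <- if (inherits(x, "tie_result") || inherits(x, "baseline_result"))
    x$signatures else x
  tiestar:::canonical_boundary_list(lapply(sigs, function(s)
    if (inherits(s, "signature")) s$variables else s))
}

set_in <- function(s, sets) {
  any(vapply(sets, function(m) identical(sort(s), sort(m)), logical(1)))
}

sets_equal <- function(a, b) {
  identical(tiestar:::canonical_boundary_list(a),
            tiestar:::canonical_boundary_list(b))
}

# A random small discrete network for oracle-equivalence checks: either a
# random-CPT DAG over 5 observed variables or a small multiplicity design.
random_small_net <- function(seed) {
  withr::with_seed(seed, {
    if (stats::runif(1) < 0.5) {
      gs <- sample(list(c(2), c(3), c(2, 2), c(2, 3)), 1)[[1]]
      build_multiplicity_network(equivalence_group_spec(
        gs, n_noise_vars = sample(0:2, 1), target_noise = stats::runif(1, 0.05, 0.3),
        seed = sample.int(1e6, 1)))$net
    } else {
      vnames <- c("V1", "V2", "V3", "V4", "T")
      ord <- sample(vnames)
      cards <- stats::setNames(sample(2:3, 5, replace = TRUE), vnames)
      parents <- stats::setNames(vector("list", 5), vnames)
      for (i in seq_along(ord)) {
        if (i == 1) next
        prev <- ord[seq_len(i - 1)]
        pa <- prev[stats::runif(i - 1) < 0.45]
        # keep the target's boundary equal to its parent/child set: a child
        # of T gets no co-parents, so no spouse is marginally independent
        # of T — the assumption class of a univariate-screened inducer
        if ("T" %in% pa) pa <- "T"
        parents[[ord[i]]] <- pa
      }
      cpts <- lapply(vnames, function(v) {
        nr <- prod(c(1, cards[parents[[v]]]))
        m <- matrix(stats::rgamma(nr * cards[v], shape = 1.2), nrow = nr)
        m / rowSums(m)
      })
      names(cpts) <- vnames
      discrete_bn(cards, parents, cpts, target = "T")
    }
  })
}

# Exact AUC of the Bayes-optimal score P(T = 1 | signature variables),
# computed from the generative network: the reference any consistent
# classifier should approach.
bayes_auc_exact <- function(net, vars) {
  jt <- exact_joint(net, vars = c(vars, net$target))
  ti <- length(vars) + 1L
  cards <- apply(jt$config, 2L, max)
  key <- tiestar:::mix_key(jt$config[, seq_along(vars), drop = FALSE],
                           cards[seq_along(vars)])
  pos <- jt$config[, ti] == 2L
  p_x <- vapply(split(jt$p, key), sum, numeric(1))
  p_pos <- vapply(split(jt$p * pos, key), sum, numeric(1))
  score <- p_pos / p_x
  w_pos <- p_pos
  w_neg <- p_x - p_pos
  num <- 0
  for (i in seq_along(score)) {
    num <- num + w_pos[i] * sum(w_neg[score < score[i]]) +
      0.5 * w_pos[i] * sum(w_neg[score == score[i]])
  }
  num / (sum(w_pos) * sum(w_neg))
}
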