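#' The three-gene pathway network with two Markov boundaries
#'
#' Builds a concrete parameterization of the illustrative pathway class with
#' genes `A`, `B`, `C` and phenotype `T`: `A -> T`, `A -> B`, `T -> C`.
#' `A`, `B`, `T` are ternary, `C` is binary. `T` depends on `A` only through
#' the coarsening \{0,1\} vs \{2\}, and `B` encodes that coarsening exactly
#' while staying non-deterministically related to `A` (given `A` in \{0,1\},
#' `B` is uniform on \{0,1\}; given `A = 2`, `B = 2`). Consequently
#' `P(T = 0 | A = 1) != 0` while `P(T = 0 | A = 2) = 0`, and the distribution
#' has exactly two Markov boundaries of `T`: \{A, C\} and \{B, C\} — two
#' maximally predictive, non-redundant signatures that persist at any sample
#' size. The construction is verified against
#' [enumerate_markov_boundaries_exact()] before returning.
#'
#' @return a list with elements `net` (a [discrete_bn()]) and `truth` (a
#'   [ground_truth()] with `markov_boundaries = list(c("A","C"), c("B","C"))`
#'   and `local_pathway = c("A", "C")`).
#' @export
build_pathway_network <- function() {
  cards <- c(A = 3L, B = 3L, C = 2L, T = 3L)
  parents <- list(B = "A", T = "A", C = "T")
  # T | A: rows are A = 0, 1, 2; columns T = 0, 1, 2.
  t_given_a <- rbind(
    c(0.50, 0.30, 0.20),   # A = 0 (class 0)
    c(0.50, 0.30, 0.20),   # A = 1 (class 0): identical, T sees only the class
    c(0.00, 0.65, 0.35)    # A = 2 (class 1): T = 0 impossible
  )
  b_given_a <- rbind(
    c(0.5, 0.5, 0.0),      # A = 0: B uniform on {0, 1}
    c(0.5, 0.5, 0.0),      # A = 1
    c(0.0, 0.0, 1.0)       # A = 2: B = 2
  )
  c_given_t <- rbind(
    c(0.85, 0.15),         # T = 0
    c(0.50, 0.50),         # T = 1
    c(0.10, 0.90)          # T = 2
  )
  cpts <- list(
    A = matrix(c(0.35, 0.35, 0.30), nrow = 1),
    B = b_given_a, T = t_given_a, C = c_given_t
  )
  net <- discrete_bn(cards, parents, cpts, target = "T")
  truth <- ground_truth(list(c("A", "C"), c("B", "C")), local_pathway = c("A", "C"))
  found <- enumerate_markov_boundaries_exact(net)
  if (!identical(found, truth$markov_boundaries))
    stop("pathway network construction failed oracle validation")
  list(net = net, truth = truth)
}

#' Ground-truth Markov boundary set
#'
#' @param markov_boundaries list of character vectors (variable sets).
#' @param local_pathway character vector: variables directly upstream or
#'   downstream of the phenotype.
#' @return object of class `ground_truth` with canonically sorted boundaries
#'   (variables sorted by name within a boundary; boundaries sorted
#'   lexicographically).
#' @export
ground_truth <- function(markov_boundaries, local_pathway = character()) {
  mb <- canonical_boundary_list(markov_boundaries)
  for (i in seq_along(mb)) for (j in seq_along(mb)) {
    if (i != j && length(mb[[i]]) < length(mb[[j]]) && all(mb[[i]] %in% mb[[j]]))
      stop("boundary ", i, " is a proper subset of boundary ", j)
  }
  structure(list(markov_boundaries = mb, local_pathway = sort(local_pathway)),
            class = "ground_truth")
}

canonical_boundary_list <- function(sets) {
  sets <- lapply(sets, function(s) sort(as.character(s)))
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  sets <- sets[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  sets[order(keys)]
}

#' Specification of an equivalence-group (multiplicity) network
#'
#' Describes a generative design with a known, combinatorial set of Markov
#' boundaries. Each group `i` has a hidden source `S_i` taking
#' `classes_per_group` equally likely classes; each of the `group_sizes[i]`
#' observed members encodes the class of its source exactly through disjoint
#' symbol sets (one block of symbols per class) but is re-randomized within
#' the block independently of its siblings. The binary phenotype is a
#' majority vote over the class vector, flipped with probability
#' `target_noise`. Every selection of one member per group is then a Markov
#' boundary of the phenotype, so the network has `prod(group_sizes)` of them.
#'
#' @param group_sizes positive integers; number of observed members per group.
#' @param classes_per_group classes of each hidden source (>= 2; default 2).
#' @param values_per_member cardinality of each observed member
#'   (>= `classes_per_group`; default 3, which makes sibling members
#'   non-deterministically related).
#' @param n_noise_vars observed variables independent of everything else.
#' @param target_noise phenotype flip probability, in (0, 0.5).
#' @param seed integer; randomizes the noise-variable marginals.
#' @param max_boundaries overflow guard on `prod(group_sizes)`.
#' @return object of class `eq_group_spec`.
#' @export
equivalence_group_spec <- function(group_sizes, classes_per_group = 2L,
                                   values_per_member = 3L, n_noise_vars = 0L,
                                   target_noise = 0.1, seed = 1L,
                                   max_boundaries = 1e6) {
  stopifnot(length(group_sizes) >= 1, all(group_sizes >= 1),
            classes_per_group >= 2, values_per_member >= classes_per_group,
            n_noise_vars >= 0, target_noise > 0, target_noise < 0.5)
  if (prod(group_sizes) > max_boundaries)
    stop("prod(group_sizes) = ", prod(group_sizes),
         " exceeds the boundary cap (", max_boundaries, ")")
  structure(list(group_sizes = as.integer(group_sizes),
                 classes_per_group = as.integer(classes_per_group),
                 values_per_member = as.integer(values_per_member),
                 n_noise_vars = as.integer(n_noise_vars),
                 target_noise = target_noise, seed = as.integer(seed)),
            class = "eq_group_spec")
}

# Symbol blocks per class: values 0..v-1 split into c contiguous blocks,
# larger blocks first, so at least one class is non-degenerate whenever v > c.
class_blocks <- function(v, c) {
  sizes <- rep(v %/% c, c)
  extra <- v %% c
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(c), function(i) (starts[i]:ends[i]) - 1L)
}

#' Build an equivalence-group network with a known boundary set
#'
#' Constructs the [discrete_bn()] described by an [equivalence_group_spec()].
#' Hidden sources are tagged latent and never appear in sampled datasets;
#' the ground truth lists every one-member-per-group selection as a Markov
#' boundary (`prod(group_sizes)` in total).
#'
#' @param spec an [equivalence_group_spec()].
#' @return a list with elements `net` (a `discrete_bn`) and `truth`
#'   (a [ground_truth()]).
#' @export
build_multiplicity_network <- function(spec) {
  stopifnot(inherits(spec, "eq_group_spec"))
  k <- length(spec$group_sizes)
  c_ <- spec$classes_per_group
  v <- spec$values_per_member
  src <- sprintf("S%d", seq_len(k))
  members <- list()
  cards <- stats::setNames(rep(c_, k), src)
  parents <- list()
  cpts <- stats::setNames(lapply(src, function(s) matrix(1 / c_, nrow = 1, ncol = c_)), src)
  blocks <- class_blocks(v, c_)
  member_cpt <- matrix(0, nrow = c_, ncol = v)
  for (cl in seq_len(c_)) member_cpt[cl, blocks[[cl]] + 1L] <- 1 / length(blocks[[cl]])
  for (i in seq_len(k)) {
    for (j in seq_len(spec$group_sizes[i])) {
      nm <- sprintf("X%d.%d", i, j)
      members[[length(members) + 1L]] <- nm
      cards[nm] <- v
      parents[[nm]] <- src[i]
      cpts[[nm]] <- member_cpt
    }
  }
  # Phenotype: majority vote over the class vector (class index >= 2 counts
  # as a "1"-side class for c_ = 2; in general the vote is over class-1
  # indicators), flipped with probability target_noise.
  thr <- ceiling(k / 2)
  nconf <- c_^k
  t_cpt <- matrix(0, nrow = nconf, ncol = 2)
  conf <- arrayInd(seq_len(nconf), .dim = rep(c_, k))  # first source fastest
  votes <- rowSums(conf >= 2L)
  hi <- votes >= thr
  t_cpt[, 2] <- ifelse(hi, 1 - spec$target_noise, spec$target_noise)
  t_cpt[, 1] <- 1 - t_cpt[, 2]
  cards["T"] <- 2L
  parents[["T"]] <- src
  cpts[["T"]] <- t_cpt
  if (spec$n_noise_vars > 0) {
    width <- nchar(as.character(spec$n_noise_vars))
    noise_probs <- withr::with_seed(spec$seed, {
      lapply(seq_len(spec$n_noise_vars), function(i) {
        p <- stats::rgamma(v, shape = 5); p / sum(p)
      })
    })
    for (i in seq_len(spec$n_noise_vars)) {
      nm <- sprintf("N%0*d", width, i)
      cards[nm] <- v
      cpts[[nm]] <- matrix(noise_probs[[i]], nrow = 1)
    }
  }
  net <- discrete_bn(cards, parents, cpts, target = "T", latent = src)
  sel <- lapply(seq_len(k), function(i) sprintf("X%d.%d", i, seq_len(spec$group_sizes[i])))
  grid <- expand.grid(sel, stringsAsFactors = FALSE)
  mbs <- lapply(seq_len(nrow(grid)), function(r) unlist(grid[r, ], use.names = FALSE))
  truth <- ground_truth(mbs, local_pathway = sort(unlist(sel)))
  list(net = net, truth = truth)
}
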