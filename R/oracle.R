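#' Exact joint distribution of a discrete Bayesian network
#'
#' Enumerates the full joint distribution by multiplying CPT entries along a
#' topological order, then (optionally) marginalizes onto a subset of
#' variables. Latent variables are summed out like any other when absent from
#' `vars`. Enumeration is refused, with an explicit infeasibility error, when
#' the configuration count exceeds `cap` — there is no silent approximation.
#'
#' @param net a [discrete_bn()].
#' @param vars variables to keep (default: all observed variables plus the
#'   target); use `names(net$variables)` for the full joint.
#' @param cap maximum number of joint configurations (default 1e6).
#' @return a list with `vars` (column names), `config` (integer matrix of
#'   1-based level indices, one row per configuration) and `p` (probability
#'   vector summing to 1).
#' @export
exact_joint <- function(net, vars = NULL, cap = 1e6) {
  if (is.null(vars)) vars <- union(observed_vars(net), net$target)
  stopifnot(all(vars %in% names(net$variables)))
  conf <- matrix(integer(0), nrow = 1, ncol = 0)
  p <- 1
  kept <- character(0)
  for (v in net$order) {
    k <- net$variables[[v]]
    m <- nrow(conf)
    if (as.double(m) * k > cap)
      stop("joint state space exceeds the enumeration cap (", cap, " configurations)")
    pa <- net$parents[[v]]
    rows <- if (length(pa) == 0L) rep.int(1L, m) else
      cpt_row_index(conf[, match(pa, kept), drop = FALSE], net$variables[pa])
    cpt <- net$cpts[[v]]
    conf <- cbind(conf[rep.int(seq_len(m), k), , drop = FALSE],
                  rep(seq_len(k), each = m))
    p <- rep.int(p, k) * cpt[cbind(rep.int(rows, k), rep(seq_len(k), each = m))]
    kept <- c(kept, v)
    # Sum out variables that are neither requested nor parents of a
    # yet-unprocessed variable: keeps the working table small.
    pending <- setdiff(net$order, kept)
    needed <- union(vars, unlist(net$parents[pending]))
    drop <- setdiff(kept, needed)
    if (length(drop)) {
      keep_idx <- match(setdiff(kept, drop), kept)
      agg <- marginalize_table(conf, p, keep_idx)
      conf <- agg$config; p <- agg$p; kept <- kept[keep_idx]
    }
  }
  idx <- match(vars, kept)
  agg <- marginalize_table(conf, p, idx)
  list(vars = vars, config = agg$config, p = agg$p)
}

# Aggregate a (config, p) table onto a subset of its columns.
marginalize_table <- function(conf, p, cols) {
  sub <- conf[, cols, drop = FALSE]
  if (ncol(sub) == 0L)
    return(list(config = matrix(integer(0), nrow = 1, ncol = 0), p = sum(p)))
  cards <- apply(sub, 2L, max)
  key <- mix_key(sub, cards)
  agg <- rowsum(p, group = key, reorder = TRUE)
  keys <- as.numeric(rownames(agg))
  list(config = key_to_config(keys, cards), p = as.vector(agg))
}

mix_key <- function(m, cards) {
  if (ncol(m) == 0L) return(rep.int(1, nrow(m)))
  mult <- cumprod(c(1, cards[-length(cards)]))
  as.vector((m - 1) %*% mult) + 1
}

key_to_config <- function(keys, cards) {
  k <- keys - 1
  out <- matrix(0L, nrow = length(keys), ncol = length(cards))
  for (j in seq_along(cards)) {
    out[, j] <- as.integer(k %% cards[j]) + 1L
    k <- k %/% cards[j]
  }
  out
}

# Conditional mutual information I(xs; ys | zs) in nats from a joint table.
cmi_from_table <- function(conf, p, xi, yi, zi) {
  keep <- p > 0
  conf <- conf[keep, , drop = FALSE]; p <- p[keep]
  cards <- apply(conf, 2L, max)
  key_of <- function(cols) if (length(cols) == 0L) rep.int(1, nrow(conf)) else
    mix_key(conf[, cols, drop = FALSE], cards[cols])
  kz <- key_of(zi); kxz <- key_of(c(xi, zi)); kyz <- key_of(c(yi, zi))
  pz <- rowsum(p, kz); pxz <- rowsum(p, kxz); pyz <- rowsum(p, kyz)
  pz_i <- pz[match(kz, as.numeric(rownames(pz)))]
  pxz_i <- pxz[match(kxz, as.numeric(rownames(pxz)))]
  pyz_i <- pyz[match(kyz, as.numeric(rownames(pyz)))]
  max(0, sum(p * log(p * pz_i / (pxz_i * pyz_i))))
}

#' Exact conditional mutual information in a network
#'
#' Computes I(xs; ys | zs) in nats from the exact joint distribution of the
#' network. Symmetric in `xs`/`ys` and nonnegative; equals 0 exactly when the
#' two sets are conditionally independent given `zs`.
#'
#' @param net a [discrete_bn()].
#' @param xs,ys,zs character vectors of variable names (`zs` may be empty).
#' @param cap enumeration cap, as in [exact_joint()].
#' @return nonnegative scalar (nats).
#' @export
conditional_mutual_information_exact <- function(net, xs, ys, zs = character(), cap = 1e6) {
  xs <- sort(unique(as.character(xs))); ys <- sort(unique(as.character(ys)))
  zs <- sort(unique(as.character(zs)))
  if (length(intersect(xs, ys)) || length(intersect(xs, zs)) || length(intersect(ys, zs)))
    stop("xs, ys, zs must be pairwise disjoint")
  vars <- c(xs, ys, zs)
  jt <- exact_joint(net, vars = vars, cap = cap)
  cmi_from_table(jt$config, jt$p, match(xs, vars), match(ys, vars), match(zs, vars))
}

#' Enumerate all Markov boundaries of the target, exactly
#'
#' Exhaustively searches subsets `S` of the observed non-target variables
#' (up to `max_size`) and returns those that are Markov blankets of the
#' target — exact I(T; rest | S) below `tol` — and minimal, i.e. no proper
#' subset is itself a blanket. When the target is independent of every
#' observed variable the unique boundary is the empty set.
#'
#' @param net a [discrete_bn()].
#' @param target target variable (default `net$target`).
#' @param max_size largest subset size searched (default: all).
#' @param tol independence tolerance on conditional mutual information, nats.
#' @param cap enumeration cap on the observed joint, as in [exact_joint()].
#' @return list of character vectors, canonically sorted (members by name,
#'   boundaries lexicographically).
#' @export
enumerate_markov_boundaries_exact <- function(net, target = net$target,
                                              max_size = Inf, tol = 1e-9,
                                              cap = 1e6) {
  w <- sort(setdiff(observed_vars(net), target))
  vars <- c(w, target)
  jt <- exact_joint(net, vars = vars, cap = cap)
  ti <- length(vars)
  max_size <- min(max_size, length(w))
  blankets <- list()
  for (s in 0:max_size) {
    combos <- if (s == 0L) list(integer(0)) else
      utils::combn(seq_along(w), s, simplify = FALSE)
    for (idx in combos) {
      rest <- setdiff(seq_along(w), idx)
      i_val <- if (length(rest) == 0L) 0 else
        cmi_from_table(jt$config, jt$p, ti, rest, idx)
      if (i_val < tol) blankets[[length(blankets) + 1L]] <- w[idx]
    }
  }
  minimal <- Filter(function(b) {
    !any(vapply(blankets, function(o)
      length(o) < length(b) && all(o %in% b), logical(1)))
  }, blankets)
  canonical_boundary_list(minimal)
}

#' Exact conditional-independence answers from a network
#'
#' Returns a conditional-independence "test" backed by the exact joint
#' distribution of `net` instead of data: p-value 1 when the conditional
#' mutual information is below `tol`, 0 otherwise, always reliable. Plugging
#' it into [hiton_pc()] or [tie_star()] separates algorithmic correctness
#' from finite-sample test error.
#'
#' @param net a [discrete_bn()].
#' @param tol independence tolerance (nats).
#' @param cap enumeration cap.
#' @return a function `(x, t, cond)` returning a [ci_result()].
#' @export
oracle_ci <- function(net, tol = 1e-9, cap = 1e6) {
  vars <- union(observed_vars(net), net$target)
  jt <- exact_joint(net, vars = vars, cap = cap)
  function(x, t, cond = character()) {
    xi <- match(x, vars); ti <- match(t, vars); zi <- match(cond, vars)
    if (anyNA(c(xi, ti, zi))) stop("unknown variable in oracle CI query")
    cols <- c(xi, ti, zi)
    sub <- marginalize_table(jt$config, jt$p, cols)
    i_val <- cmi_from_table(sub$config, sub$p, seq_along(xi),
                            seq_along(ti) + length(xi),
                            seq_along(zi) + length(xi) + length(ti))
    ci_result(statistic = i_val, dof = 1L,
              p_value = if (i_val < tol) 1 else 0, reliable = TRUE)
  }
}
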