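#' Base inducer configuration
#'
#' Parameters of the local Markov boundary induction algorithm ([hiton_pc()])
#' that [tie_star()] and the baselines call.
#'
#' @param alpha significance level for the conditional-independence tests,
#'   in (0, 1); default 0.05.
#' @param max_k maximum conditioning-set size in the elimination and backward
#'   phases (>= 0); default 3. `max_k = 0` degenerates to univariate
#'   filtering.
#' @param h reliability heuristic: minimum average samples per contingency
#'   cell for a test to count (default 5). Unreliable tests are treated as
#'   "dependence not established".
#' @param test_kind `"discrete"` (G2) or `"continuous"` (Fisher-z); chosen
#'   once per dataset from the declared column kinds, not guessed per call.
#' @return object of class `base_inducer_config`.
#' @export
base_inducer_config <- function(alpha = 0.05, max_k = 3L, h = 5,
                                test_kind = c("discrete", "continuous")) {
  stopifnot(alpha > 0, alpha < 1, max_k >= 0)
  structure(list(alpha = alpha, max_k = as.integer(max_k), h = h,
                 test_kind = match.arg(test_kind)),
            class = "base_inducer_config")
}

#' A molecular signature (variable set with provenance)
#'
#' @param variables character vector; stored sorted by name.
#' @param removed_subset variables withheld from the data when this signature
#'   was induced (empty for a reference signature). Must be disjoint from
#'   `variables`.
#' @param predictivity optional predictivity estimate record.
#' @return object of class `signature`.
#' @export
signature <- function(variables, removed_subset = character(),
                      predictivity = NULL) {
  variables <- sort(unique(as.character(variables)))
  removed_subset <- sort(unique(as.character(removed_subset)))
  if (length(intersect(variables, removed_subset)))
    stop("a signature cannot contain variables from its removed subset")
  structure(list(variables = variables, removed_subset = removed_subset,
                 predictivity = predictivity),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat("{", paste(x$variables, collapse = ", "), "}",
      if (length(x$removed_subset))
        paste0("  [found with {", paste(x$removed_subset, collapse = ", "), "} removed]"),
      "\n", sep = "")
  invisible(x)
}

sig_vars <- function(s) if (inherits(s, "signature")) s$variables else sort(unique(as.character(s)))
set_key <- function(vars) paste0("k:", paste(sort(vars), collapse = "\r"))

# Subsets of `pool` with size <= max_k, in increasing cardinality then
# lexicographic order (pool is assumed name-sorted). Optionally only subsets
# containing `must_include`.
k_subsets <- function(pool, max_k, must_include = NULL) {
  out <- list()
  if (!is.null(must_include)) {
    if (max_k < 1L) return(out)
    rest <- setdiff(pool, must_include)
    for (s in 0:min(max_k - 1L, length(rest))) {
      combos <- if (s == 0L) list(character(0)) else
        utils::combn(rest, s, simplify = FALSE)
      for (cmb in combos) out[[length(out) + 1L]] <- sort(c(must_include, cmb))
    }
  } else {
    for (s in 0:min(max_k, length(pool))) {
      combos <- if (s == 0L) list(character(0)) else
        utils::combn(pool, s, simplify = FALSE)
      out <- c(out, combos)
    }
  }
  out
}

# A ci function over a context: (x, t, cond) -> ci_result, where arguments
# are variable names.
ctx_ci_fun <- function(ctx, h) {
  function(x, t, cond = character()) {
    g2_ctx(ctx, match(x, ctx$vars), match(t, ctx$vars),
           match(cond, ctx$vars), h = h)
  }
}

# TRUE when the test gives positive evidence of independence: a reliable
# non-rejection. Unreliable tests establish nothing in either direction
# during elimination.
indep_established <- function(res, alpha) res$reliable && res$p_value >= alpha

# Is `x` separable from t by some subset of `others` (sizes <= max_k)?
separable <- function(x, t, others, ci, alpha, max_k) {
  for (z in k_subsets(others, max_k))
    if (indep_established(ci(x, t, z), alpha)) return(TRUE)
  FALSE
}

#' HITON-PC: induce one Markov boundary signature
#'
#' Semi-interleaved local discovery of a maximally predictive, non-redundant
#' signature (a Markov boundary under the algorithm's assumptions):
#' candidates unconditionally dependent on the target at `alpha` are admitted
#' in order of association strength; after each admission every tentative
#' member is dropped if some conditioning subset of the other members (size
#' at most `max_k`) renders it independent of the target; a final backward
#' pass re-checks every member against subsets of the final set. Eliminated
#' candidates are discarded permanently. All tie-breaks are by ascending
#' variable name, so the output is deterministic given
#' `(data, config, excluded)`.
#'
#' @param data a data frame of factor (discrete) or numeric (continuous)
#'   predictors with the target column present.
#' @param t target column name.
#' @param config a [base_inducer_config()].
#' @param excluded variables withheld from consideration (must not contain
#'   `t`).
#' @param ci optional conditional-independence function
#'   `(x, t, cond) -> ci_result`, e.g. [oracle_ci()]; when `NULL`, the test
#'   named by `config$test_kind` runs on `data`.
#' @return a [signature()] with `removed_subset = excluded`. With no
#'   admissible candidate the signature is empty (a valid result).
#' @export
hiton_pc <- function(data, t, config = base_inducer_config(),
                     excluded = character(), ci = NULL) {
  if (!t %in% names(data)) stop("dataset has no target column '", t, "'")
  if (t %in% excluded) stop("cannot exclude the target")
  ranked <- hiton_rank(data, t, config, ci)
  if (is.null(ci)) {
    if (config$test_kind == "discrete") {
      ci <- ctx_ci_fun(ci_context(data, c(t, sort(setdiff(names(data), t)))), config$h)
    } else {
      ci <- function(x, tt, cond = character()) fisher_z_test(data, x, tt, cond)
    }
  }
  hiton_pc_ranked(data, t, config, excluded, ci, ranked)
}

# Univariate ranking used for admission order; factored out so that
# make_base_inducer can cache it across repeated calls on the same dataset.
hiton_rank <- function(data, t, config, ci = NULL) {
  candidates <- sort(setdiff(names(data), t))
  if (length(candidates) == 0L)
    return(data.frame(variable = character(0), p_value = numeric(0),
                      statistic = numeric(0), reliable = logical(0)))
  if (!is.null(ci)) {
    res <- lapply(candidates, function(v) ci(v, t, character()))
    out <- data.frame(
      variable = candidates,
      p_value = vapply(res, function(r) r$p_value, numeric(1)),
      statistic = vapply(res, function(r) r$statistic, numeric(1)),
      reliable = vapply(res, function(r) r$reliable, logical(1)),
      stringsAsFactors = FALSE
    )
    return(out[order(out$p_value, -out$statistic, out$variable), , drop = FALSE])
  }
  if (config$test_kind == "continuous") {
    rank_by_association(data, t, candidates, h = config$h)
  } else {
    ctx <- ci_context(data, c(t, candidates))
    ti <- 1L
    res <- lapply(seq_along(candidates) + 1L, function(i) g2_ctx(ctx, i, ti, h = config$h))
    out <- data.frame(
      variable = candidates,
      p_value = vapply(res, function(r) r$p_value, numeric(1)),
      statistic = vapply(res, function(r) r$statistic, numeric(1)),
      reliable = vapply(res, function(r) r$reliable, logical(1)),
      stringsAsFactors = FALSE
    )
    out[order(out$p_value, -out$statistic, out$variable), , drop = FALSE]
  }
}

#' Create a reusable base-inducer handle
#'
#' Wraps [hiton_pc()] into the callable contract `(data, t, excluded)`
#' expected by [tie_star()] and the baseline extractors. The handle memoizes
#' the univariate association ranking and the integer-coded test context per
#' dataset (exclusions do not change univariate associations), which acts as
#' the univariate pre-filter that keeps repeated invocations on
#' high-dimensional data cheap.
#'
#' @param config a [base_inducer_config()].
#' @param ci optional CI function as in [hiton_pc()].
#' @return a function `(data, t, excluded = character())` returning a
#'   [signature()]. Handles built from identical configs give identical
#'   outputs on identical inputs.
#' @export
make_base_inducer <- function(config = base_inducer_config(), ci = NULL) {
  stopifnot(inherits(config, "base_inducer_config"))
  cache <- new.env(parent = emptyenv())
  function(data, t, excluded = character()) {
    key_ok <- !is.null(cache$data) && identical(cache$data, data) &&
      identical(cache$t, t)
    if (!key_ok) {
      cache$data <- data
      cache$t <- t
      cache$rank <- hiton_rank(data, t, config, ci)
      cache$ci <- if (!is.null(ci)) ci else if (config$test_kind == "discrete")
        ctx_ci_fun(ci_context(data, c(t, sort(setdiff(names(data), t)))), config$h)
      else
        function(x, tt, cond = character()) fisher_z_test(data, x, tt, cond)
    }
    hiton_pc_ranked(data, t, config, excluded, cache$ci, cache$rank)
  }
}

# hiton_pc with precomputed ranking and ci function (internal fast path).
hiton_pc_ranked <- function(data, t, config, excluded, ci, ranked) {
  if (t %in% excluded) stop("cannot exclude the target")
  ranked <- ranked[!ranked$variable %in% excluded &
                   ranked$reliable & ranked$p_value < config$alpha, , drop = FALSE]
  tpc <- character(0)
  for (x in ranked$variable) {
    if (separable(x, t, tpc, ci, config$alpha, config$max_k)) next
    tpc_new <- sort(c(tpc, x))
    for (y in tpc) {
      if (!y %in% tpc_new) next
      others <- setdiff(tpc_new, y)
      for (z in k_subsets(others, config$max_k, must_include = x)) {
        if (indep_established(ci(y, t, z), config$alpha)) {
          tpc_new <- setdiff(tpc_new, y)
          break
        }
      }
    }
    tpc <- tpc_new
  }
  for (y in tpc) {
    if (separable(y, t, setdiff(tpc, y), ci, config$alpha, config$max_k))
      tpc <- setdiff(tpc, y)
  }
  signature(tpc, removed_subset = excluded)
}
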