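#' TIE* run configuration
#'
#' @param equivalence_criterion `"independence"` (default; conditional
#'   independence of the reference remainder given the new signature) or
#'   `"predictivity"` (Wilcoxon comparison of repeated-holdout AUC samples).
#' @param alpha_equiv significance level of the equivalence check.
#' @param max_subsets cap on generated removal subsets; runs hitting it are
#'   flagged `terminated = "capped"`.
#' @param classifier_spec a [classifier_spec()] for the predictivity
#'   criterion.
#' @param n_eval_splits repeated-holdout count for the predictivity
#'   criterion.
#' @param test_fraction held-out fraction per split.
#' @param seed integer seed for evaluation splits.
#' @param max_k,h conditioning-size bound and reliability heuristic for the
#'   independence criterion (same meaning as in [base_inducer_config()]).
#' @return object of class `tie_config`.
#' @export
tie_config <- function(equivalence_criterion = c("independence", "predictivity"),
                       alpha_equiv = 0.05, max_subsets = 1e5,
                       classifier_spec = NULL,
                       n_eval_splits = 10L, test_fraction = 0.3, seed = 1L,
                       max_k = 3L, h = 5) {
  stopifnot(alpha_equiv > 0, alpha_equiv < 1, max_subsets >= 1)
  if (is.null(classifier_spec)) classifier_spec <- classifier_spec()
  structure(list(equivalence_criterion = match.arg(equivalence_criterion),
                 alpha_equiv = alpha_equiv, max_subsets = max_subsets,
                 classifier_spec = classifier_spec,
                 n_eval_splits = as.integer(n_eval_splits),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 max_k = as.integer(max_k), h = h),
            class = "tie_config")
}

#' Removal-subset generator state
#'
#' TIE* explores the lattice of variable subsets to withhold from the data.
#' The generator enumerates nonempty subsets of the union of all variables
#' appearing in signatures discovered so far, in order of increasing
#' cardinality then lexicographic within a cardinality; it never repeats a
#' subset, prunes any subset containing a previously generated subset whose
#' removal produced a non-equivalent signature (dead-end pruning), and
#' enlarges its universe on the fly as new signatures are discovered.
#'
#' @param reference_vars variables of the reference signature.
#' @return a state environment for [generate_next_subset()].
#' @export
new_subset_state <- function(reference_vars) {
  st <- new.env(parent = emptyenv())
  st$universe <- sort(unique(as.character(reference_vars)))
  st$generated <- new.env(parent = emptyenv())
  st$dead <- list()
  st$cur_size <- 0L
  st$cur_list <- NULL
  st$cur_idx <- 1L
  st
}

#' @rdname new_subset_state
#' @param state a state created by [new_subset_state()].
#' @return `generate_next_subset`: the next removal subset (character
#'   vector), or `NULL` when the lattice is exhausted.
#' @export
generate_next_subset <- function(state) {
  repeat {
    if (is.null(state$cur_list) || state$cur_idx > length(state$cur_list)) {
      state$cur_size <- state$cur_size + 1L
      if (state$cur_size > length(state$universe)) return(NULL)
      state$cur_list <- utils::combn(state$universe, state$cur_size,
                                     simplify = FALSE)
      state$cur_idx <- 1L
    }
    g <- state$cur_list[[state$cur_idx]]
    state$cur_idx <- state$cur_idx + 1L
    key <- set_key(g)
    if (!is.null(state$generated[[key]])) next
    state$generated[[key]] <- TRUE
    if (superset_of_dead(state, g)) next
    return(g)
  }
}

superset_of_dead <- function(state, g) {
  for (d in state$dead) if (all(d %in% g)) return(TRUE)
  FALSE
}

#' @rdname new_subset_state
#' @param vars variables of a newly accepted signature; any not yet in the
#'   universe enlarge it and restart enumeration at cardinality 1 (already
#'   generated subsets are remembered and skipped).
#' @export
note_signature <- function(state, vars) {
  new_vars <- setdiff(vars, state$universe)
  if (length(new_vars)) {
    state$universe <- sort(c(state$universe, new_vars))
    state$cur_size <- 0L
    state$cur_list <- NULL
  }
  invisible(state)
}

#' @rdname new_subset_state
#' @param g a generated subset whose removal produced a non-equivalent
#'   signature; all supersets of it are pruned from future generation.
#' @export
note_dead <- function(state, g) {
  state$dead[[length(state$dead) + 1L]] <- g
  invisible(state)
}

# Positive screening: is x independent of t given the discovered signature,
# judged from reliable tests only? Conditioning sets are the subsets of
# `blanket` up to max_k plus the full blanket itself (the latter matters for
# exact-oracle CI, where every test is reliable). With no reliable test at
# all, dependence is not established and x counts as screened off.
screened_off <- function(x, t, blanket, ci, alpha, max_k) {
  zs <- k_subsets(blanket, max_k)
  if (length(blanket) > max_k) zs <- c(zs, list(blanket))
  saw_reliable <- FALSE
  for (z in zs) {
    res <- ci(x, t, z)
    if (res$reliable) {
      saw_reliable <- TRUE
      if (res$p_value >= alpha) return(TRUE)
    }
  }
  !saw_reliable
}

#' Check predictive equivalence of a new signature against the reference
#'
#' Criterion `"independence"`: the new signature is equivalent when every
#' reference variable absent from it is screened off from the target by the
#' new signature — judged by reliable conditional-independence tests with
#' conditioning sets drawn from the new signature (subsets up to `max_k`,
#' plus the whole signature where that test is reliable) at `alpha_equiv`.
#' Criterion `"predictivity"`: repeated-holdout AUC samples of the two
#' signatures are compared by a two-sided Wilcoxon rank-sum test; equivalent
#' when the test does not reject at `alpha_equiv` and the new signature's
#' mean AUC is not more than 0.05 below the reference's.
#'
#' @param data the dataset both signatures were induced from.
#' @param t target column name.
#' @param m_new,m_ref [signature()]s (or character vectors). An empty
#'   `m_new` with a nonempty `m_ref` is rejected outright.
#' @param config a [tie_config()].
#' @param ci optional CI function (e.g. [oracle_ci()]) for the independence
#'   criterion.
#' @return a list with `equivalent` (logical) and `reason` (character).
#' @export
check_equivalence <- function(data, t, m_new, m_ref, config = tie_config(),
                              ci = NULL) {
  vn <- sig_vars(m_new); vr <- sig_vars(m_ref)
  if (length(vn) == 0L && length(vr) == 0L)
    return(list(equivalent = TRUE, reason = "both signatures empty"))
  if (length(vn) == 0L)
    return(list(equivalent = FALSE, reason = "empty signature against nonempty reference"))
  if (identical(vn, vr))
    return(list(equivalent = TRUE, reason = "identical variable sets"))
  if (config$equivalence_criterion == "independence") {
    if (is.null(ci))
      ci <- if (is.factor(data[[t]]))
        ctx_ci_fun(ci_context(data, unique(c(t, vr, vn))), config$h)
      else
        function(x, tt, cond = character()) fisher_z_test(data, x, tt, cond)
    for (x in setdiff(vr, vn)) {
      if (!screened_off(x, t, vn, ci, config$alpha_equiv, config$max_k))
        return(list(equivalent = FALSE,
                    reason = paste0("'", x, "' stays dependent on '", t,
                                    "' given the new signature")))
    }
    list(equivalent = TRUE, reason = "reference remainder screened off")
  } else {
    est_new <- repeated_holdout_auc(data, vn, t = t,
                                    classifier_spec = config$classifier_spec,
                                    n_splits = config$n_eval_splits,
                                    test_fraction = config$test_fraction,
                                    seed = config$seed)
    est_ref <- repeated_holdout_auc(data, vr, t = t,
                                    classifier_spec = config$classifier_spec,
                                    n_splits = config$n_eval_splits,
                                    test_fraction = config$test_fraction,
                                    seed = config$seed)
    p <- wilcoxon_rank_sum(est_new$per_split_auc, est_ref$per_split_auc)
    diff <- est_new$mean_auc - est_ref$mean_auc
    ok <- p >= config$alpha_equiv && diff > -0.05
    list(equivalent = ok,
         reason = sprintf("Wilcoxon p = %.3g, mean AUC difference = %.3f", p, diff))
  }
}

#' TIE*: extract all maximally predictive, non-redundant signatures
#'
#' Runs the base Markov boundary inducer on the full data to obtain a
#' reference signature, then repeatedly re-runs it on views of the data with
#' subsets of already-discovered signature variables withheld (see
#' [new_subset_state()] for the generation order and pruning). Each new
#' signature passing the equivalence check (see [check_equivalence()])
#' against the reference is emitted; removal subsets whose signature fails
#' the check are dead-ends whose supersets are never generated. Terminates
#' when the subset lattice is exhausted or `max_subsets` is hit.
#'
#' @param data a data frame with the target column.
#' @param t target column name.
#' @param base_inducer a handle from [make_base_inducer()], or any function
#'   `(data, t, excluded)` returning a [signature()].
#' @param config a [tie_config()].
#' @param ci optional CI function for the equivalence check (e.g.
#'   [oracle_ci()]).
#' @return object of class `tie_result`: `signatures` (reference first, then
#'   discovery order; pairwise distinct as variable sets), `rejected` (list
#'   of removal subset + reason), `terminated` (`"exhausted"` or
#'   `"capped"`), `n_subsets_generated`.
#' @export
tie_star <- function(data, t, base_inducer = make_base_inducer(),
                     config = tie_config(), ci = NULL) {
  if (!t %in% names(data)) stop("dataset has no target column '", t, "'")
  ref <- base_inducer(data, t, character())
  sigs <- list(ref)
  seen <- new.env(parent = emptyenv())
  seen[[set_key(ref$variables)]] <- TRUE
  rejected <- list()
  n_gen <- 0L
  terminated <- "exhausted"
  if (length(ref$variables) > 0L) {
    state <- new_subset_state(ref$variables)
    repeat {
      if (n_gen >= config$max_subsets) { terminated <- "capped"; break }
      g <- generate_next_subset(state)
      if (is.null(g)) break
      n_gen <- n_gen + 1L
      m_new <- base_inducer(data, t, g)
      chk <- check_equivalence(data, t, m_new, ref, config, ci = ci)
      if (chk$equivalent) {
        key <- set_key(m_new$variables)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          sigs[[length(sigs) + 1L]] <- signature(m_new$variables, removed_subset = g)
        }
        note_signature(state, m_new$variables)
      } else {
        note_dead(state, g)
        rejected[[length(rejected) + 1L]] <-
          list(removed_subset = g, reason = chk$reason)
      }
    }
  }
  structure(list(signatures = sigs, rejected = rejected,
                 terminated = terminated, n_subsets_generated = n_gen,
                 target = t),
            class = "tie_result")
}

#' @export
print.tie_result <- function(x, ...) {
  cat("TIE* run: ", length(x$signatures), " signature(s) of '", x$target,
      "' (", x$terminated, " after ", x$n_subsets_generated,
      " removal subsets)\n", sep = "")
  show <- utils::head(x$signatures, 10L)
  for (s in show) print(s)
  if (length(x$signatures) > 10L)
    cat("... and", length(x$signatures) - 10L, "more\n")
  invisible(x)
}

#' Keep only non-reducible signatures
#'
#' A signature is non-reducible when it is not a proper superset of another
#' signature in the same output: among `{A,B,C}`, `{A,B,X}` and `{A,B}`
#' only `{A,B}` survives.
#'
#' @param signatures list of [signature()]s or character vectors.
#' @return the retained elements, in the original order.
#' @export
filter_non_reducible <- function(signatures) {
  vars <- lapply(signatures, sig_vars)
  keep <- vapply(seq_along(vars), function(i) {
    !any(vapply(seq_along(vars), function(j) {
      i != j && length(vars[[j]]) < length(vars[[i]]) && all(vars[[j]] %in% vars[[i]])
    }, logical(1)))
  }, logical(1))
  signatures[keep]
}

#' Write a signature set to JSON or TSV
#'
#' JSON records one object per signature (variables plus the removal subset
#' that produced it); TSV writes one signature per row with comma-joined
#' variable lists. Ordering follows the input (reference first for a
#' [tie_star()] result).
#'
#' @param x a `tie_result`, a baseline run result, or a list of signatures.
#' @param path output file path.
#' @param method method name recorded in the JSON output.
#' @param extra named list of additional top-level fields (e.g. a
#'   configuration hash) merged into the JSON object.
#' @return `path`, invisibly.
#' @export
write_signatures_json <- function(x, path, method = "tie", extra = list()) {
  sigs <- extract_signatures(x)
  obj <- c(list(method = method,
                signatures = lapply(sigs, function(s)
                  list(variables = sig_vars(s),
                       removed_subset = if (inherits(s, "signature"))
                         s$removed_subset else character()))),
           lapply(extra, jsonlite::unbox))
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)),
             path)
  invisible(path)
}

#' @rdname write_signatures_json
#' @export
write_signatures_tsv <- function(x, path) {
  sigs <- extract_signatures(x)
  df <- data.frame(
    index = seq_along(sigs),
    variables = vapply(sigs, function(s) paste(sig_vars(s), collapse = ","), character(1)),
    removed_subset = vapply(sigs, function(s)
      paste(if (inherits(s, "signature")) s$removed_subset else character(),
            collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

extract_signatures <- function(x) {
  if (inherits(x, "tie_result") || inherits(x, "baseline_result")) x$signatures
  else if (inherits(x, "signature")) list(x)
  else x
}
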