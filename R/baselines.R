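#' Baseline run result
#'
#' @param method method name.
#' @param signatures list of [signature()]s, deduplicated by variable set.
#' @param n_iterations iterations performed.
#' @param seed seed used (NA for deterministic methods).
#' @return object of class `baseline_result`.
#' @export
baseline_result <- function(method, signatures, n_iterations, seed = NA_integer_) {
  keys <- vapply(signatures, function(s) set_key(sig_vars(s)), character(1))
  signatures <- signatures[!duplicated(keys)]
  structure(list(method = method, signatures = signatures,
                 n_iterations = as.integer(n_iterations), seed = seed),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(x$method, ": ", length(x$signatures), " signature(s) in ",
      x$n_iterations, " iteration(s)\n", sep = "")
  for (s in utils::head(x$signatures, 10L)) print(s)
  invisible(x)
}

#' Iterative-removal multiple-signature extraction
#'
#' Repeats signature extraction after deleting every variable found in the
#' previously discovered signatures from the candidate pool. Stops when the
#' new signature is empty, or when its repeated-holdout AUC is statistically
#' below the first signature's (two-sided Wilcoxon rank-sum at `alpha_stop`
#' with a lower mean). By construction the accepted signatures are pairwise
#' disjoint, so any two optimal signatures sharing a variable can never both
#' be found — the family's structural blind spot.
#'
#' @param data a data frame with the target column.
#' @param t target column name (binary for the predictivity stop rule).
#' @param base_inducer handle from [make_base_inducer()].
#' @param alpha_stop significance level of the stop rule.
#' @param stop_rule `"predictivity"` (default) or `"empty_only"` (for
#'   non-binary targets).
#' @param classifier_spec,n_splits,test_fraction,seed holdout evaluation
#'   parameters (see [repeated_holdout_auc()]).
#' @return a [baseline_result()]; signatures in discovery order. An empty
#'   first signature yields zero signatures.
#' @export
iterative_removal <- function(data, t, base_inducer = make_base_inducer(),
                              alpha_stop = 0.05,
                              stop_rule = c("predictivity", "empty_only"),
                              classifier_spec = NULL, n_splits = 10L,
                              test_fraction = 0.3, seed = 1L) {
  stop_rule <- match.arg(stop_rule)
  if (is.null(classifier_spec)) classifier_spec <- classifier_spec()
  removed <- character(0)
  sigs <- list()
  ref_est <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    s <- base_inducer(data, t, removed)
    if (length(s$variables) == 0L) break
    if (stop_rule == "predictivity") {
      est <- repeated_holdout_auc(data, s$variables, t = t,
                                  classifier_spec = classifier_spec,
                                  n_splits = n_splits,
                                  test_fraction = test_fraction, seed = seed)
      if (is.null(ref_est)) {
        ref_est <- est
      } else {
        p <- wilcoxon_rank_sum(est$per_split_auc, ref_est$per_split_auc)
        if (p < alpha_stop && est$mean_auc < ref_est$mean_auc) break
      }
      s$predictivity <- est
    }
    sigs[[length(sigs) + 1L]] <- s
    removed <- union(removed, s$variables)
  }
  baseline_result("iterative_removal", sigs, iter)
}

#' Bootstrap-resampling multiple-signature extraction
#'
#' Applies the base inducer to `n_iter` bootstrap resamples (rows drawn with
#' replacement, original size) and returns the deduplicated signatures.
#' Deterministic given `seed`.
#'
#' @param data a data frame with the target column.
#' @param t target column name.
#' @param base_inducer handle from [make_base_inducer()].
#' @param n_iter number of bootstrap iterations (>= 1).
#' @param seed integer seed.
#' @return a [baseline_result()].
#' @export
resampling_extraction <- function(data, t, base_inducer = make_base_inducer(),
                                  n_iter = 50L, seed = 1L) {
  stopifnot(n_iter >= 1)
  n <- nrow(data)
  idx <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_iter), function(i) sample.int(n, n, replace = TRUE))
  })
  sigs <- lapply(idx, function(i) {
    boot <- data[i, , drop = FALSE]
    rownames(boot) <- NULL
    attr(boot, "target") <- attr(data, "target")
    base_inducer(boot, t, character())
  })
  baseline_result("resampling", sigs, n_iter, seed = as.integer(seed))
}

#' KIAMB: randomized IAMB-style Markov blanket search
#'
#' Forward phase: candidates conditionally dependent on the target given the
#' whole current blanket estimate (at `alpha`, reliable tests only) are
#' ranked by that conditional association; the next admission is drawn
#' uniformly from the top `ceil(k_rand * m)` of the `m` eligible candidates
#' (`k_rand = 0` always takes the top one, recovering deterministic IAMB).
#' Backward phase: members independent of the target given the rest of the
#' blanket are removed. Conditioning on the full blanket estimate is what
#' gives the algorithm its non-zero probability of reaching any boundary —
#' and its appetite for sample, since the tests lose reliability as the
#' blanket grows.
#'
#' @param data a data frame of factor columns with the target.
#' @param t target column name.
#' @param k_rand randomization fraction in `[0, 1]`.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param h reliability heuristic (average samples per cell).
#' @return a [signature()].
#' @export
kiamb <- function(data, t, k_rand = 0.8, alpha = 0.05, seed = 1L, h = 5) {
  stopifnot(k_rand >= 0, k_rand <= 1)
  vars <- sort(setdiff(names(data), t))
  ctx <- ci_context(data, c(t, vars))
  ci <- ctx_ci_fun(ctx, h)
  withr::with_seed(as.integer(seed), {
    mb <- character(0)
    repeat {
      cand <- setdiff(vars, mb)
      if (length(cand) == 0L) break
      res <- lapply(cand, function(v) ci(v, t, mb))
      ok <- vapply(res, function(r) r$reliable && r$p_value < alpha, logical(1))
      if (!any(ok)) break
      cand <- cand[ok]
      p <- vapply(res[ok], function(r) r$p_value, numeric(1))
      stat <- vapply(res[ok], function(r) r$statistic, numeric(1))
      ord <- order(p, -stat, cand)
      m <- length(cand)
      top <- max(1L, as.integer(ceiling(k_rand * m)))
      pick <- cand[ord[sample.int(top, 1L)]]
      mb <- sort(c(mb, pick))
    }
    for (x in mb) {
      res <- ci(x, t, setdiff(mb, x))
      if (!(res$reliable && res$p_value < alpha)) mb <- setdiff(mb, x)
    }
    signature(mb)
  })
}
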