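#' Area under the ROC curve
#'
#' Probability that a uniformly drawn positive outranks a uniformly drawn
#' negative, ties counted half (the Mann-Whitney identity). Negating the
#' scores maps AUC to 1 - AUC.
#'
#' @param labels binary vector: logical, 0/1 numeric, or a two-level factor
#'   (the second level is the positive class). Both classes must be present.
#' @param scores numeric scores, higher means more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  pos <- as_binary_labels(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present to compute AUC")
  stopifnot(length(pos) == length(scores))
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("AUC requires a binary phenotype")
    return(labels == levels(labels)[2L])
  }
  u <- sort(unique(labels))
  if (length(u) > 2L) stop("AUC requires a binary phenotype")
  labels == u[length(u)]
}

#' Classifier specification for predictivity estimation
#'
#' The evaluation classifier is a linear max-margin model (support vector
#' machine, linear kernel) with a single fixed regularization constant — no
#' nested tuning, so seeded runs are exactly reproducible. Discrete
#' predictors are one-hot encoded.
#'
#' @param type currently `"svm_linear"`.
#' @param cost SVM cost (regularization) parameter.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(type = "svm_linear", cost = 1) {
  stopifnot(identical(type, "svm_linear"), cost > 0)
  structure(list(type = type, cost = cost), class = "classifier_spec")
}

# One-hot design matrix using the dataset's recorded factor levels, so train
# and test splits always share an encoding. Numeric columns pass through.
one_hot <- function(data, vars) {
  cols <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.factor(x)) {
      m <- outer(as.integer(x), seq_len(nlevels(x)), `==`) * 1
      colnames(m) <- paste0(v, ".", levels(x))
      m
    } else {
      m <- matrix(as.numeric(x), ncol = 1)
      colnames(m) <- v
      m
    }
  })
  do.call(cbind, cols)
}

fit_score_svm <- function(x_train, y_train, x_test, spec) {
  y <- factor(y_train)
  fit <- e1071::svm(x = x_train, y = y, kernel = "linear", cost = spec$cost,
                    scale = FALSE)
  pred <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm labels the decision value "a/b": positive values favor class a.
  parts <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]]
  pos <- levels(y)[2L]
  if (identical(parts[1L], pos)) as.numeric(dv[, 1L]) else -as.numeric(dv[, 1L])
}

#' Predictivity estimate record
#'
#' @param per_split_auc AUC per holdout split.
#' @param classifier_spec the [classifier_spec()] used.
#' @return object of class `predictivity_estimate` with fields
#'   `per_split_auc`, `mean_auc`, `n_splits`, `classifier_spec`.
#' @export
predictivity_estimate <- function(per_split_auc, classifier_spec) {
  structure(list(per_split_auc = as.numeric(per_split_auc),
                 mean_auc = mean(per_split_auc),
                 n_splits = length(per_split_auc),
                 classifier_spec = classifier_spec),
            class = "predictivity_estimate")
}

#' Repeated-holdout AUC of a signature
#'
#' For each of `n_splits` seeded random splits: fit the classifier on the
#' training part restricted to the signature variables, score the held-out
#' part, record the AUC. Splits with a single class on either side are
#' redrawn (bounded retries).
#'
#' @param data a data frame with a binary target column.
#' @param signature a [signature()] or nonempty character vector of
#'   predictor names.
#' @param t target column name; defaults to the dataset's `"target"`
#'   attribute.
#' @param classifier_spec a [classifier_spec()].
#' @param n_splits number of holdout repetitions.
#' @param test_fraction held-out fraction per split, in (0, 1).
#' @param seed integer seed; identical seeds give identical splits and AUCs.
#' @return a [predictivity_estimate()].
#' @export
repeated_holdout_auc <- function(data, signature, t = attr(data, "target"),
                                 classifier_spec = NULL, n_splits = 10L,
                                 test_fraction = 0.3, seed = 1L) {
  vars <- sig_vars(signature)
  if (length(vars) == 0L) stop("cannot evaluate an empty signature")
  if (is.null(t)) stop("target column not specified")
  if (is.null(classifier_spec)) classifier_spec <- classifier_spec()
  y <- as_binary_labels(data[[t]])
  n <- nrow(data)
  n_test <- max(1L, round(test_fraction * n))
  if (n_test >= n) stop("test_fraction leaves no training data")
  x_all <- one_hot(data, vars)
  aucs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_splits), function(s) {
      for (try in 1:100) {
        test_idx <- sample.int(n, n_test)
        y_tr <- y[-test_idx]; y_te <- y[test_idx]
        if (any(y_tr) && !all(y_tr) && any(y_te) && !all(y_te)) {
          scores <- fit_score_svm(x_all[-test_idx, , drop = FALSE], y_tr,
                                  x_all[test_idx, , drop = FALSE],
                                  classifier_spec)
          return(auc_score(y_te, scores))
        }
      }
      stop("could not draw a split with both classes on both sides")
    }, numeric(1))
  })
  predictivity_estimate(aucs, classifier_spec)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact distribution when the combined sample size is at most 20 and there
#' are no ties; normal approximation with tie correction otherwise. Used for
#' all predictivity comparisons.
#'
#' @param sample_a,sample_b numeric samples (each of size >= 2).
#' @return the two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("both samples must have at least 2 observations")
  if (all(sample_a == sample_a[1]) && all(sample_b == sample_b[1]) &&
      sample_a[1] == sample_b[1]) return(1)
  n <- length(sample_a) + length(sample_b)
  has_ties <- anyDuplicated(c(sample_a, sample_b)) > 0L
  p <- suppressWarnings(stats::wilcox.test(
    sample_a, sample_b, exact = (n <= 20L && !has_ties), correct = TRUE
  )$p.value)
  if (is.nan(p)) 1 else min(1, p)
}

#' Per-method evaluation report
#'
#' @param method method name.
#' @param signatures list of signatures evaluated.
#' @param discovery list of [predictivity_estimate()]s, one per signature
#'   (holdout on the discovery data; epsilon_1).
#' @param validation_auc numeric vector, one per signature: AUC of the model
#'   fitted on the full discovery data and scored on the validation data
#'   (epsilon_2), or `NULL` when no validation data was supplied.
#' @return object of class `method_report` with `avg_discovery_auc`,
#'   `avg_validation_auc` and `overfitting` (mean over signatures of
#'   epsilon_1 - epsilon_2).
#' @export
method_report <- function(method, signatures, discovery,
                          validation_auc = NULL) {
  e1 <- vapply(discovery, function(d) d$mean_auc, numeric(1))
  avg_val <- if (is.null(validation_auc) || length(validation_auc) == 0L)
    NA_real_ else mean(validation_auc)
  overfit <- if (is.null(validation_auc) || length(validation_auc) == 0L)
    NA_real_ else mean(e1 - validation_auc)
  structure(list(method = method, signatures = signatures,
                 discovery = discovery, validation_auc = validation_auc,
                 avg_discovery_auc = if (length(e1)) mean(e1) else NA_real_,
                 avg_validation_auc = avg_val, overfitting = overfit),
            class = "method_report")
}

#' @export
print.method_report <- function(x, ...) {
  cat(sprintf("%s: %d signature(s), discovery AUC %.3f%s\n", x$method,
              length(x$signatures), x$avg_discovery_auc,
              if (!is.na(x$avg_validation_auc))
                sprintf(", validation AUC %.3f, overfitting %+.3f",
                        x$avg_validation_auc, x$overfitting) else ""))
  invisible(x)
}

#' Maximal predictivity across methods
#'
#' The maximum over methods of the average signature AUC (validation AUC
#' when available, discovery holdout otherwise). A method attains the
#' maximum when its per-signature AUC sample is statistically
#' indistinguishable from the best method's by a two-sided Wilcoxon
#' rank-sum test at `alpha`.
#'
#' @param reports list of [method_report()]s (at least one, each with at
#'   least one signature).
#' @param alpha significance level for the attainment comparison.
#' @return list with `value` (the maximal predictivity) and `methods`
#'   (names of the attaining methods).
#' @export
maximal_predictivity <- function(reports, alpha = 0.05) {
  stopifnot(length(reports) >= 1)
  samples <- lapply(reports, function(r) {
    if (!is.null(r$validation_auc) && length(r$validation_auc))
      r$validation_auc
    else vapply(r$discovery, function(d) d$mean_auc, numeric(1))
  })
  avg <- vapply(samples, mean, numeric(1))
  best <- which.max(avg)
  attain <- vapply(seq_along(reports), function(i) {
    if (i == best) return(TRUE)
    if (length(samples[[i]]) < 2L || length(samples[[best]]) < 2L)
      return(isTRUE(all.equal(mean(samples[[i]]), avg[best])))
    wilcoxon_rank_sum(samples[[i]], samples[[best]]) >= alpha
  }, logical(1))
  list(value = avg[best],
       methods = vapply(reports[attain], function(r) r$method, character(1)))
}

#' Discovery/validation reproducibility protocol
#'
#' For each method: extract signatures on the discovery dataset; estimate
#' each signature's predictivity there by repeated holdout (epsilon_1);
#' refit on the full discovery data and score the independent validation
#' dataset (epsilon_2). The per-method overfitting magnitude is the mean of
#' epsilon_1 - epsilon_2 over signatures; a method with perfect statistical
#' reproducibility sits at 0.
#'
#' @param discovery,validation data frames sharing a variable namespace
#'   (the intersection is used; disjoint namespaces are an error) and a
#'   binary target.
#' @param methods named list of extractors `function(data, t)` returning a
#'   list of signatures (or character vectors).
#' @param t target column name.
#' @param classifier_spec,n_splits,test_fraction,seed evaluation parameters.
#' @return list of [method_report()]s, one per method, in input order.
#' @export
reproducibility_protocol <- function(discovery, validation, methods,
                                     t = attr(discovery, "target"),
                                     classifier_spec = NULL, n_splits = 10L,
                                     test_fraction = 0.3, seed = 1L) {
  if (is.null(classifier_spec)) classifier_spec <- classifier_spec()
  common <- intersect(names(discovery), names(validation))
  if (!t %in% common) stop("target column must be present in both datasets")
  if (length(setdiff(common, t)) == 0L)
    stop("discovery and validation datasets share no predictor variables")
  if (length(setdiff(names(discovery), common)))
    message("dropping ", length(setdiff(names(discovery), common)),
            " discovery-only variable(s)")
  disc <- discovery[common]
  attr(disc, "target") <- t
  val <- validation[common]
  y_val <- as_binary_labels(val[[t]])
  lapply(names(methods), function(mname) {
    sig_list <- methods[[mname]](disc, t)
    sig_list <- lapply(sig_list, sig_vars)
    sig_list <- Filter(length, sig_list)
    if (length(sig_list) == 0L)
      return(method_report(mname, list(), list(), numeric(0)))
    est <- lapply(sig_list, function(s)
      repeated_holdout_auc(disc, s, t = t, classifier_spec = classifier_spec,
                           n_splits = n_splits,
                           test_fraction = test_fraction, seed = seed))
    val_auc <- vapply(sig_list, function(s) {
      scores <- fit_score_svm(one_hot(disc, s), as_binary_labels(disc[[t]]),
                              one_hot(val, s), classifier_spec)
      auc_score(y_val, scores)
    }, numeric(1))
    method_report(mname, sig_list, est, val_auc)
  })
}

#' Scatter data for discovery-vs-validation predictivity
#'
#' One row per (method, signature): discovery holdout AUC against validation
#' AUC, the raw material of a reproducibility scatter plot.
#'
#' @param reports list of [method_report()]s from
#'   [reproducibility_protocol()].
#' @param path optional TSV output path.
#' @return a data frame with columns `method`, `signature`,
#'   `discovery_auc`, `validation_auc` (invisibly when `path` is given).
#' @export
reproducibility_scatter <- function(reports, path = NULL) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    if (length(r$signatures) == 0L) return(NULL)
    data.frame(
      method = r$method,
      signature = vapply(r$signatures, function(s)
        paste(sig_vars(s), collapse = ","), character(1)),
      discovery_auc = vapply(r$discovery, function(d) d$mean_auc, numeric(1)),
      validation_auc = if (is.null(r$validation_auc)) NA_real_ else r$validation_auc,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(rows)) rows <- data.frame(method = character(0),
                                        signature = character(0),
                                        discovery_auc = numeric(0),
                                        validation_auc = numeric(0))
  if (!is.null(path)) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
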