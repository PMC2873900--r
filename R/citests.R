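#' Conditional-independence test result
#'
#' @param statistic nonnegative test statistic (G2, |z|, or exact CMI).
#' @param dof degrees of freedom (>= 1).
#' @param p_value p-value in [0, 1].
#' @param reliable whether the sample-size heuristic was satisfied. When
#'   `FALSE` the caller must treat the result as "dependence not
#'   established", never as evidence of dependence.
#' @return object of class `ci_result`.
#' @export
ci_result <- function(statistic, dof, p_value, reliable) {
  structure(list(statistic = statistic, dof = as.integer(dof),
                 p_value = p_value, reliable = isTRUE(reliable)),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("CI test: statistic = %.4g, dof = %d, p = %.4g%s\n",
              x$statistic, x$dof, x$p_value,
              if (x$reliable) "" else " (unreliable)"))
  invisible(x)
}

# Integer-coded view of a dataset's discrete columns: codes is an n x p
# matrix of 0-based level codes, cards the level counts. Built once per
# algorithm run so that individual tests avoid factor bookkeeping.
ci_context <- function(data, vars = NULL) {
  if (is.null(vars)) vars <- names(data)
  cols <- data[vars]
  is_fac <- vapply(cols, is.factor, logical(1))
  if (!all(is_fac)) stop("discrete tests require factor columns; got non-factor: ",
                         paste(vars[!is_fac], collapse = ", "))
  codes <- vapply(cols, function(f) as.integer(f) - 1L, integer(nrow(data)))
  if (nrow(data) == 1L) codes <- matrix(codes, nrow = 1L)
  if (nrow(data) == 0L) codes <- matrix(integer(0), nrow = 0L, ncol = length(vars))
  list(vars = vars, codes = codes,
       cards = vapply(cols, nlevels, integer(1)), n = nrow(data))
}

# G2 test on a ci_context, by column index.
g2_ctx <- function(ctx, xi, ti, zi = integer(0), h = 5) {
  cx <- ctx$cards[xi]; ct <- ctx$cards[ti]; cz <- ctx$cards[zi]
  n <- ctx$n
  if (cx < 2L || ct < 2L)
    return(ci_result(0, 1L, 1, reliable = n >= h))
  cells <- cx * ct * prod(cz)
  reliable <- n / cells >= h
  if (cells > 5e7)
    return(ci_result(NA_real_, 1L, 1, reliable = FALSE))
  res <- g2_stat_cpp(ctx$codes[, xi], ctx$codes[, ti],
                     ctx$codes[, zi, drop = FALSE], cx, ct, cz)
  dof <- max(1L, (cx - 1L) * (ct - 1L) * as.integer(res[2]))
  ci_result(res[1], dof, stats::pchisq(res[1], df = dof, lower.tail = FALSE),
            reliable)
}

#' G2 conditional-independence test for discrete data
#'
#' Likelihood-ratio test of `x` independent of `t` given the variables in
#' `cond`: G2 = 2 * sum O * log(O / E) over the cells of the x-by-t table
#' within each stratum of the conditioning configuration. Degrees of freedom
#' are `(|x| - 1) (|t| - 1)` per nonempty stratum (empty strata contribute
#' neither to the statistic nor to the dof), and the p-value is the upper
#' chi-square tail. The result is flagged reliable when the average sample
#' per contingency cell, `n / (|x| |t| prod |cond_i|)`, is at least `h`.
#'
#' @param data a data frame of factor columns (see [tabular_dataset()]).
#' @param x,t column names of the tested pair (`x != t`).
#' @param cond character vector of conditioning column names.
#' @param h reliability heuristic: minimum average samples per cell.
#' @return a [ci_result()]. A degenerate (single-level) `x` or `t` yields
#'   statistic 0, dof 1, p-value 1.
#' @export
g2_test <- function(data, x, t, cond = character(), h = 5) {
  stopifnot(x != t, !x %in% cond, !t %in% cond)
  ctx <- ci_context(data, c(x, t, cond))
  g2_ctx(ctx, 1L, 2L, zi = seq_along(cond) + 2L, h = h)
}

#' Fisher-z conditional-independence test for continuous data
#'
#' Tests zero partial correlation of `x` and `t` given `cond` in
#' jointly-Gaussian-like data: the partial correlation `r` is computed from
#' the inverse of the correlation matrix, then
#' `z = sqrt(n - |cond| - 3) * atanh(r)` is referred to a standard normal
#' (two-sided). A singular conditioning covariance yields `reliable = FALSE`
#' and p-value 1.
#'
#' @param data a data frame with numeric columns `x`, `t`, `cond`.
#' @param x,t,cond as in [g2_test()].
#' @param h unused, kept for interface symmetry.
#' @return a [ci_result()].
#' @export
fisher_z_test <- function(data, x, t, cond = character(), h = 5) {
  stopifnot(x != t, !x %in% cond, !t %in% cond)
  vars <- c(x, t, cond)
  m <- as.matrix(data[vars])
  if (!is.numeric(m)) stop("fisher_z_test requires numeric columns")
  n <- nrow(m)
  k <- length(cond)
  if (n <= k + 3) stop("need n > |cond| + 3 observations")
  # residual route: robust to |r| = 1 between x and t, and makes a singular
  # conditioning covariance detectable via the regression rank
  design <- cbind(1, m[, -(1:2), drop = FALSE])
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) return(ci_result(0, 1L, 1, reliable = FALSE))
  rx <- stats::residuals(stats::lm.fit(design, m[, 1]))
  rt <- stats::residuals(stats::lm.fit(design, m[, 2]))
  if (stats::sd(rx) == 0 || stats::sd(rt) == 0)
    return(ci_result(0, 1L, 1, reliable = FALSE))
  r <- stats::cor(rx, rt)
  if (!is.finite(r)) return(ci_result(0, 1L, 1, reliable = FALSE))
  r <- max(-1 + 1e-12, min(1 - 1e-12, r))
  z <- sqrt(n - k - 3) * atanh(r)
  ci_result(abs(z), 1L, 2 * stats::pnorm(-abs(z)), reliable = TRUE)
}

#' Rank candidate variables by univariate association with the target
#'
#' Tests every candidate against `t` unconditionally with the test matching
#' the dataset's column kind (G2 for discrete, Fisher-z for continuous) and
#' returns them sorted by ascending p-value, stronger statistic first within
#' p-value ties, then by variable name.
#'
#' @param data a data frame (all-factor or all-numeric candidate columns).
#' @param t target column name.
#' @param candidates nonempty character vector of candidate names.
#' @param h reliability heuristic passed to the test.
#' @return a data frame with columns `variable`, `p_value`, `statistic`,
#'   `reliable`, ordered as described.
#' @export
rank_by_association <- function(data, t, candidates, h = 5) {
  if (length(candidates) == 0L) stop("no candidate variables to rank")
  discrete <- is.factor(data[[t]])
  res <- lapply(candidates, function(v) {
    if (discrete) g2_test(data, v, t, h = h) else fisher_z_test(data, v, t)
  })
  out <- data.frame(
    variable = as.character(candidates),
    p_value = vapply(res, function(r) r$p_value, numeric(1)),
    statistic = vapply(res, function(r) r$statistic, numeric(1)),
    reliable = vapply(res, function(r) r$reliable, logical(1)),
    stringsAsFactors = FALSE
  )
  out[order(out$p_value, -out$statistic, out$variable), , drop = FALSE]
}
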