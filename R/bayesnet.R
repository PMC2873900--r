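#' Discrete Bayesian network
#'
#' Constructs a discrete Bayesian network from a node list, a parent map and
#' conditional probability tables. The network is the ground-truth object for
#' simulation (see [sample_bn()]) and for exact oracle computations (see
#' [enumerate_markov_boundaries_exact()]).
#'
#' @param variables named integer vector of cardinalities (>= 2), one entry
#'   per variable; names are the variable names.
#' @param parents named list; for each variable, a character vector of parent
#'   names. Variables absent from the list have no parents. The relation must
#'   be acyclic.
#' @param cpts named list of numeric matrices. For variable `v` with parents
#'   `p1, ..., pk`, `cpts[[v]]` has one row per parent configuration
#'   (`prod(cardinality(p1..pk))` rows, configurations enumerated with the
#'   first parent varying fastest) and `cardinality(v)` columns. Each row is a
#'   probability vector summing to 1 within 1e-10. Root variables have a
#'   single-row matrix (the marginal).
#' @param target name of the designated phenotype variable.
#' @param latent character vector of variable names that are hidden sources:
#'   they are dropped from sampled datasets when `observed_only = TRUE` and
#'   are never considered by the exact boundary oracle.
#'
#' @return an object of class `discrete_bn` with fields `variables`,
#'   `parents`, `cpts`, `target`, `latent`, and `order` (a topological order).
#' @export
discrete_bn <- function(variables, parents = list(), cpts, target, latent = character()) {
  stopifnot(is.numeric(variables), length(variables) >= 1, !is.null(names(variables)))
  vnames <- names(variables)
  if (anyDuplicated(vnames)) stop("duplicate variable names")
  if (any(variables < 2)) stop("all cardinalities must be >= 2")
  variables <- as.integer(variables)
  names(variables) <- vnames
  parents <- parents[intersect(names(parents), vnames)]
  full_parents <- stats::setNames(vector("list", length(vnames)), vnames)
  for (v in vnames) full_parents[[v]] <- as.character(parents[[v]] %||% character())
  bad <- setdiff(unlist(full_parents), vnames)
  if (length(bad)) stop("unknown parent variable(s): ", paste(bad, collapse = ", "))
  ord <- topo_order(vnames, full_parents)
  if (!target %in% vnames) stop("target variable '", target, "' not in network")
  if (!all(latent %in% vnames)) stop("latent names must be network variables")
  if (target %in% latent) stop("target cannot be latent")
  net <- structure(
    list(variables = variables, parents = full_parents, cpts = cpts,
         target = target, latent = as.character(latent), order = ord),
    class = "discrete_bn"
  )
  validate_bn(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kahn's algorithm; errors on cycles.
topo_order <- function(vnames, parents) {
  indeg <- vapply(vnames, function(v) length(parents[[v]]), integer(1))
  children <- stats::setNames(vector("list", length(vnames)), vnames)
  for (v in vnames) for (p in parents[[v]]) children[[p]] <- c(children[[p]], v)
  queue <- sort(vnames[indeg == 0L])
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- sort(c(queue, ch))
    }
  }
  if (length(out) != length(vnames)) stop("parent relation is cyclic")
  out
}

validate_bn <- function(net) {
  for (v in names(net$variables)) {
    cpt <- net$cpts[[v]]
    if (is.null(cpt)) stop("missing CPT for variable '", v, "'")
    cpt <- as.matrix(cpt)
    k <- net$variables[[v]]
    nrow_expected <- prod(c(1L, net$variables[net$parents[[v]]]))
    if (ncol(cpt) != k) stop("CPT for '", v, "' must have ", k, " columns")
    if (nrow(cpt) != nrow_expected)
      stop("CPT for '", v, "' must have ", nrow_expected, " rows (one per parent configuration)")
    if (any(cpt < 0)) stop("CPT for '", v, "' has negative entries")
    if (any(abs(rowSums(cpt) - 1) > 1e-10))
      stop("CPT rows for '", v, "' must sum to 1 within 1e-10")
  }
  invisible(net)
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$variables), "variables\n")
  cat("  target:", x$target, if (length(x$latent)) paste0("(", length(x$latent), " latent)") else "", "\n")
  narcs <- sum(lengths(x$parents))
  cat("  arcs:", narcs, "\n")
  invisible(x)
}

#' Observed variables of a network
#'
#' @param net a `discrete_bn`.
#' @return character vector of non-latent variable names, in name order.
#' @export
observed_vars <- function(net) sort(setdiff(names(net$variables), net$latent))

# Row index into a CPT given integer parent values (1-based), parents in the
# declared order, first parent varying fastest.
cpt_row_index <- function(parent_values, cards) {
  if (length(cards) == 0L) return(rep.int(1L, max(1L, NROW(parent_values))))
  mult <- cumprod(c(1L, cards[-length(cards)]))
  1L + as.integer(as.matrix(parent_values - 1L) %*% mult)
}

#' Sample a dataset from a discrete Bayesian network
#'
#' Ancestral (forward) sampling in topological order. Identical
#' `(net, n, seed)` give identical datasets.
#'
#' @param net a `discrete_bn`.
#' @param n number of rows (>= 0).
#' @param seed integer seed.
#' @param observed_only drop latent source variables from the result
#'   (default `TRUE`).
#' @return a [tabular_dataset()]: a `data.frame` of factors whose levels are
#'   `"0", "1", ...` up to each variable's cardinality, with the network's
#'   target recorded in the `"target"` attribute.
#' @export
sample_bn <- function(net, n, seed, observed_only = TRUE) {
  stopifnot(n >= 0)
  cols <- withr::with_seed(as.integer(seed), {
    out <- stats::setNames(vector("list", length(net$order)), net$order)
    for (v in net$order) {
      pa <- net$parents[[v]]
      cpt <- net$cpts[[v]]
      if (n == 0L) { out[[v]] <- integer(0); next }
      rows <- if (length(pa) == 0L) rep.int(1L, n) else {
        pv <- do.call(cbind, out[pa])
        cpt_row_index(pv, net$variables[pa])
      }
      cum <- t(apply(cpt, 1L, cumsum))
      u <- stats::runif(n)
      out[[v]] <- 1L + rowSums(u > cum[rows, , drop = FALSE])
    }
    out
  })
  keep <- if (observed_only) setdiff(net$order, net$latent) else net$order
  keep <- keep[order(keep != net$target, keep)]  # target first, rest by name
  df <- as.data.frame(lapply(keep, function(v) {
    factor(cols[[v]] - 1L, levels = 0:(net$variables[[v]] - 1L))
  }), col.names = keep, optional = TRUE, stringsAsFactors = FALSE)
  names(df) <- keep
  tabular_dataset(df, target = net$target)
}

#' Serialize a network to JSON / read it back
#'
#' The format records variable names, cardinalities, parent lists, CPT rows
#' (row-major, one row per parent configuration with the first parent varying
#' fastest), the target and the latent set. `bn_from_json(bn_to_json(net))`
#' reconstructs an identical network.
#'
#' @param net a `discrete_bn`.
#' @param path file path; for `bn_to_json`, `NULL` returns the JSON string.
#' @param extra named list of additional top-level fields (e.g. a
#'   configuration hash); ignored by `bn_from_json`.
#' @return `bn_to_json`: the path (or JSON string) invisibly;
#'   `bn_from_json`: a `discrete_bn`.
#' @export
bn_to_json <- function(net, path = NULL, extra = list()) {
  obj <- c(list(
    variables = lapply(names(net$variables), function(v)
      list(name = v, cardinality = net$variables[[v]])),
    parents = net$parents,
    cpts = lapply(net$cpts, function(m) unclass(as.matrix(m))),
    target = net$target,
    latent = net$latent
  ), extra)
  txt <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(invisible(as.character(txt)))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname bn_to_json
#' @param json for `bn_from_json`: a path to a JSON file, or a JSON string.
#' @export
bn_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyMatrix = TRUE,
                            simplifyDataFrame = FALSE)
  cards <- vapply(obj$variables, function(v) as.integer(v$cardinality), integer(1))
  names(cards) <- vapply(obj$variables, function(v) v$name, character(1))
  parents <- lapply(obj$parents, as.character)
  cpts <- lapply(obj$cpts, function(m) matrix(as.numeric(m), nrow = NROW(m)))
  discrete_bn(cards, parents, cpts, target = obj$target,
              latent = as.character(obj$latent %||% character()))
}
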