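#' Latent Gaussian DAG model
#'
#' A linear-Gaussian structural equation model over latent variables
#' \eqn{Y_1, \ldots, Y_m},
#' \deqn{Y_k \mid y_{pa(k)} \sim N\!\big(\mu_k + \sum_{j \in pa(k)} b_{jk} (y_j - \mu_j),\; v_k\big),}
#' each observed only through its ordinal discretization
#' \eqn{X_k = l \iff Y_k \in [\alpha(k, l), \alpha(k, l+1))} with 0-based
#' levels and thresholds \eqn{-\infty = \alpha(k,0) < \alpha(k,1) < \cdots <
#' \alpha(k, L_k) = +\infty}.
#'
#' @param nodes character vector of variable names.
#' @param parents named list: for each node, character vector of parents.
#' @param coef named list: for each node, numeric vector of edge coefficients
#'   named by parent.
#' @param means named numeric vector of node means (default all 0).
#' @param vars named numeric vector of positive conditional variances.
#' @param thresholds named list: per node, numeric vector of length
#'   `L_k + 1` starting at `-Inf` and ending at `+Inf`, strictly increasing.
#' @return Object of class `latent_dag`.
#' @export
latent_dag <- function(nodes, parents, coef, means = NULL, vars = NULL,
                       thresholds = NULL) {
  m <- length(nodes)
  if (is.null(means)) means <- stats::setNames(rep(0, m), nodes)
  if (is.null(vars)) vars <- stats::setNames(rep(1, m), nodes)
  parents <- parents[nodes]
  coef <- coef[nodes]
  names(parents) <- nodes
  names(coef) <- nodes
  for (k in nodes) {
    parents[[k]] <- as.character(parents[[k]] %||% character(0))
    coef[[k]] <- coef[[k]] %||% stats::setNames(numeric(0), character(0))
    if (!setequal(names(coef[[k]]), parents[[k]])) {
      stop_named("latent_dag: coef names for '%s' do not match parents", k)
    }
    coef[[k]] <- coef[[k]][parents[[k]]]
    if (!all(parents[[k]] %in% nodes)) stop_named("latent_dag: unknown parent of '%s'", k)
  }
  if (any(vars[nodes] <= 0)) stop_named("latent_dag: conditional variances must be > 0")
  obj <- structure(
    list(nodes = nodes, parents = parents, coef = coef,
         means = means[nodes], vars = vars[nodes],
         thresholds = thresholds),
    class = "latent_dag"
  )
  if (is.null(topological_order(obj))) stop_named("latent_dag: graph has a cycle")
  if (!is.null(thresholds)) {
    for (k in nodes) {
      a <- thresholds[[k]]
      if (is.null(a) || a[1] != -Inf || a[length(a)] != Inf ||
          is.unsorted(a, strictly = TRUE)) {
        stop_named("latent_dag: thresholds for '%s' must be strictly increasing from -Inf to Inf", k)
      }
    }
  }
  obj
}

#' @export
print.latent_dag <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat(sprintf("<latent_dag> %d nodes, %d edges\n", length(x$nodes), ne))
  for (k in x$nodes) {
    if (length(x$parents[[k]])) {
      cat(sprintf("  %s <- %s\n", k,
                  paste(sprintf("%s (%.3f)", x$parents[[k]], x$coef[[k]]),
                        collapse = ", ")))
    }
  }
  invisible(x)
}

#' Adjacency matrix of a latent DAG
#'
#' @param model a [latent_dag].
#' @return m x m 0/1 matrix, `A[j, k] = 1` iff edge j -> k.
#' @export
dag_adjacency <- function(model) {
  m <- length(model$nodes)
  A <- matrix(0L, m, m, dimnames = list(model$nodes, model$nodes))
  for (k in model$nodes) A[model$parents[[k]], k] <- 1L
  A
}

# Topological order of node names, or NULL if cyclic.
topological_order <- function(model) {
  A <- if (inherits(model, "latent_dag")) dag_adjacency(model) else model
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  if (!igraph::is_dag(g)) return(NULL)
  names(igraph::topo_sort(g, mode = "out"))
}

# TRUE iff a directed path from `from` to `to` exists.
has_directed_path <- function(model, from, to) {
  A <- dag_adjacency(model)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  d <- igraph::distances(g, v = from, to = to, mode = "out")
  is.finite(d[1, 1])
}

#' Implied covariance of the latent joint distribution
#'
#' Computes the covariance matrix of \eqn{Y} implied by the structural
#' equations, by recursion in topological order:
#' \eqn{\mathrm{Cov}(Y_k, Y_j) = \sum_{p \in pa(k)} b_{pk} \mathrm{Cov}(Y_p, Y_j)}
#' for earlier j, and
#' \eqn{\mathrm{Var}(Y_k) = b_k^\top \Sigma_{pa(k)} b_k + v_k}.
#' The recursion produces exact zeros between nodes with no connecting
#' path, which keeps null causal effects identically zero.
#'
#' @param model a [latent_dag].
#' @return Symmetric positive-definite m x m covariance matrix.
#' @export
implied_covariance <- function(model) {
  nodes <- model$nodes
  ord <- topological_order(model)
  m <- length(nodes)
  S <- matrix(0, m, m, dimnames = list(nodes, nodes))
  for (k in ord) {
    pa <- model$parents[[k]]
    b <- model$coef[[k]]
    if (length(pa)) {
      cross <- drop(b %*% S[pa, , drop = FALSE])  # Cov(sum b Yp, Y_j) for all j
      S[k, ] <- cross
      S[, k] <- cross
      S[k, k] <- drop(b %*% S[pa, pa, drop = FALSE] %*% b) + model$vars[[k]]
    } else {
      S[k, k] <- model$vars[[k]]
    }
  }
  S
}

#' Estimate latent thresholds from an ordinal column
#'
#' Probit threshold estimator: on the standard-normal latent scale,
#' \eqn{\alpha(k, l) = \Phi^{-1}(\hat P(X_k < l))} from the cumulative level
#' frequencies, with infinite endpoints. Empty interior levels are collapsed
#' with a warning.
#'
#' @param column an [ordinal_column] or integer vector of 0-based levels.
#' @return Numeric vector of length `L + 1`: `-Inf`, interior thresholds,
#'   `+Inf`, where `L` is the number of occupied levels after collapsing.
#' @export
estimate_thresholds <- function(column) {
  lev <- if (inherits(column, "ordinal_column")) column$levels else as.integer(column)
  L <- max(lev) + 1L
  counts <- tabulate(lev + 1L, nbins = L)
  if (sum(counts > 0) < 2L) {
    stop_named("estimate_thresholds: all mass at one level")
  }
  if (any(counts == 0L)) {
    warning("estimate_thresholds: empty level(s) collapsed", call. = FALSE)
    counts <- counts[counts > 0L]
  }
  cum <- cumsum(counts) / sum(counts)
  c(-Inf, qnorm(cum[-length(cum)]), Inf)
}

# Rescale a fitted model so every latent has mean 0 and marginal variance 1.
# Thresholds are assumed to live on the standardized scale already and are
# left untouched; coefficients and conditional variances are rescaled via
# b'_jk = b_jk * s_j / s_k, v'_k = v_k / s_k^2 with s = sqrt(diag(Sigma)).
standardize_latent_dag <- function(model) {
  S <- implied_covariance(model)
  s <- sqrt(diag(S))
  for (k in model$nodes) {
    pa <- model$parents[[k]]
    if (length(pa)) {
      model$coef[[k]] <- model$coef[[k]] * s[pa] / s[k]
    }
    model$vars[[k]] <- model$vars[[k]] / s[k]^2
    model$means[[k]] <- 0
  }
  model
}
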