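# Markov-equivalence (CPDAG) utilities and bootstrap edge frequencies.

# Chickering's edge ordering: a total order over directed edges driven by a
# topological node order, used by the label-compelled algorithm.
order_edges <- function(A) {
  nodes <- colnames(A)
  ord <- topological_order(A)
  rank <- stats::setNames(seq_along(ord), ord)
  edges <- which(A == 1L, arr.ind = TRUE)
  if (nrow(edges) == 0L) return(edges)
  res <- matrix(0L, 0, 2)
  unordered <- rep(TRUE, nrow(edges))
  while (any(unordered)) {
    tgt_rank <- rank[nodes[edges[, 2]]]
    tgt_rank[!unordered] <- Inf
    y_rank <- min(tgt_rank)
    cand <- which(unordered & tgt_rank == y_rank)
    src_rank <- rank[nodes[edges[cand, 1]]]
    pick <- cand[which.max(src_rank)]
    res <- rbind(res, edges[pick, , drop = FALSE])
    unordered[pick] <- FALSE
  }
  res
}

#' Convert a DAG to its CPDAG
#'
#' Computes the completed partially directed acyclic graph representing the
#' Markov equivalence class of a DAG: compelled edges (those shared by every
#' equivalent DAG, including all v-structure edges) stay directed, reversible
#' edges become undirected. Uses the label-compelled transformational
#' algorithm.
#'
#' @param x a [latent_dag] or 0/1 adjacency matrix (`A[j,k]=1` iff j -> k).
#' @return Object of class `cpdag`: adjacency matrix where a directed edge
#'   j -> k has `A[j,k]=1, A[k,j]=0` and an undirected edge has both entries 1.
#' @export
dag_to_cpdag <- function(x) {
  A <- if (inherits(x, "latent_dag")) dag_adjacency(x) else {
    storage.mode(x) <- "integer"; x
  }
  if (is.null(topological_order(A))) stop_named("dag_to_cpdag: input is cyclic")
  ord <- order_edges(A)
  lab <- rep(0L, nrow(ord))  # 0 unknown, 1 compelled, -1 reversible
  pa <- function(k) which(A[, k] == 1L)
  edge_idx <- function(j, k) which(ord[, 1] == j & ord[, 2] == k)
  i <- 1L
  while (i <= nrow(ord)) {
    if (lab[i] != 0L) { i <- i + 1L; next }
    x1 <- ord[i, 1]; y <- ord[i, 2]
    done <- FALSE
    for (w in pa(x1)) {
      if (lab[edge_idx(w, x1)] != 1L) next
      if (!(w %in% pa(y))) {
        for (z in pa(y)) lab[edge_idx(z, y)] <- 1L
        done <- TRUE
        break
      } else {
        lab[edge_idx(w, y)] <- 1L
      }
    }
    if (!done) {
      z_exists <- any(vapply(pa(y), function(z) {
        z != x1 && !(z %in% pa(x1))
      }, logical(1)))
      for (z in pa(y)) {
        jdx <- edge_idx(z, y)
        if (lab[jdx] == 0L) lab[jdx] <- if (z_exists) 1L else -1L
      }
    }
    i <- i + 1L
  }
  out <- A
  rev_idx <- which(lab == -1L)
  for (r in rev_idx) out[ord[r, 2], ord[r, 1]] <- 1L
  structure(out, class = c("cpdag", "matrix", "array"))
}

#' @export
print.cpdag <- function(x, ...) {
  nodes <- colnames(x)
  dir_e <- und_e <- character(0)
  for (j in seq_along(nodes)) for (k in seq_along(nodes)) {
    if (x[j, k] == 1L && x[k, j] == 1L && j < k) {
      und_e <- c(und_e, paste(nodes[j], "-", nodes[k]))
    } else if (x[j, k] == 1L && x[k, j] == 0L) {
      dir_e <- c(dir_e, paste(nodes[j], "->", nodes[k]))
    }
  }
  cat(sprintf("<cpdag> %d directed, %d undirected edge(s)\n",
              length(dir_e), length(und_e)))
  if (length(dir_e)) cat(" ", paste(dir_e, collapse = "; "), "\n")
  if (length(und_e)) cat(" ", paste(und_e, collapse = "; "), "\n")
  invisible(x)
}

#' Structural Hamming distance between two CPDAGs
#'
#' Number of node pairs whose edge status (absent, undirected, or a specific
#' direction) differs between two partially directed graphs.
#'
#' @param a,b `cpdag` objects or adjacency matrices over the same nodes.
#' @return Nonnegative integer.
#' @export
shd <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  stopifnot(identical(dim(a), dim(b)))
  d <- 0L
  m <- ncol(a)
  for (j in seq_len(m - 1L)) for (k in (j + 1L):m) {
    sa <- c(a[j, k], a[k, j]); sb <- c(b[j, k], b[k, j])
    if (!identical(sa, sb)) d <- d + 1L
  }
  d
}

#' Bootstrap CPDAG edge frequencies
#'
#' Refits the latent DAG on bootstrap resamples of the records, converts
#' each fit to its CPDAG, and accumulates directed-edge frequencies with an
#' undirected edge contributing 0.5 to each direction. The point-estimate
#' CPDAG comes from a fit on the full data.
#'
#' @inheritParams osem_fit
#' @param B number of bootstrap resamples (500 is a common choice for stability heatmaps).
#' @param ... further arguments passed to [osem_fit()].
#' @return Object of class `cpdag_summary`: list with `cpdag` (point
#'   estimate), `edge_frequency` (m x m matrix of directed-edge bootstrap
#'   proportions), `B`, `B_effective` (resamples that fit successfully), and
#'   `failures`.
#' @export
bootstrap_cpdag <- function(data, B = 500L, K = 5L, lambda = 6, seed = NULL,
                            ...) {
  stopifnot(B >= 1L)
  data <- if (inherits(data, "ordinal_dataset")) data else ordinal_dataset(data)
  nodes <- colnames(data)
  m <- length(nodes)
  with_seed(seed, {
    fit0 <- osem_fit(data, K = K, lambda = lambda,
                     seed = sample.int(2^31 - 1L, 1L), ...)
    point <- dag_to_cpdag(fit0)
    freq <- matrix(0, m, m, dimnames = list(nodes, nodes))
    ok <- 0L
    failures <- character(0)
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(data), replace = TRUE)
      sub_seed <- sample.int(2^31 - 1L, 1L)
      cp <- tryCatch({
        fit <- osem_fit(ordinal_dataset(data[idx, , drop = FALSE]),
                        K = K, lambda = lambda, seed = sub_seed, ...)
        unclass(dag_to_cpdag(fit))[nodes, nodes]
      }, error = function(e) e)
      if (inherits(cp, "error")) {
        failures <- c(failures, conditionMessage(cp))
        next
      }
      ok <- ok + 1L
      und <- cp == 1L & t(cp) == 1L
      freq <- freq + cp * (1 - und) + 0.5 * und
    }
    if (ok == 0L) stop_named("bootstrap_cpdag: every resample failed")
    structure(
      list(cpdag = point, edge_frequency = freq / ok, B = B,
           B_effective = ok, failures = failures, point_fit = fit0),
      class = "cpdag_summary"
    )
  })
}

#' @export
print.cpdag_summary <- function(x, ...) {
  cat(sprintf("<cpdag_summary> B = %d (effective %d)\n", x$B, x$B_effective))
  print(x$cpdag)
  cat("directed-edge bootstrap frequencies:\n")
  print(round(x$edge_frequency, 3))
  invisible(x)
}
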