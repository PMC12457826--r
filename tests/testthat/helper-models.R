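# Shared fixtures: small latent DAG models and an independent brute-force
# Markov-equivalence oracle used to cross-check dag_to_cpdag().

equi_thresholds <- function(L) c(-Inf, qnorm(seq_len(L - 1L) / L), Inf)

# Chain X1 -> X2 -> ... -> Xm with common raw coefficient b, standardized
# to unit marginal variances.
make_chain <- function(m = 3L, b = 0.8, L = 3L) {
  nodes <- paste0("X", seq_len(m))
  parents <- c(list(character(0)), as.list(nodes[-m]))
  names(parents) <- nodes
  coef <- lapply(seq_len(m), function(k) {
    if (k == 1L) stats::setNames(numeric(0), character(0))
    else stats::setNames(b, nodes[k - 1L])
  })
  names(coef) <- nodes
  thr <- stats::setNames(rep(list(equi_thresholds(L)), m), nodes)
  ordinalcausal:::standardize_latent_dag(
    latent_dag(nodes, parents, coef, thresholds = thr))
}

# Collider X1 -> X3 <- X2.
make_collider <- function(b1 = 0.8, b2 = 0.8, L = 3L) {
  nodes <- c("X1", "X2", "X3")
  thr <- stats::setNames(rep(list(equi_thresholds(L)), 3), nodes)
  ordinalcausal:::standardize_latent_dag(latent_dag(
    nodes,
    parents = list(X1 = character(0), X2 = character(0), X3 = c("X1", "X2")),
    coef = list(X1 = stats::setNames(numeric(0), character(0)),
                X2 = stats::setNames(numeric(0), character(0)),
                X3 = c(X1 = b1, X2 = b2)),
    thresholds = thr))
}

# All v-structures (unshielded colliders) of a DAG adjacency, as a sorted
# character key set.
vstructure_keys <- function(A) {
  nodes <- colnames(A)
  keys <- character(0)
  for (y in seq_along(nodes)) {
    pa <- which(A[, y] == 1L)
    if (length(pa) < 2L) next
    for (a in seq_along(pa)) for (b in seq_along(pa)) {
      if (a >= b) next
      j <- pa[a]; k <- pa[b]
      if (A[j, k] == 0L && A[k, j] == 0L) {
        keys <- c(keys, paste(sort(c(nodes[j], nodes[k]))[1],
                              sort(c(nodes[j], nodes[k]))[2],
                              nodes[y], sep = "|"))
      }
    }
  }
  sort(keys)
}

# Brute-force CPDAG: enumerate every orientation of the skeleton, keep the
# acyclic ones with identical v-structures, and mark an edge direction
# compelled iff all class members agree. Feasible for small graphs only.
brute_force_cpdag <- function(A) {
  nodes <- colnames(A)
  m <- length(nodes)
  sk <- which(A == 1L | t(A) == 1L, arr.ind = TRUE)
  sk <- sk[sk[, 1] < sk[, 2], , drop = FALSE]
  E <- nrow(sk)
  target_v <- vstructure_keys(A)
  out <- matrix(0L, m, m, dimnames = dimnames(A))
  seen <- NULL
  for (mask in 0:(2^E - 1)) {
    B <- matrix(0L, m, m, dimnames = dimnames(A))
    for (e in seq_len(E)) {
      if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) > 0) {
        B[sk[e, 1], sk[e, 2]] <- 1L
      } else {
        B[sk[e, 2], sk[e, 1]] <- 1L
      }
    }
    if (is.null(ordinalcausal:::topological_order(B))) next
    if (!identical(vstructure_keys(B), target_v)) next
    seen <- if (is.null(seen)) B else seen + B
  }
  # union of directions over the class: agreement = compelled, else undirected
  (seen > 0L) * 1L
}
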