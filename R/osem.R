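# Structural-EM learning of a latent Gaussian DAG from ordinal data.

# Bin bounds implied by observed levels: n x m matrices of lower/upper
# thresholds for each record's latent value.
bin_bounds <- function(data, thresholds) {
  nodes <- colnames(data)
  lo <- hi <- matrix(0, nrow(data), ncol(data), dimnames = dimnames(data))
  for (k in nodes) {
    a <- thresholds[[k]]
    lev <- data[, k] + 1L
    if (any(lev + 1L > length(a))) {
      stop_named("bin_bounds: level codes of '%s' exceed threshold bins", k)
    }
    lo[, k] <- a[lev]
    hi[, k] <- a[lev + 1L]
  }
  list(lo = lo, hi = hi)
}

# One systematic-scan Gibbs sweep over nodes. Omega is the latent precision;
# full conditionals are univariate truncated normals.
gibbs_sweep <- function(Y, Omega, lo, hi) {
  for (k in seq_len(ncol(Y))) {
    w <- Omega[-k, k] / Omega[k, k]
    mu <- -drop(Y[, -k, drop = FALSE] %*% w)
    s <- 1 / sqrt(Omega[k, k])
    Y[, k] <- rtruncnorm_inv(nrow(Y), mean = mu, sd = s, lo = lo[, k], hi = hi[, k])
  }
  Y
}

#' Monte-Carlo completion of the latent variables
#'
#' Draws `K` imputations of the latent Gaussian matrix conditional on every
#' latent value lying in the threshold bin of its observed ordinal level,
#' by systematic-scan Gibbs sampling with exact univariate truncated-normal
#' full conditionals.
#'
#' @param data an [ordinal_dataset] (or 0-based integer matrix).
#' @param model a [latent_dag] whose `thresholds` cover the observed levels.
#' @param K number of completions (default 5).
#' @param seed RNG seed; identical seeds give identical completions.
#' @param burnin Gibbs sweeps between stored completions (default 5).
#' @param init optional n x m start matrix (e.g. the previous EM state);
#'   defaults to independent truncated standard normals per bin.
#' @return List of `K` numeric n x m matrices; the final sampler state is
#'   attached as attribute `"state"`.
#' @export
sample_latent_completion <- function(data, model, K = 5L, seed = NULL,
                                     burnin = 5L, init = NULL) {
  data <- if (inherits(data, "ordinal_dataset")) data else ordinal_dataset(data)
  data <- data[, model$nodes, drop = FALSE]
  S <- implied_covariance(model)
  if (!all(is.finite(S))) stop_named("sample_latent_completion: non-finite covariance")
  Omega <- chol2inv(chol(S))
  b <- bin_bounds(data, model$thresholds)
  with_seed(seed, {
    Y <- init
    if (is.null(Y)) {
      Y <- matrix(rtruncnorm_inv(length(b$lo), 0, 1, b$lo, b$hi),
                  nrow(data), ncol(data), dimnames = dimnames(data))
    }
    out <- vector("list", K)
    for (j in seq_len(K)) {
      for (s in seq_len(burnin)) Y <- gibbs_sweep(Y, Omega, b$lo, b$hi)
      out[[j]] <- Y
    }
    attr(out, "state") <- Y
    out
  })
}

# Pooled (across completions) cross-product matrix of [1, Y].
pooled_crossprod <- function(completions) {
  Xs <- lapply(completions, function(Y) crossprod(cbind(1, Y)))
  C <- Reduce(`+`, Xs) / length(completions)
  dimnames(C) <- list(c("(Intercept)", colnames(completions[[1]])),
                      c("(Intercept)", colnames(completions[[1]])))
  C
}

# Node score from pooled cross-moments: maximized expected Gaussian
# log-likelihood of node k given `parents`, minus lambda * (|pa| + 2) * log(n)/2.
node_score_C <- function(C, k, parents, lambda, n) {
  p <- c("(Intercept)", parents)
  beta <- tryCatch(
    solve(C[p, p, drop = FALSE], C[p, k]),
    error = function(e) {
      warning(sprintf("node_score: singular design for '%s'; ridge fallback", k),
              call. = FALSE)
      solve(C[p, p, drop = FALSE] + diag(1e-8, length(p)), C[p, k])
    })
  rss <- C[k, k] - drop(crossprod(beta, C[p, k]))
  sigma2 <- max(rss / n, 1e-12)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  loglik - lambda * (length(parents) + 2) * log(n) / 2
}

#' Penalized node score on completed data
#'
#' Decomposable score of one node given a candidate parent set: the
#' maximized Gaussian log-likelihood of the least-squares fit, pooled over
#' the Monte-Carlo completions, minus a penalty
#' `lambda * (|parents| + 2) * log(n) / 2` (slopes + intercept + variance).
#'
#' @param completions list of completed latent matrices (from
#'   [sample_latent_completion()]).
#' @param k node name.
#' @param parents character vector of candidate parents.
#' @param lambda penalty coefficient (default 6).
#' @return Scalar score; the total graph score is the sum over nodes.
#' @export
node_score <- function(completions, k, parents, lambda = 6) {
  C <- pooled_crossprod(completions)
  node_score_C(C, k, parents, lambda, nrow(completions[[1]]))
}

# TRUE iff adding edge j -> k to adjacency A keeps it acyclic.
addition_keeps_acyclic <- function(A, j, k) {
  # cycle iff a directed path k ~> j already exists
  m <- ncol(A)
  reach <- logical(m)
  stack <- k
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == j) return(FALSE)
    nxt <- which(A[v, ] == 1L & !reach)
    reach[nxt] <- TRUE
    stack <- c(stack, nxt)
  }
  TRUE
}

# Greedy hill climbing over add/delete/reverse moves on the pooled score.
structure_search_C <- function(C, lambda, n, nodes, max_parents = Inf,
                               start = NULL) {
  m <- length(nodes)
  A <- start %||% matrix(0L, m, m, dimnames = list(nodes, nodes))
  sc <- vapply(seq_len(m), function(k) {
    node_score_C(C, nodes[k], nodes[A[, k] == 1L], lambda, n)
  }, numeric(1))
  repeat {
    best <- list(gain = 1e-10, move = NULL)
    for (j in seq_len(m)) for (k in seq_len(m)) {
      if (j == k) next
      if (A[j, k] == 0L && A[k, j] == 0L) {
        # addition j -> k
        if (sum(A[, k]) >= max_parents) next
        if (!addition_keeps_acyclic(A, j, k)) next
        g <- node_score_C(C, nodes[k], nodes[c(which(A[, k] == 1L), j)],
                          lambda, n) - sc[k]
        if (g > best$gain + 1e-12) best <- list(gain = g, move = c(1L, j, k))
      } else if (A[j, k] == 1L) {
        # deletion j -> k
        g <- node_score_C(C, nodes[k], nodes[setdiff(which(A[, k] == 1L), j)],
                          lambda, n) - sc[k]
        if (g > best$gain + 1e-12) best <- list(gain = g, move = c(2L, j, k))
        # reversal j -> k  =>  k -> j
        if (sum(A[, j]) < max_parents) {
          A2 <- A; A2[j, k] <- 0L
          if (addition_keeps_acyclic(A2, k, j)) {
            g2 <- node_score_C(C, nodes[k], nodes[setdiff(which(A[, k] == 1L), j)],
                               lambda, n) - sc[k] +
                  node_score_C(C, nodes[j], nodes[c(which(A[, j] == 1L), k)],
                               lambda, n) - sc[j]
            if (g2 > best$gain + 1e-12) best <- list(gain = g2, move = c(3L, j, k))
          }
        }
      }
    }
    if (is.null(best$move)) break
    mv <- best$move
    j <- mv[2]; k <- mv[3]
    if (mv[1] == 1L) {
      A[j, k] <- 1L
    } else if (mv[1] == 2L) {
      A[j, k] <- 0L
    } else {
      A[j, k] <- 0L; A[k, j] <- 1L
      sc[j] <- node_score_C(C, nodes[j], nodes[A[, j] == 1L], lambda, n)
    }
    sc[k] <- node_score_C(C, nodes[k], nodes[A[, k] == 1L], lambda, n)
  }
  list(adjacency = A, score = sum(sc))
}

#' Greedy structure search on completed latent data
#'
#' Hill climbing over single-edge additions, deletions and reversals that
#' maximizes the total penalized score, with acyclicity enforced and
#' lexicographic tie-breaking (first improving move in source-then-target
#' order wins among equal gains), so the search is deterministic.
#'
#' @inheritParams node_score
#' @param max_parents optional cap on parent-set size.
#' @param start optional starting adjacency (default: empty graph).
#' @return List with `adjacency` (0/1 matrix, `A[j,k]=1` iff j -> k) and
#'   `score` (total penalized score at the local optimum).
#' @export
structure_search <- function(completions, lambda = 6, max_parents = Inf,
                             start = NULL) {
  C <- pooled_crossprod(completions)
  structure_search_C(C, lambda, nrow(completions[[1]]),
                     colnames(completions[[1]]), max_parents, start)
}

# Refit node parameters from pooled moments for a given adjacency.
refit_parameters <- function(C, A, nodes, n, thresholds) {
  parents <- coef <- stats::setNames(vector("list", length(nodes)), nodes)
  vars <- means <- stats::setNames(numeric(length(nodes)), nodes)
  for (k in nodes) {
    pa <- nodes[A[, k] == 1L]
    p <- c("(Intercept)", pa)
    beta <- solve(C[p, p, drop = FALSE] + diag(1e-10, length(p)), C[p, k])
    rss <- C[k, k] - drop(crossprod(beta, C[p, k]))
    parents[[k]] <- pa
    coef[[k]] <- stats::setNames(beta[-1] * 1, pa)
    vars[[k]] <- max(rss / n, 1e-8)
    means[[k]] <- C["(Intercept)", k] / n
  }
  latent_dag(nodes, parents, coef, means, vars, thresholds)
}

#' Fit a latent Gaussian DAG to ordinal data by structural EM
#'
#' Alternates a Monte-Carlo E-step ([sample_latent_completion()]) with an
#' M-step (greedy [structure_search()] plus per-node least-squares refits),
#' keeping the latent scale identified by standardizing all latents to zero
#' mean and unit marginal variance after each M-step. Thresholds are
#' estimated once from the marginal level frequencies on the probit scale
#' and held fixed.
#'
#' @param data an [ordinal_dataset], 0-based integer matrix, or data.frame
#'   of level codes; every column needs >= 2 occupied levels.
#' @param K Monte-Carlo completions per E-step (default 5).
#' @param lambda score penalty coefficient (default 6).
#' @param max_iter maximum EM iterations (default 50).
#' @param tol absolute total-score change declaring convergence (default
#'   1e-4); because the E-step is Monte Carlo, the fit also stops when the
#'   structure is unchanged for two consecutive iterations.
#' @param seed RNG seed; identical seeds give identical fits.
#' @param burnin Gibbs sweeps per stored completion.
#' @param max_parents optional cap on parent-set size.
#' @return A [latent_dag] with attribute `"osem"`: list with `converged`,
#'   `iterations`, and `score`.
#' @export
osem_fit <- function(data, K = 5L, lambda = 6, max_iter = 50L, tol = 1e-4,
                     seed = NULL, burnin = 5L, max_parents = Inf) {
  data <- if (inherits(data, "ordinal_dataset")) data else ordinal_dataset(data)
  nodes <- colnames(data)
  n <- nrow(data)
  thresholds <- lapply(stats::setNames(nodes, nodes), function(k) {
    lev <- data[, k]
    if (length(unique(lev)) < 2L) {
      stop_named("osem_fit: column '%s' has a single occupied level", k)
    }
    estimate_thresholds(lev)
  })
  # collapse level codes where estimate_thresholds dropped empty bins
  for (k in nodes) {
    L <- length(thresholds[[k]]) - 1L
    if (max(data[, k]) + 1L > L) {
      data[, k] <- as.integer(factor(data[, k])) - 1L
    }
  }
  model <- latent_dag(nodes,
                      parents = stats::setNames(rep(list(character(0)), length(nodes)), nodes),
                      coef = stats::setNames(rep(list(stats::setNames(numeric(0), character(0)))
                                                 , length(nodes)), nodes),
                      thresholds = thresholds)
  with_seed(seed, {
    state <- NULL
    prev_adj <- NULL
    prev_score <- -Inf
    stable <- 0L
    converged <- FALSE
    iter <- 0L
    score <- NA_real_
    while (iter < max_iter) {
      iter <- iter + 1L
      comps <- sample_latent_completion(data, model, K = K, burnin = burnin,
                                        init = state)
      state <- attr(comps, "state")
      C <- pooled_crossprod(comps)
      hc <- structure_search_C(C, lambda, n, nodes, max_parents,
                               start = prev_adj)
      model <- standardize_latent_dag(
        refit_parameters(C, hc$adjacency, nodes, n, thresholds))
      score <- hc$score
      if (!is.null(prev_adj) && identical(hc$adjacency, prev_adj)) {
        stable <- stable + 1L
      } else {
        stable <- 0L
      }
      if (abs(score - prev_score) < tol || stable >= 2L) {
        converged <- TRUE
        break
      }
      prev_adj <- hc$adjacency
      prev_score <- score
    }
    if (!converged) {
      warning("osem_fit: EM did not converge; returning last iterate", call. = FALSE)
    }
    attr(model, "osem") <- list(converged = converged, iterations = iter,
                                score = score)
    model
  })
}
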