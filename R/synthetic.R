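# Seeded generators: random DAGs, latent simulation, discretization, and a
# training-log-like table for end-to-end tests without any external data.

#' Random DAG adjacency
#'
#' Draws a uniformly random topological order and includes each forward edge
#' independently with probability `edge_probability`, so the result is
#' acyclic by construction.
#'
#' @param m number of nodes.
#' @param edge_probability probability of each forward edge, in `[0, 1]`.
#' @param seed RNG seed.
#' @param nodes optional node names (default `X1..Xm`).
#' @return 0/1 adjacency matrix (`A[j,k]=1` iff j -> k).
#' @export
random_dag <- function(m, edge_probability = 0.3, seed = NULL, nodes = NULL) {
  stopifnot(edge_probability >= 0, edge_probability <= 1, m >= 1)
  nodes <- nodes %||% paste0("X", seq_len(m))
  with_seed(seed, {
    ord <- sample(m)
    A <- matrix(0L, m, m, dimnames = list(nodes, nodes))
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      if (runif(1) < edge_probability) A[ord[a], ord[b]] <- 1L
    }
    A
  })
}

#' Random latent Gaussian DAG model
#'
#' Builds a fully parameterized [latent_dag] on a random structure: edge
#' coefficients drawn uniformly from `[-hi, -lo] U [lo, hi]` (avoiding
#' near-null edges), unit conditional variances, then standardized to unit
#' marginal variances, with thresholds at equiprobable probit cut points.
#'
#' @inheritParams random_dag
#' @param n_levels integer (recycled): ordinal levels per node, >= 2.
#' @param coef_range positive two-vector `(lo, hi)` of coefficient magnitudes.
#' @return A [latent_dag] with thresholds.
#' @export
random_latent_dag <- function(m, edge_probability = 0.3, n_levels = 3L,
                              coef_range = c(0.3, 0.9), seed = NULL,
                              nodes = NULL) {
  n_levels <- rep_len(as.integer(n_levels), m)
  with_seed(seed, {
    A <- random_dag(m, edge_probability, seed = NULL, nodes = nodes)
    nodes <- colnames(A)
    parents <- coef <- stats::setNames(vector("list", m), nodes)
    for (k in seq_len(m)) {
      pa <- nodes[A[, k] == 1L]
      parents[[nodes[k]]] <- pa
      b <- runif(length(pa), coef_range[1], coef_range[2]) *
        sample(c(-1, 1), length(pa), replace = TRUE)
      coef[[nodes[k]]] <- stats::setNames(b, pa)
    }
    thresholds <- stats::setNames(lapply(seq_len(m), function(k) {
      L <- n_levels[k]
      c(-Inf, qnorm(seq_len(L - 1L) / L), Inf)
    }), nodes)
    standardize_latent_dag(
      latent_dag(nodes, parents, coef, thresholds = thresholds))
  })
}

#' Simulate latent Gaussian data from a DAG model
#'
#' Ancestral sampling of the linear-Gaussian structural equations; the
#' sample covariance converges to [implied_covariance()].
#'
#' @param model a [latent_dag].
#' @param n number of records.
#' @param seed RNG seed.
#' @return n x m numeric matrix.
#' @export
simulate_latent <- function(model, n, seed = NULL) {
  ord <- topological_order(model)
  with_seed(seed, {
    Y <- matrix(0, n, length(model$nodes),
                dimnames = list(NULL, model$nodes))
    for (k in ord) {
      pa <- model$parents[[k]]
      mu <- model$means[[k]]
      if (length(pa)) {
        mu <- mu + drop((Y[, pa, drop = FALSE] -
                           matrix(model$means[pa], n, length(pa), byrow = TRUE)) %*%
                          model$coef[[k]])
      }
      Y[, k] <- mu + rnorm(n, 0, sqrt(model$vars[[k]]))
    }
    Y
  })
}

#' Discretize latent data at model thresholds
#'
#' Maps each latent value to its 0-based ordinal level with left-closed
#' upper bins: level `l` iff `alpha(k, l) <= y < alpha(k, l+1)`.
#'
#' @param Y numeric matrix of latent values.
#' @param thresholds named list of threshold vectors (with `-Inf`/`Inf`
#'   endpoints), or a [latent_dag] carrying them.
#' @return An [ordinal_dataset].
#' @export
discretize_latent <- function(Y, thresholds) {
  if (inherits(thresholds, "latent_dag")) thresholds <- thresholds$thresholds
  X <- Y
  for (k in colnames(Y)) {
    a <- thresholds[[k]]
    X[, k] <- findInterval(Y[, k], a[-c(1L, length(a))])
  }
  ordinal_dataset(X, n_levels = vapply(thresholds[colnames(Y)], length, 1L) - 1L)
}

#' Simulate an ordinal dataset from a latent DAG
#'
#' Convenience wrapper: [simulate_latent()] then [discretize_latent()].
#'
#' @inheritParams simulate_latent
#' @return An [ordinal_dataset]; the latent matrix is in attribute `"latent"`.
#' @export
simulate_ordinal <- function(model, n, seed = NULL) {
  Y <- simulate_latent(model, n, seed)
  X <- discretize_latent(Y, model$thresholds)
  attr(X, "latent") <- Y
  X
}

#' Synthetic training-log table
#'
#' Generates a table shaped like a daily endurance-training log: session
#' counts, kilometre volumes with heavy spikes at zero (point mass at 0 plus
#' a lognormal tail), bounded self-ratings, binary flags, and a rare binary
#' injury outcome weakly driven by sprint volume and poor recovery. Columns
#' 1, 6 and 11 are natively ordinal; the rest are continuous and meant for
#' quantile-threshold discretization. Entirely synthetic: it emulates the
#' schema and marginal shapes of such logs, not any real athletes.
#'
#' @param n number of records.
#' @param seed RNG seed.
#' @param zero_inflation named numeric vector of zero-mass weights for the
#'   spiked continuous columns; defaults mimic sparse high-intensity
#'   training days.
#' @return data.frame with 11 columns; attribute `"column_types"` is a named
#'   character vector `"ordinal"`/`"continuous"`.
#' @export
make_training_log_like <- function(n = 2000L, seed = NULL,
                                   zero_inflation = c(kmmiddle = 0.93,
                                                      kmhigh = 0.92,
                                                      kmsprinting = 0.90,
                                                      hoursalternative = 0.90)) {
  zi <- c(kmmiddle = 0.93, kmhigh = 0.92, kmsprinting = 0.90,
          hoursalternative = 0.90)
  zi[names(zero_inflation)] <- zero_inflation
  spike <- function(w, meanlog, sdlog) {
    z <- runif(n) < w
    ifelse(z, 0, stats::rlnorm(n, meanlog, sdlog))
  }
  with_seed(seed, {
    sessions <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.55, 0.15))
    totalkm <- ifelse(sessions == 0, 0,
                      pmax(0, rnorm(n, 8 + 4 * sessions, 4)))
    kmmiddle <- spike(zi[["kmmiddle"]], log(6), 0.5)
    kmhigh <- spike(zi[["kmhigh"]], log(4), 0.6)
    kmsprinting <- spike(zi[["kmsprinting"]], log(0.6), 0.9)
    strengthtraining <- rbinom(n, 1, 0.2)
    perceivedtrainingsuccess <- ifelse(
      sessions == 0, 0,
      pmin(1, pmax(0, rnorm(n, 0.6 + 0.1 * strengthtraining, 0.15))))
    hoursalternative <- spike(zi[["hoursalternative"]], log(1.2), 0.6)
    perceivedexertion <- ifelse(sessions == 0, 0,
                                pmin(1, pmax(0, rnorm(n, 0.35 + 0.02 * totalkm, 0.15))))
    perceivedrecovery <- ifelse(sessions == 0, 0,
                                pmin(1, pmax(0, rnorm(n, 0.5 - 0.2 * perceivedexertion, 0.15))))
    lin <- -3.4 + 0.5 * kmsprinting - 1.2 * perceivedrecovery
    injury <- rbinom(n, 1, stats::plogis(lin))
    out <- data.frame(sessions, totalkm, kmmiddle, kmhigh, kmsprinting,
                      strengthtraining, perceivedtrainingsuccess,
                      hoursalternative, perceivedexertion, perceivedrecovery,
                      injury)
    attr(out, "column_types") <- c(
      sessions = "ordinal", totalkm = "continuous", kmmiddle = "continuous",
      kmhigh = "continuous", kmsprinting = "continuous",
      strengthtraining = "ordinal", perceivedtrainingsuccess = "continuous",
      hoursalternative = "continuous", perceivedexertion = "continuous",
      perceivedrecovery = "continuous", injury = "ordinal")
    out
  })
}
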