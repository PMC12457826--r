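# Ordinal causal effects under interval interventions on latent variables.

#' Mutilate a latent DAG for an intervention
#'
#' Implements the do-operator at the graph level: removes every edge into
#' the intervened node and replaces its mechanism by its standardized
#' observational marginal; all other mechanisms are unchanged.
#'
#' @param model a [latent_dag].
#' @param i name of the intervention node.
#' @return A [latent_dag] with `pa(i)` empty.
#' @export
mutilate <- function(model, i) {
  stopifnot(inherits(model, "latent_dag"), i %in% model$nodes)
  S <- implied_covariance(model)
  model$parents[[i]] <- character(0)
  model$coef[[i]] <- stats::setNames(numeric(0), character(0))
  model$vars[[i]] <- S[i, i]
  model
}

# P[l1 < Y1 <= u1, l2 < Y2 <= u2] for centered bivariate normal with
# variances s11, s22 and covariance s12, via the conditioning integral
# P = Int_{l1}^{u1} phi(y; s11) [Phi((u2 - b y)/s) - Phi((l2 - b y)/s)] dy.
bvn_rect <- function(l1, u1, l2, u2, s11, s22, s12, abs_tol = 1e-12) {
  sd1 <- sqrt(s11)
  if (s12 == 0) {
    return((pnorm(u1, 0, sd1) - pnorm(l1, 0, sd1)) *
             (pnorm(u2, 0, sqrt(s22)) - pnorm(l2, 0, sqrt(s22))))
  }
  beta <- s12 / s11
  cvar <- s22 - s12^2 / s11
  if (cvar <= 1e-12 * s22) {
    warning("bvn_rect: near-degenerate correlation; perturbing", call. = FALSE)
    cvar <- 1e-12 * s22
  }
  cs <- sqrt(cvar)
  f <- function(y) {
    dnorm(y, 0, sd1) * (pnorm((u2 - beta * y) / cs) - pnorm((l2 - beta * y) / cs))
  }
  stats::integrate(f, l1, u1, abs.tol = abs_tol, rel.tol = 1e-10,
                   subdivisions = 500L)$value
}

#' Interventional bin probability
#'
#' Probability that the outcome's latent variable falls in the threshold bin
#' of level `k` when the intervention node's latent variable is forced into
#' the bin of level `l`:
#' \deqn{P\big[Y_o \in [\alpha(o,k), \alpha(o,k+1)) \mid
#'       do(Y_i \in [\alpha(i,l), \alpha(i,l+1)))\big],}
#' computed analytically from bivariate-normal rectangle probabilities under
#' the mutilated graph (the intervened latent is drawn from its standardized
#' marginal truncated to the bin). Levels are 0-based.
#'
#' @param model a fitted [latent_dag] with thresholds.
#' @param i,o intervention and outcome node names (`i != o`).
#' @param outcome_level 0-based level `k` of the outcome.
#' @param intervention_level 0-based level `l` the intervention forces.
#' @return Probability in `[0, 1]`; over all outcome levels these sum to 1.
#' @export
interventional_bin_probability <- function(model, i, o, outcome_level,
                                           intervention_level) {
  check_intervention(model, i, o, outcome_level, intervention_level)
  mut <- mutilate(model, i)
  S <- implied_covariance(mut)
  ai <- model$thresholds[[i]]
  ao <- model$thresholds[[o]]
  l <- intervention_level; k <- outcome_level
  denom <- pnorm(ai[l + 2L], 0, sqrt(S[i, i])) - pnorm(ai[l + 1L], 0, sqrt(S[i, i]))
  if (denom < 1e-300) {
    stop_named("interventional_bin_probability: intervention bin %d of '%s' has zero probability",
               l, i)
  }
  num <- bvn_rect(ai[l + 1L], ai[l + 2L], ao[k + 1L], ao[k + 2L],
                  S[i, i], S[o, o], S[i, o])
  min(max(num / denom, 0), 1)
}

check_intervention <- function(model, i, o, outcome_level, intervention_level,
                               to_level = NULL) {
  stopifnot(inherits(model, "latent_dag"))
  if (is.null(model$thresholds)) stop_named("model has no thresholds")
  if (!(i %in% model$nodes) || !(o %in% model$nodes)) {
    stop_named("unknown node(s): %s, %s", i, o)
  }
  if (i == o) stop_named("intervention and outcome must differ")
  Li <- length(model$thresholds[[i]]) - 1L
  Lo <- length(model$thresholds[[o]]) - 1L
  if (outcome_level < 0L || outcome_level >= Lo) {
    stop_named("outcome level %d outside 0..%d", outcome_level, Lo - 1L)
  }
  bad <- c(intervention_level, to_level)
  if (any(bad < 0L | bad >= Li)) {
    stop_named("intervention level outside 0..%d", Li - 1L)
  }
  invisible(TRUE)
}

#' Ordinal causal effect of an interval intervention shift
#'
#' The change in the probability that the outcome occupies level `k` when
#' the intervention variable is forced from level `from` to level `to`:
#' \deqn{OCE_{io}(k, l \to l') = P[X_o = k \mid do(X_i = l')] -
#'       P[X_o = k \mid do(X_i = l)].}
#' Antisymmetric in `(from, to)`; sums to 0 over outcome levels; identically
#' 0 when the mutilated graph has no directed path from `i` to `o`.
#'
#' @inheritParams interventional_bin_probability
#' @param from,to 0-based intervention levels, `from != to`.
#' @return Value in `[-1, 1]`.
#' @export
oce <- function(model, i, o, outcome_level, from, to) {
  if (from == to) stop_named("oce: 'from' and 'to' levels must differ")
  check_intervention(model, i, o, outcome_level, from, to_level = to)
  interventional_bin_probability(model, i, o, outcome_level, to) -
    interventional_bin_probability(model, i, o, outcome_level, from)
}

#' Full OCE table for one intervention-outcome pair
#'
#' All combinations of outcome level `k` and upward intervention shifts
#' `l -> l'` with `l < l'`, in long form (`L_o * choose(L_i, 2)` rows).
#'
#' @inheritParams interventional_bin_probability
#' @return data.frame of class `oce_table` with columns `intervention`,
#'   `outcome`, `outcome_level`, `from_level`, `to_level`, `value`.
#' @export
oce_matrix <- function(model, i, o) {
  stopifnot(inherits(model, "latent_dag"))
  Li <- length(model$thresholds[[i]]) - 1L
  Lo <- length(model$thresholds[[o]]) - 1L
  # interventional probabilities once per (k, l)
  P <- outer(seq_len(Lo) - 1L, seq_len(Li) - 1L,
             Vectorize(function(k, l) {
               interventional_bin_probability(model, i, o, k, l)
             }))
  rows <- expand.grid(outcome_level = seq_len(Lo) - 1L,
                      from_level = seq_len(Li) - 1L,
                      to_level = seq_len(Li) - 1L)
  rows <- rows[rows$from_level < rows$to_level, , drop = FALSE]
  rows$value <- P[cbind(rows$outcome_level + 1L, rows$to_level + 1L)] -
    P[cbind(rows$outcome_level + 1L, rows$from_level + 1L)]
  out <- data.frame(intervention = i, outcome = o, rows, row.names = NULL)
  class(out) <- c("oce_table", "data.frame")
  out
}

#' Bootstrap distribution of ordinal causal effects
#'
#' Refits the model on bootstrap resamples and recomputes the OCE table per
#' resample, yielding the distribution summarized by raincloud plots (one
#' row per resample and cell) plus per-cell means.
#'
#' @inheritParams osem_fit
#' @param i,o intervention and outcome node names.
#' @param B number of bootstrap resamples.
#' @param ... passed to [osem_fit()].
#' @return List of class `oce_bootstrap`: `draws` (`oce_table` with a
#'   `bootstrap_rep` column), `summary` (per-cell bootstrap means), and
#'   `B_effective`.
#' @export
oce_bootstrap <- function(data, i, o, B = 500L, K = 5L, lambda = 6,
                          seed = NULL, ...) {
  data <- if (inherits(data, "ordinal_dataset")) data else ordinal_dataset(data)
  with_seed(seed, {
    draws <- list()
    ok <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(data), replace = TRUE)
      sub_seed <- sample.int(2^31 - 1L, 1L)
      tab <- tryCatch({
        fit <- osem_fit(ordinal_dataset(data[idx, , drop = FALSE]),
                        K = K, lambda = lambda, seed = sub_seed, ...)
        oce_matrix(fit, i, o)
      }, error = function(e) NULL)
      if (is.null(tab)) next
      ok <- ok + 1L
      tab$bootstrap_rep <- ok
      draws[[ok]] <- tab
    }
    if (ok == 0L) stop_named("oce_bootstrap: every resample failed")
    draws <- do.call(rbind, draws)
    summ <- stats::aggregate(
      value ~ intervention + outcome + outcome_level + from_level + to_level,
      data = draws, FUN = mean)
    names(summ)[names(summ) == "value"] <- "mean_value"
    structure(list(draws = draws, summary = summ, B = B, B_effective = ok),
              class = "oce_bootstrap")
  })
}

# Forward-simulate the mutilated SEM with Y_i truncated to bin `l`;
# returns the n x m latent draws.
simulate_do <- function(model, i, level, n) {
  mut <- mutilate(model, i)
  ord <- topological_order(mut)
  ai <- model$thresholds[[i]]
  Y <- matrix(0, n, length(mut$nodes), dimnames = list(NULL, mut$nodes))
  for (k in ord) {
    if (k == i) {
      Y[, k] <- rtruncnorm_inv(n, 0, sqrt(mut$vars[[k]]),
                               ai[level + 1L], ai[level + 2L])
    } else {
      pa <- mut$parents[[k]]
      mu <- if (length(pa)) drop(Y[, pa, drop = FALSE] %*% mut$coef[[k]]) else 0
      Y[, k] <- mu + rnorm(n, 0, sqrt(mut$vars[[k]]))
    }
  }
  Y
}

#' Monte-Carlo oracle for interventional probabilities and OCE
#'
#' Forward-simulates the mutilated structural equations (the intervened
#' latent drawn from its truncated standardized marginal) and estimates the
#' outcome bin frequencies, with binomial standard errors. This estimator is
#' unbiased and independent of the analytic rectangle-probability route, so
#' it serves as a cross-check.
#'
#' `mc_interventional_probability()` returns the estimated probabilities
#' over all outcome levels for one intervention level; `mc_oracle_oce()`
#' returns the estimated OCE for one shift.
#'
#' @inheritParams oce
#' @param n_draws Monte-Carlo sample size.
#' @param seed RNG seed.
#' @return `mc_interventional_probability()`: list with `p` (vector over
#'   outcome levels) and `se`. `mc_oracle_oce()`: list with `estimate`,
#'   `se`, `p_from`, `p_to`.
#' @export
mc_interventional_probability <- function(model, i, o, intervention_level,
                                          n_draws = 1e5, seed = NULL) {
  check_intervention(model, i, o, 0L, intervention_level)
  ao <- model$thresholds[[o]]
  with_seed(seed, {
    Y <- simulate_do(model, i, intervention_level, n_draws)
    lev <- findInterval(Y[, o], ao[-c(1L, length(ao))])
    counts <- tabulate(lev + 1L, nbins = length(ao) - 1L)
    p <- counts / n_draws
    list(p = p, se = sqrt(p * (1 - p) / n_draws))
  })
}

#' @rdname mc_interventional_probability
#' @param from,to 0-based intervention levels of the shift.
#' @export
mc_oracle_oce <- function(model, i, o, outcome_level, from, to,
                          n_draws = 1e5, seed = NULL) {
  if (from == to) stop_named("mc_oracle_oce: 'from' and 'to' must differ")
  check_intervention(model, i, o, outcome_level, from, to_level = to)
  s <- if (is.null(seed)) NULL else c(seed, seed + 1L)
  a <- mc_interventional_probability(model, i, o, from, n_draws,
                                     if (is.null(s)) NULL else s[1])
  b <- mc_interventional_probability(model, i, o, to, n_draws,
                                     if (is.null(s)) NULL else s[2])
  k1 <- outcome_level + 1L
  list(estimate = b$p[k1] - a$p[k1],
       se = sqrt(a$se[k1]^2 + b$se[k1]^2),
       p_from = a$p[k1], p_to = b$p[k1])
}
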