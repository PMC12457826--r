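# Latent Gaussian DAG machinery: thresholds, completions, scoring, search,
# structural EM, CPDAG conversion, and bootstrap edge frequencies.

test_that("probit threshold estimation matches closed-form quantiles", {
  b <- ordinal_column(rep(c(0L, 1L), each = 50), 2)
  expect_equal(estimate_thresholds(b), c(-Inf, 0, Inf), tolerance = 1e-12)
  tri <- ordinal_column(rep(c(0L, 1L, 2L), times = c(50, 25, 25)), 3)
  expect_equal(estimate_thresholds(tri), c(-Inf, 0, qnorm(0.75), Inf),
               tolerance = 1e-12)
  expect_error(estimate_thresholds(ordinal_column(rep(0L, 10), 1)), "one level")
  expect_warning(a <- estimate_thresholds(c(0L, 0L, 2L, 2L)), "collapsed")
  expect_equal(a, c(-Inf, 0, Inf))
})

test_that("threshold estimator is consistent on simulated no-edge data", {
  model <- random_latent_dag(3, edge_probability = 0, n_levels = 4, seed = 91)
  X <- simulate_ordinal(model, 5000, seed = 92)
  for (k in model$nodes) {
    est <- estimate_thresholds(X[, k])
    truth <- model$thresholds[[k]]
    expect_lt(max(abs(est[is.finite(est)] - truth[is.finite(truth)])), 0.1)
  }
})

test_that("implied covariance matches the structural equations and is positive definite", {
  chain <- make_chain(3, b = 0.8)
  S <- implied_covariance(chain)
  expect_equal(diag(S), stats::setNames(rep(1, 3), chain$nodes), tolerance = 1e-12)
  # correlations of a standardized chain: r, r^2 with r = 0.8/sqrt(1.64)
  r <- 0.8 / sqrt(1.64)
  r23 <- 0.8 * 1.64 / sqrt(1.64 * (0.64 * 1.64 + 1))
  expect_equal(S["X1", "X2"], r, tolerance = 1e-12)
  expect_equal(S["X2", "X3"], r23, tolerance = 1e-12)
  expect_equal(S["X1", "X3"], r * r23, tolerance = 1e-12)
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  # sample covariance of ancestral draws converges to it
  Y <- simulate_latent(chain, 1e5, seed = 93)
  expect_equal(unname(cov(Y)), unname(S), tolerance = 0.02)
  expect_error(latent_dag(c("A", "B"),
                          parents = list(A = "B", B = "A"),
                          coef = list(A = c(B = 1), B = c(A = 1))),
               "cycle")
})

test_that("latent completions respect the observed threshold bins exactly", {
  model <- make_chain(3, b = 0.8)
  X <- simulate_ordinal(model, 400, seed = 94)
  comps <- sample_latent_completion(X, model, K = 5, seed = 95)
  expect_length(comps, 5L)
  for (Y in comps) {
    for (k in model$nodes) {
      a <- model$thresholds[[k]]
      lev <- findInterval(Y[, k], a[-c(1, length(a))])
      expect_equal(lev, unname(X[, k]))
    }
  }
  comps2 <- sample_latent_completion(X, model, K = 5, seed = 95)
  expect_identical(comps, comps2)
})

test_that("single-node completion reproduces the truncated standard normal mean", {
  X <- ordinal_dataset(matrix(1L, 4000, 1, dimnames = list(NULL, "X1")),
                       n_levels = 2L)
  model <- latent_dag("X1", parents = list(X1 = character(0)),
                      coef = list(X1 = stats::setNames(numeric(0), character(0))),
                      thresholds = list(X1 = c(-Inf, 0, Inf)))
  comps <- sample_latent_completion(X, model, K = 3, seed = 96)
  y <- unlist(lapply(comps, function(Y) Y[, 1]))
  expect_true(all(y >= 0))
  expect_lt(abs(mean(y) - sqrt(2 / pi)), 3 * sd(y) / sqrt(length(y)))
})

test_that("node score instantiates the penalized likelihood and is decomposable", {
  set.seed(97)
  n <- 500
  Y <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("A", "B")))
  comps <- list(Y)
  lambda <- 6
  s_empty <- node_score(comps, "A", character(0), lambda)
  sigma2 <- mean((Y[, "A"] - mean(Y[, "A"]))^2)
  ref <- -n / 2 * (log(2 * pi * sigma2) + 1) - lambda * 2 * log(n) / 2
  expect_equal(s_empty, ref, tolerance = 1e-8)
  # decomposability: B's score is unaffected by A's parent set
  sB1 <- node_score(comps, "B", character(0), lambda)
  expect_equal(node_score(comps, "B", character(0), lambda), sB1)
  # adding a null parent at lambda = 6, n = 500 lowers the score nearly always
  worse <- replicate(40, {
    Z <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("A", "B")))
    node_score(list(Z), "A", "B", lambda) < node_score(list(Z), "A", character(0), lambda)
  })
  expect_gte(mean(worse), 0.95)
})

test_that("structure search finds single strong edges, drops null ones, and stays acyclic", {
  set.seed(98)
  n <- 800
  y1 <- rnorm(n)
  y2 <- 0.8 * y1 + rnorm(n, 0, 0.6)
  comps <- list(cbind(X1 = y1, X2 = y2))
  res <- structure_search(comps, lambda = 6)
  expect_equal(sum(res$adjacency), 1L)
  expect_equal(sum(res$adjacency["X1", "X2"] + res$adjacency["X2", "X1"]), 1L)
  ind <- list(cbind(X1 = rnorm(n), X2 = rnorm(n), X3 = rnorm(n)))
  expect_equal(sum(structure_search(ind, lambda = 6)$adjacency), 0L)
  dep <- make_chain(4, b = 0.7)
  comps4 <- list(simulate_latent(dep, 1500, seed = 99))
  A <- structure_search(comps4, lambda = 6)$adjacency
  expect_false(is.null(ordinalcausal:::topological_order(A)))
})

test_that("osem_fit recovers chain structure, is seed-deterministic, and scores decompose", {
  chain <- make_chain(3, b = 0.8)
  X <- simulate_ordinal(chain, 2000, seed = 100)
  fit <- osem_fit(X, seed = 101)
  expect_s3_class(fit, "latent_dag")
  expect_equal(shd(dag_to_cpdag(fit), dag_to_cpdag(chain)), 0L)
  expect_true(attr(fit, "osem")$converged)
  fit2 <- osem_fit(X, seed = 101)
  expect_equal(fit$coef, fit2$coef)
  expect_identical(dag_adjacency(fit), dag_adjacency(fit2))
  # implied covariance of the fit is positive definite
  ev <- eigen(implied_covariance(fit), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_error(osem_fit(cbind(A = rep(0L, 10), B = rep(c(0L, 1L), 5))),
               "single occupied level")
})

test_that("CPDAG recovery improves with sample size (structural Hamming distance)", {
  chain <- make_chain(4, b = 0.8)
  truth <- dag_to_cpdag(chain)
  med_shd <- sapply(c(250, 1000, 4000), function(n) {
    median(sapply(1:5, function(s) {
      X <- simulate_ordinal(chain, n, seed = 200 + 10 * s + n %% 7)
      shd(dag_to_cpdag(osem_fit(X, seed = 300 + s)), truth)
    }))
  })
  expect_true(med_shd[3] <= med_shd[1])
  expect_lte(med_shd[3], 1)
})

test_that("dag_to_cpdag handles canonical cases", {
  # v-structure stays directed
  coll <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  coll["A", "C"] <- 1L; coll["B", "C"] <- 1L
  cp <- dag_to_cpdag(coll)
  expect_equal(unname(cp["A", "C"]), 1L)
  expect_equal(unname(cp["C", "A"]), 0L)
  expect_equal(unname(cp["B", "C"]), 1L)
  # chain becomes fully undirected
  ch <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ch["A", "B"] <- 1L; ch["B", "C"] <- 1L
  cp <- dag_to_cpdag(ch)
  expect_true(all(cp[c(2, 4, 6, 8)] == 1L))
  # single edge undirected
  e <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  e["A", "B"] <- 1L
  cp <- dag_to_cpdag(e)
  expect_equal(unname(cp["B", "A"]), 1L)
})

test_that("dag_to_cpdag agrees with the brute-force equivalence-class oracle", {
  for (s in 1:12) {
    A <- random_dag(4, edge_probability = 0.5, seed = 400 + s)
    expect_identical(unclass(dag_to_cpdag(A)), brute_force_cpdag(A),
                     info = paste("seed", 400 + s))
  }
})

test_that("bootstrap edge frequencies are proper proportions favouring true compelled edges", {
  coll <- make_collider(0.8, 0.8)
  X <- simulate_ordinal(coll, 2000, seed = 500)
  bs <- bootstrap_cpdag(X, B = 50, seed = 501)
  f <- bs$edge_frequency
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(f + t(f) <= 1 + 1e-12))
  expect_equal(bs$B_effective, 50L)
  # compelled collider edges appear in the majority of resamples
  expect_gt(f["X1", "X3"], 0.5)
  expect_gt(f["X2", "X3"], 0.5)
})
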