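#' Fit a Gaussian-kernel density for quantile-threshold discretization
#'
#' Fits the kernel density estimate
#' \deqn{\hat f(x) = \frac{1}{nh}\sum_{i=1}^n K\!\left(\frac{x - x_i}{h}\right)}
#' with the standard normal kernel \eqn{K}. The default bandwidth is the
#' Silverman-type rule of thumb
#' \eqn{h = 0.9\,\min(\hat\sigma, \mathrm{IQR}/1.34)\, n^{-1/5}}.
#'
#' @param values numeric vector of raw measurements (length >= 2, finite).
#' @param name variable name used in messages and reports.
#' @param bandwidth optional positive bandwidth override.
#' @return Object of class `qtf_model` with fields `values`, `name`,
#'   `bandwidth`; thresholds are added by [solve_thresholds()].
#' @seealso [kde_cdf()], [solve_thresholds()], [qtf_discretize()]
#' @export
fit_kde <- function(values, name = "x", bandwidth = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop_named("fit_kde: '%s' needs >= 2 observations", name)
  if (!all(is.finite(values))) stop_named("fit_kde: '%s' has non-finite values", name)
  if (is.null(bandwidth)) {
    if (stats::sd(values) == 0) {
      stop_named(
        "fit_kde: column '%s' has zero variance; supply an explicit bandwidth",
        name)
    }
    bandwidth <- stats::bw.nrd0(values)
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop_named("fit_kde: bandwidth must be a positive number")
  }
  structure(
    list(values = values, name = name, bandwidth = bandwidth,
         thresholds = NULL, n_levels = NULL, start_index = NULL,
         target_fractions = NULL),
    class = "qtf_model"
  )
}

#' @export
print.qtf_model <- function(x, ...) {
  cat(sprintf("<qtf_model> '%s': n = %d, h = %.4g\n",
              x$name, length(x$values), x$bandwidth))
  if (!is.null(x$thresholds)) {
    cat(sprintf("  thresholds (targets %s): %s\n",
                paste(signif(x$target_fractions, 4), collapse = ", "),
                paste(signif(x$thresholds, 6), collapse = ", ")))
  }
  invisible(x)
}

#' Kernel density and CDF evaluation
#'
#' `kde_pdf()` evaluates the fitted mixture density; `kde_cdf()` evaluates
#' its distribution function
#' \eqn{\hat F(x) = \frac{1}{n}\sum_i \Phi\!\left((x - x_i)/h\right)},
#' which is nondecreasing with limits 0 and 1.
#'
#' @param model a `qtf_model` from [fit_kde()].
#' @param x numeric vector of evaluation points.
#' @return Numeric vector of densities / probabilities.
#' @export
kde_cdf <- function(model, x) {
  stopifnot(inherits(model, "qtf_model"))
  vapply(x, function(xx) {
    mean(pnorm((xx - model$values) / model$bandwidth))
  }, numeric(1))
}

#' @rdname kde_cdf
#' @export
kde_pdf <- function(model, x) {
  stopifnot(inherits(model, "qtf_model"))
  vapply(x, function(xx) {
    mean(dnorm((xx - model$values) / model$bandwidth)) / model$bandwidth
  }, numeric(1))
}

#' Solve quantile thresholds on the fitted KDE
#'
#' Finds cut points \eqn{Q_i, \ldots, Q_{i+n-1}} with
#' \eqn{\hat F(Q_j) = j/(n+2)} by bisection, yielding `n + 1` ordered
#' levels. The defaults `n = 2, i = 2` place thresholds at the fitted
#' median and 75th percentile, so a continuous variable splits into
#' levels with nominal mass 0.5 / 0.25 / 0.25.
#'
#' @param model a `qtf_model`.
#' @param n number of thresholds (levels = `n + 1`); default 2.
#' @param i index of the first threshold, so targets are
#'   `i/(n+2), ..., (i+n-1)/(n+2)`; default 2. Requires `i >= 1` and
#'   `i + n - 1 <= n + 1` so all targets lie strictly inside (0, 1).
#' @param tol absolute tolerance on `|F(Q) - target|`; default 1e-9.
#' @return The model with `thresholds`, `n_levels`, `start_index`,
#'   `target_fractions` filled in. Thresholds that coincide within 1e-12
#'   (possible under extreme point masses) are collapsed with a warning and
#'   `n_levels` reduced.
#' @export
solve_thresholds <- function(model, n = 2L, i = 2L, tol = 1e-9) {
  stopifnot(inherits(model, "qtf_model"))
  n <- as.integer(n); i <- as.integer(i)
  if (n < 1L || i < 1L || (i + n - 1L) > (n + 1L)) {
    stop_named("solve_thresholds: need 1 <= i and i+n-1 <= n+1 (got n=%d, i=%d)", n, i)
  }
  targets <- (i:(i + n - 1L)) / (n + 2L)
  h <- model$bandwidth
  lo0 <- min(model$values) - 10 * h
  hi0 <- max(model$values) + 10 * h
  solve_one <- function(p) {
    lo <- lo0; hi <- hi0
    flo <- kde_cdf(model, lo); fhi <- kde_cdf(model, hi)
    if (flo > p || fhi < p) {
      stop_named("solve_thresholds: target %.4g not bracketed for '%s'", p, model$name)
    }
    repeat {
      mid <- (lo + hi) / 2
      fm <- kde_cdf(model, mid)
      if (abs(fm - p) <= tol || (hi - lo) < .Machine$double.eps * max(1, abs(mid))) {
        return(mid)
      }
      if (fm < p) lo <- mid else hi <- mid
    }
  }
  q <- vapply(targets, solve_one, numeric(1))
  keep <- c(TRUE, diff(q) > 1e-12)
  if (!all(keep)) {
    warning(sprintf(
      "solve_thresholds: %d coincident threshold(s) collapsed for '%s'; levels reduced to %d",
      sum(!keep), model$name, sum(keep) + 1L), call. = FALSE)
    q <- q[keep]
    targets <- targets[keep]
  }
  model$thresholds <- q
  model$n_levels <- length(q) + 1L
  model$start_index <- i
  model$target_fractions <- targets
  model
}

#' Discretize a continuous sample at given thresholds
#'
#' Applies the quantile-threshold map: level 0 for `x <= Q_1` (the boundary
#' belongs to the lower level), level j for `Q_j < x <= Q_{j+1}`, and the
#' top level for `x` above the last threshold. The map is monotone
#' nondecreasing in `x`.
#'
#' @param values numeric vector to discretize.
#' @param thresholds ordered numeric cut points (or a solved `qtf_model`).
#' @param source tag recorded on the output column.
#' @return An [ordinal_column] with `n_levels = length(thresholds) + 1`.
#' @export
discretize <- function(values, thresholds, source = "qtf") {
  if (inherits(thresholds, "qtf_model")) {
    if (is.null(thresholds$thresholds)) {
      stop_named("discretize: model has no thresholds; call solve_thresholds() first")
    }
    thresholds <- thresholds$thresholds
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_named("discretize: thresholds must be strictly increasing")
  }
  values <- as.numeric(values)
  # x <= Q maps to the lower level: count thresholds strictly below x
  lev <- findInterval(values, thresholds, left.open = TRUE)
  ordinal_column(lev, n_levels = length(thresholds) + 1L, source = source,
                 meta = list(thresholds = thresholds))
}

#' One-call quantile-threshold discretization
#'
#' Convenience wrapper: fit the KDE, solve thresholds at the `(n, i)`
#' targets, and discretize.
#'
#' @inheritParams fit_kde
#' @inheritParams solve_thresholds
#' @return An [ordinal_column]; the solved `qtf_model` is in `meta$model`.
#' @export
qtf_discretize <- function(values, name = "x", n = 2L, i = 2L,
                           bandwidth = NULL, tol = 1e-9) {
  model <- solve_thresholds(fit_kde(values, name, bandwidth), n = n, i = i, tol = tol)
  col <- discretize(values, model)
  col$meta$model <- model
  col
}

#' Validate a discretization by one-way ANOVA
#'
#' Tests whether the raw values differ in mean across the assigned levels
#' (H0: all group means equal) with the classical one-way F test at
#' significance level 0.05, and reports per-group mean, SD and n.
#'
#' @param values raw continuous measurements.
#' @param column the [ordinal_column] grouping them.
#' @return Object of class `anova_result`: list with `group_means`,
#'   `group_sds`, `group_ns`, `F`, `df`, `p`.
#' @export
anova_validate <- function(values, column) {
  stopifnot(inherits(column, "ordinal_column"),
            length(values) == length(column$levels))
  g <- factor(column$levels, levels = sort(unique(column$levels)))
  if (nlevels(g) < 2L) stop_named("anova_validate: classification degenerate (single occupied level)")
  fit <- stats::lm(values ~ g)
  av <- stats::anova(fit)
  grp_mean <- tapply(values, g, mean)
  grp_sd <- tapply(values, g, stats::sd)
  grp_n <- as.integer(table(g))
  structure(
    list(group_means = as.numeric(grp_mean),
         group_sds = as.numeric(grp_sd),
         group_ns = grp_n,
         F = av[1, "F value"],
         df = c(av[1, "Df"], av[2, "Df"]),
         p = av[1, "Pr(>F)"]),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  stars <- if (x$p < 0.001) "***" else if (x$p < 0.01) "**" else if (x$p < 0.05) "*" else ""
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g %s\n",
              x$df[1], x$df[2], x$F, x$p, stars))
  for (j in seq_along(x$group_means)) {
    cat(sprintf("  level %d: %.4g +/- %.4g (n = %d)\n",
                j - 1L, x$group_means[j], x$group_sds[j], x$group_ns[j]))
  }
  invisible(x)
}

#' Baseline discretizers: equal width, equal frequency, k-means
#'
#' Reference binning methods used to contextualize the quantile-threshold
#' approach. `equal_width_discretize()` cuts `[min, max]` into bins of equal
#' width (boundary values go to the lower bin); `equal_frequency_discretize()`
#' places edges at empirical quantiles (type-1 / "lower" interpolation, so
#' identical values are never split across bins; a warning is emitted when
#' ties make occupancies unequal); `kmeans_discretize()` runs 1-D k-means and
#' relabels clusters by increasing center so the levels are ordinal.
#'
#' @param values numeric vector.
#' @param n_levels number of bins.
#' @param seed RNG seed for the k-means initialization.
#' @return An [ordinal_column].
#' @name baseline_discretizers
NULL

#' @rdname baseline_discretizers
#' @export
equal_width_discretize <- function(values, n_levels) {
  values <- as.numeric(values)
  rng <- range(values)
  if (diff(rng) == 0) stop_named("equal_width_discretize: zero range")
  edges <- seq(rng[1], rng[2], length.out = n_levels + 1L)[2:n_levels]
  lev <- findInterval(values, edges, left.open = TRUE)
  ordinal_column(lev, n_levels, source = "equal_width",
                 meta = list(thresholds = edges))
}

#' @rdname baseline_discretizers
#' @export
equal_frequency_discretize <- function(values, n_levels) {
  values <- as.numeric(values)
  probs <- seq_len(n_levels - 1L) / n_levels
  edges <- stats::quantile(values, probs, type = 1L, names = FALSE)
  edges_u <- unique(edges)
  lev <- findInterval(values, edges_u, left.open = TRUE)
  occ <- tabulate(lev + 1L, nbins = length(edges_u) + 1L)
  expected <- length(values) / n_levels
  if (length(edges_u) < length(edges) || max(abs(occ - expected)) > expected * 0.5) {
    warning("equal_frequency_discretize: heavy ties give unequal bin occupancy",
            call. = FALSE)
  }
  ordinal_column(lev, length(edges_u) + 1L, source = "equal_frequency",
                 meta = list(thresholds = edges_u))
}

#' @rdname baseline_discretizers
#' @export
kmeans_discretize <- function(values, n_levels, seed = 1L) {
  values <- as.numeric(values)
  if (length(unique(values)) < n_levels) {
    stop_named("kmeans_discretize: fewer distinct values than clusters")
  }
  km <- with_seed(seed, stats::kmeans(values, centers = n_levels, nstart = 5L))
  ord <- order(km$centers)
  relabel <- integer(n_levels)
  relabel[ord] <- seq_len(n_levels) - 1L
  ordinal_column(relabel[km$cluster], n_levels, source = "kmeans",
                 meta = list(centers = sort(as.numeric(km$centers)),
                             seed = seed,
                             note = "boundaries are data- and seed-dependent"))
}
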