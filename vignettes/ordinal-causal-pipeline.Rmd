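---
title: "Ordinal causal analysis with quantile thresholds and latent Gaussian DAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal causal analysis with quantile thresholds and latent Gaussian DAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordinalcausal)
```

## The problem

Daily training logs — and much observational data in sports epidemiology —
mix continuous measurements (kilometres run at various intensities, hours of
cross-training) with inherently ordinal ones (session counts, binary injury
status, coarse self-ratings). Causal questions about such data ("how does
forcing sprint volume from *low* to *high* change the probability of
injury?") need three ingredients this package provides:

1. a principled, reproducible way to turn continuous variables into ordered
   levels (`qtf_discretize()`),
2. a causal structure learned from the ordinal data while respecting the
   ordering of categories (`osem_fit()`, `bootstrap_cpdag()`),
3. an interventional effect measure defined directly on ordinal levels
   (`oce()` and relatives).

## Quantile-threshold discretization

For a continuous variable \(X\) with observations \(x_1,\dots,x_n\) we fit a
Gaussian-kernel density
\[
\hat f(x) = \frac{1}{nh} \sum_{i=1}^n K\!\Big(\frac{x - x_i}{h}\Big),
\qquad K(u) = \tfrac{1}{\sqrt{2\pi}} e^{-u^2/2},
\]
whose distribution function has the closed form
\(\hat F(x) = n^{-1}\sum_i \Phi((x-x_i)/h)\). Cut points
\(Q_i, \dots, Q_{i+n-1}\) solve \(\hat F(Q_j) = j/(n+2)\), and the level map
assigns 0 for \(x \le Q_i\), stepping up by one per threshold crossed
(boundaries belong to the lower level). With the default `n = i = 2` the
targets are \(1/2\) and \(3/4\): three levels with nominal occupancy
0.5 / 0.25 / 0.25, a deliberately asymmetric split that keeps a broad
"baseline" level and two progressively more extreme ones.

Parameter choices:

* **Bandwidth** `h` defaults to the rule of thumb
  \(0.9 \min(\hat\sigma, \mathrm{IQR}/1.34)\, n^{-1/5}\) — standard,
  reproducible, and overridable per column (it is the only tunable with
  units, those of the variable itself). A zero-variance column is an error
  unless a bandwidth is supplied, since the rule degenerates there.
* **Threshold solving** uses bisection on
  \([\min x - 10h, \max x + 10h]\) to \(|\hat F - \text{target}| \le 10^{-9}\):
  \(\hat F\) is monotone, so bracketed root-finding cannot fail on that
  interval.
* **Degenerate spikes**: when a variable is almost a point mass, two solved
  thresholds can coincide to machine precision (within \(10^{-12}\)); the
  empty level is collapsed with a warning rather than crashing, and the
  reduced level count is recorded. Zero-inflated kilometre-type columns make
  this a practical concern, not a theoretical one.
* **Validation**: `anova_validate()` runs the classical one-way F test of
  equal group means at \(\alpha = 0.05\) and reports per-level mean, SD and
  n. A significant F with monotone group means is the sanity pattern a
  successful discretization shows. On heavily tied data the occupancies may
  be far from nominal — only the partition property (proportions sum to 1)
  is guaranteed.

The baseline discretizers (`equal_width_discretize()`,
`equal_frequency_discretize()`, `kmeans_discretize()`) exist for
comparison. Equal-frequency uses type-1 ("lower") quantile edges so tied
values are never split across bins; k-means relabels clusters by center so
its output is ordinal, but its boundaries move with seed and data, which is
exactly the interpretability drawback that motivates fixed quantile targets.

## The latent Gaussian DAG model

Each ordinal variable \(X_k\) with \(L_k \ge 2\) levels is modelled as a
discretized latent Gaussian \(Y_k\):
\(X_k = l \iff Y_k \in [\alpha(k,l), \alpha(k,l+1))\) with 0-based levels
and thresholds \(-\infty = \alpha(k,0) < \cdots < \alpha(k,L_k) = \infty\).
The latent vector follows a linear-Gaussian structural equation model over a
DAG \(G\):
\[
Y_k \mid y_{pa(k)} \sim N\Big(\mu_k + \sum_{j \in pa(k)} b_{jk}(y_j - \mu_j),\; v_k\Big).
\]

**Identifiability.** A probit-type discretization model is invariant to
location–scale changes of each latent, so the package fixes the scale:
after every M-step all latents are standardized to zero mean and unit
*marginal* variance (coefficients transform as
\(b_{jk} \mapsto b_{jk} s_j / s_k\), conditional variances as
\(v_k / s_k^2\)). Thresholds are estimated once from the marginal level
frequencies on the probit scale, \(\alpha(k,l) = \Phi^{-1}(\hat P(X_k < l))\),
and held fixed; with unit marginal variances that estimator is consistent,
and both thresholds and causal effects are then well-defined quantities.
(The alternative — fixing conditional variances — would let marginal scales
drift away from the fixed thresholds.)

**Structural EM.** `osem_fit()` alternates:

* *E-step*: `sample_latent_completion()` draws `K` completions of the
  latent matrix conditional on each value lying in its observed threshold
  bin, via systematic-scan Gibbs sampling. The full conditionals are exact
  univariate truncated normals derived from the latent precision matrix, so
  5 sweeps between stored completions (and chain state carried across EM
  iterations) mix well at the correlation levels ordinal data can express.
  Completions are drawn by inverse-CDF truncated-normal sampling,
  vectorized over records.
* *M-step*: greedy hill climbing (`structure_search()`) over single-edge
  additions, deletions and reversals on the decomposable score
  \[
  \sum_k \Big[\max_{\beta} \;\overline{\ell}_k(\beta) \;-\;
  \lambda\,(|pa(k)|+2)\,\tfrac{\log n}{2}\Big],
  \]
  the Gaussian log-likelihood maximized by least squares on cross-moments
  pooled across the `K` completions, with a per-parameter BIC-type penalty
  scaled by \(\lambda\) (slopes + intercept + variance are the free
  parameters). The default \(\lambda = 6\), well above the BIC's
  \(\lambda = 1\), reflects that Monte-Carlo completions understate
  uncertainty: a stiff penalty guards against spurious edges. Both
  \(\lambda\) and `K` (default 5) are exposed. Moves are examined in a
  fixed lexicographic order and only strict improvements accepted, so the
  search is deterministic.

**Convergence.** The loop stops when the absolute total-score change falls
below `tol` (default \(10^{-4}\)) *or* when the structure is unchanged for
two consecutive M-steps, capped at `max_iter = 50`. The second rule is the
one that fires in practice: with a finite-`K` Monte-Carlo E-step the score
fluctuates by more than any tight tolerance even at the fixed point, so
structure stability is the operative notion of convergence; parameters are
refit at the final structure either way. Non-convergence returns the last
iterate with a warning and a flag in `attr(fit, "osem")`.

**Equivalence classes and stability.** A DAG is only identified up to its
Markov equivalence class, so reports use `dag_to_cpdag()` — the
label-compelled transformational algorithm: v-structure and otherwise
compelled edges stay directed, reversible ones become undirected (the test
suite cross-checks it against brute-force enumeration of equivalence
classes on 4-node graphs). `bootstrap_cpdag()` refits on `B` row resamples
(default 500, matching common practice for edge-stability heatmaps) and
accumulates directed-edge frequencies, an undirected edge counting 0.5 to
each direction; failed resamples are excluded with the denominator
adjusted.

## Ordinal causal effects

The effect of forcing the intervention variable \(X_i\) from level \(l\) to
\(l'\) on outcome level \(k\) is
\[
\mathrm{OCE}_{io}(k, l \to l') =
\mathbb{P}\big[Y_o \in B_{o,k} \mid do(Y_i \in B_{i,l'})\big]
- \mathbb{P}\big[Y_o \in B_{o,k} \mid do(Y_i \in B_{i,l})\big],
\qquad B_{k,l} = [\alpha(k,l), \alpha(k,l+1)),
\]
an interval intervention on the *latent* scale: the ordinal variables
themselves have no causal paths (they are deterministic children of their
latents), but forcing \(Y_i\) into the bin that realizes level \(l\)
propagates through the mutilated graph. `mutilate()` removes all edges into
\(i\) and replaces its mechanism by its standardized marginal — so under
the package's standardization the intervened latent is a truncated standard
normal. Because \(i\) is exogenous after mutilation, its observational and
mutilated marginals coincide, which resolves the ambiguity of which
marginal to truncate.

Under the mutilated model \((Y_i, Y_o)\) is bivariate normal, so each
interventional bin probability is a ratio of a bivariate rectangle
probability to a univariate one. Rectangles are computed by the
conditioning integral
\(\int_{a}^{b} \phi(y;\sigma_i)\,[\Phi(\cdot) - \Phi(\cdot)]\,dy\) with
adaptive quadrature at absolute tolerance \(10^{-12}\); a zero latent
covariance short-circuits to an exact product, which makes null effects
*identically* zero rather than zero up to quadrature error (the implied
covariance is built by topological recursion precisely so that "no directed
path" yields an exact structural zero). A near-degenerate correlation
(\(|\rho| \to 1\)) is perturbed with a warning. By construction the
effects are antisymmetric in \((l, l')\), sum to zero over outcome levels,
and vanish when the mutilated graph has no directed path from \(i\) to
\(o\).

`mc_oracle_oce()` / `mc_interventional_probability()` implement an
independent route — forward simulation of the mutilated structural
equations with binomial standard errors — used throughout the tests to
cross-check the analytic values; it is an oracle, not a fallback.
`oce_bootstrap()` recomputes the OCE table per bootstrap refit, producing
the distribution a raincloud plot of effect estimates summarizes (the data
are exported; plotting aesthetics are intentionally out of scope).

Levels are 0-based everywhere in this package, including intervention
shifts: a shift reported elsewhere as "1 → 2" on 1-based labels is
`from = 0, to = 1` here.

## The synthetic-data generator

`random_latent_dag()` + `simulate_ordinal()` generate ground-truth models
and ordinal data for recovery experiments: random topological order,
Bernoulli edges, edge coefficients drawn from
\([-0.9,-0.3] \cup [0.3,0.9]\) (near-null edges would make recovery tests
uninformative about the search itself), standardized marginals, and
equiprobable probit thresholds. `make_training_log_like()` emulates the
*schema* of a daily endurance-training log — session counts, kilometre
volumes as point mass at zero plus a lognormal tail (zero weights 0.90 to
0.93, matching how rarely high-intensity sessions occur), bounded
self-ratings, a rare binary injury outcome weakly driven by sprint volume
and poor recovery. It does **not** emulate athlete-level longitudinal
correlation, measurement error, or missingness; passing tests on it show
the pipeline's statistical machinery works under its stated model, not that
any substantive sports-science conclusion transfers to real logs.

## Problem sizes and numerical choices in the test suite

The suite exercises: occupancy at \(n = 10^5\) (tolerance 0.02 against the
nominal 0.5/0.25/0.25); KDE CDF vs trapezoid integration at \(10^{-6}\);
chain-recovery at \(n = 2000\), 20 seeds, requiring \(\ge 80\%\) exact
CPDAG recovery at `K = 5`, \(\lambda = 6\); analytic-vs-oracle agreement
within 3 Monte-Carlo standard errors at \(10^5\) draws on 2–4-node models
with coefficients in \(\{-0.8, 0.3, 0.8\}\); antisymmetry to \(10^{-12}\)
and zero-sum to \(10^{-10}\) on 20 random models; and bootstrap runs at
reduced `B` (4–50) that validate plumbing, not frequencies. These sizes
were chosen to make each property measurable with comfortable margin while
keeping a full run in well under a minute per file.

## A worked example

```{r example, eval = FALSE}
library(ordinalcausal)

# ground truth: X1 -> X2 -> X3 with raw coefficient 0.8, three levels each
thr <- c(-Inf, qnorm(c(1/3, 2/3)), Inf)
truth <- latent_dag(
  c("X1", "X2", "X3"),
  parents = list(X1 = character(0), X2 = "X1", X3 = "X2"),
  coef = list(X1 = setNames(numeric(0), character(0)),
              X2 = c(X1 = 0.8), X3 = c(X2 = 0.8)),
  thresholds = list(X1 = thr, X2 = thr, X3 = thr))

X <- simulate_ordinal(truth, n = 2000, seed = 42)
fit <- osem_fit(X, K = 5, lambda = 6, seed = 7)
dag_to_cpdag(fit)          # X1 - X2 - X3, the chain's equivalence class
oce_matrix(fit, "X1", "X3") # effect of every upward shift on every level
```

## Limitations

* Single-node interval interventions only; joint interventions and
  path-specific (direct-effect) decompositions are not implemented — the
  engine computes total effects through the mutilated graph.
* All variables must be ordinal after discretization; mixed
  continuous-plus-ordinal learning is out of scope.
* Records are treated as exchangeable; repeated measures on the same
  subject violate the bootstrap's assumptions.
* Hill climbing finds a local score optimum; the bootstrap frequencies are
  the intended guard against over-reading any single fitted graph.
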