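# End-to-end pipeline: QTF discretization -> ANOVA report -> structural-EM
# DAG -> bootstrap CPDAG -> ordinal causal effects, with CSV artifacts.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the defaults used throughout:
#' quantile-threshold discretization at `n = i = 2` (three levels with
#' nominal mass 0.5/0.25/0.25), structural EM with `K = 5` Monte-Carlo
#' completions and penalty `lambda = 6`, and `B = 500` bootstrap resamples.
#'
#' @param column_types named character vector mapping every data column to
#'   `"continuous"` or `"ordinal"`.
#' @param n,i quantile-threshold parameters (see [solve_thresholds()]).
#' @param bandwidth named list of per-column bandwidth overrides.
#' @param K,lambda,max_iter,tol structural-EM settings (see [osem_fit()]).
#' @param B bootstrap resamples for [bootstrap_cpdag()] and [oce_bootstrap()].
#' @param interventions list of `c(intervention, outcome)` name pairs for
#'   which OCE tables are computed.
#' @param seed mandatory RNG seed governing every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(column_types, n = 2L, i = 2L, bandwidth = list(),
                            K = 5L, lambda = 6, max_iter = 50L, tol = 1e-4,
                            B = 500L, interventions = list(), seed) {
  if (missing(seed)) stop_named("pipeline_config: a seed is mandatory")
  stopifnot(is.character(column_types), !is.null(names(column_types)))
  bad <- setdiff(unique(column_types), c("continuous", "ordinal"))
  if (length(bad)) stop_named("pipeline_config: unknown column type(s): %s",
                              paste(bad, collapse = ", "))
  structure(
    list(column_types = column_types, n = n, i = i, bandwidth = bandwidth,
         K = K, lambda = lambda, max_iter = max_iter, tol = tol, B = B,
         interventions = interventions, seed = seed),
    class = "pipeline_config"
  )
}

# Tiny FNV-1a text hash for provenance headers (no external digest package).
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Read a pipeline artifact or input table
#'
#' Reads a CSV with header, ignoring `#` provenance/comment lines.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Write a pipeline artifact with provenance header
#'
#' Writes a CSV preceded by `#`-prefixed provenance lines recording the
#' package version, config hash, seed and pipeline stage, so every artifact
#' is traceable to the run that produced it.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param stage character stage label.
#' @param hash config hash (from the pipeline); free-form text.
#' @param seed the run seed.
#' @export
write_artifact <- function(df, path, stage = "adhoc", hash = "", seed = NA) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# ordinalcausal %s | config=%s | seed=%s | stage=%s",
                     as.character(utils::packageVersion("ordinalcausal")),
                     hash, seed, stage), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Export a DAG or CPDAG as DOT text
#'
#' @param x a [latent_dag], `cpdag`, or adjacency matrix.
#' @param path output file.
#' @export
write_dot <- function(x, path) {
  A <- if (inherits(x, "latent_dag")) dag_adjacency(x) else unclass(x)
  nodes <- colnames(A)
  lines <- c("digraph G {")
  for (v in nodes) lines <- c(lines, sprintf('  "%s";', v))
  for (j in seq_along(nodes)) for (k in seq_along(nodes)) {
    if (A[j, k] == 1L && A[k, j] == 1L) {
      if (j < k) lines <- c(lines, sprintf('  "%s" -> "%s" [dir=none];',
                                           nodes[j], nodes[k]))
    } else if (A[j, k] == 1L) {
      lines <- c(lines, sprintf('  "%s" -> "%s";', nodes[j], nodes[k]))
    }
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

# Map a native ordinal column (arbitrary ordered numeric codes) to 0-based
# consecutive levels.
recode_native <- function(values) {
  u <- sort(unique(values))
  ordinal_column(match(values, u) - 1L, n_levels = length(u), source = "native")
}

#' Run the full causal pipeline
#'
#' Executes, in order: quantile-threshold discretization of continuous
#' columns (native ordinal columns are recoded to 0-based levels), one-way
#' ANOVA validation of each discretized column, structural-EM DAG learning,
#' bootstrap CPDAG edge frequencies, and OCE tables for the configured
#' intervention/outcome pairs. Every stage's artifact is written to
#' `out_dir` as CSV (plus a DOT export of the learned graph). The run is
#' deterministic given (data, config).
#'
#' @param data data.frame or path to a CSV with header.
#' @param config a [pipeline_config] whose `column_types` covers every column.
#' @param out_dir output directory (created if missing); `NULL` skips writing.
#' @param stages subset of `c("discretize", "anova", "learn", "bootstrap",
#'   "oce")` to run (later stages require earlier ones in the same call).
#' @return Invisible list with elements per stage: `ordinal` (the
#'   [ordinal_dataset]), `thresholds_report`, `anova_report`, `fit`,
#'   `cpdag_summary`, `oce_tables`, `oce_bootstraps`.
#' @export
run_pipeline <- function(data, config, out_dir = NULL,
                         stages = c("discretize", "anova", "learn",
                                    "bootstrap", "oce")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(data)) data <- read_table(data)
  missing_cols <- setdiff(names(data), names(config$column_types))
  untyped <- setdiff(names(config$column_types), names(data))
  if (length(missing_cols) || length(untyped)) {
    stop_named("run_pipeline: schema mismatch; untyped columns: [%s]; typed but absent: [%s]",
               paste(missing_cols, collapse = ", "),
               paste(untyped, collapse = ", "))
  }
  hash <- config_hash(config)
  seed <- config$seed
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name, stage) {
    if (!is.null(out_dir)) {
      write_artifact(df, file.path(out_dir, name), stage, hash, seed)
    }
  }
  bundle <- list()
  t0 <- Sys.time()
  log_stage <- function(stage) {
    message(sprintf("[ordinalcausal] %-10s done in %.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  # -- discretize ------------------------------------------------------------
  if ("discretize" %in% stages) {
    cols <- list()
    thr_rows <- list()
    for (v in names(data)) {
      if (config$column_types[[v]] == "continuous") {
        bw <- config$bandwidth[[v]] %||% NULL
        col <- qtf_discretize(data[[v]], name = v, n = config$n,
                              i = config$i, bandwidth = bw)
        md <- col$meta$model
        thr_rows[[v]] <- data.frame(
          variable = v, bandwidth = md$bandwidth,
          threshold = md$thresholds,
          target_fraction = md$target_fractions)
      } else {
        col <- recode_native(data[[v]])
      }
      cols[[v]] <- col
    }
    X <- ordinal_dataset(
      do.call(cbind, lapply(cols, function(cc) cc$levels)),
      n_levels = vapply(cols, function(cc) cc$n_levels, 1L))
    colnames(X) <- names(cols)
    bundle$columns <- cols
    bundle$ordinal <- X
    bundle$thresholds_report <- do.call(rbind, thr_rows)
    emit(as.data.frame(unclass(X)), "discretized.csv", "discretize")
    if (!is.null(bundle$thresholds_report)) {
      emit(bundle$thresholds_report, "thresholds.csv", "discretize")
    }
    log_stage("discretize")
  }

  # -- anova -----------------------------------------------------------------
  if ("anova" %in% stages) {
    res <- list()
    for (v in names(data)) {
      if (config$column_types[[v]] != "continuous") next
      res[[v]] <- anova_validate(data[[v]], bundle$columns[[v]])
    }
    bundle$anova <- res
    bundle$anova_report <- if (length(res)) {
      gmax <- max(vapply(res, function(a) length(a$group_means), 1L))
      do.call(rbind, lapply(names(res), function(v) {
        a <- res[[v]]
        cells <- rep(NA_character_, gmax)
        cells[seq_along(a$group_means)] <- sprintf(
          "%.3f +/- %.3f (n=%d)", a$group_means, a$group_sds, a$group_ns)
        out <- data.frame(variable = v, t(cells), F = a$F, p = a$p)
        names(out)[2:(gmax + 1L)] <- paste0("group", seq_len(gmax) - 1L)
        out
      }))
    } else NULL
    if (!is.null(bundle$anova_report)) {
      emit(bundle$anova_report, "anova.csv", "anova")
    }
    log_stage("anova")
  }

  # -- learn -----------------------------------------------------------------
  if ("learn" %in% stages) {
    fit <- osem_fit(bundle$ordinal, K = config$K, lambda = config$lambda,
                    max_iter = config$max_iter, tol = config$tol, seed = seed)
    bundle$fit <- fit
    edges <- which(dag_adjacency(fit) == 1L, arr.ind = TRUE)
    edge_df <- data.frame(
      parent = fit$nodes[edges[, 1]], child = fit$nodes[edges[, 2]],
      coefficient = vapply(seq_len(nrow(edges)), function(r) {
        fit$coef[[fit$nodes[edges[r, 2]]]][[fit$nodes[edges[r, 1]]]]
      }, numeric(1)))
    thr_df <- do.call(rbind, lapply(fit$nodes, function(k) {
      a <- fit$thresholds[[k]]
      data.frame(variable = k, level_below = seq_along(a[-c(1, length(a))]),
                 alpha = a[-c(1, length(a))])
    }))
    emit(edge_df, "edges.csv", "learn")
    emit(thr_df, "latent_thresholds.csv", "learn")
    if (!is.null(out_dir)) write_dot(fit, file.path(out_dir, "dag.dot"))
    log_stage("learn")
  }

  # -- bootstrap -------------------------------------------------------------
  if ("bootstrap" %in% stages) {
    bs <- bootstrap_cpdag(bundle$ordinal, B = config$B, K = config$K,
                          lambda = config$lambda, seed = seed,
                          max_iter = config$max_iter, tol = config$tol)
    bundle$cpdag_summary <- bs
    emit(as.data.frame(unclass(bs$cpdag)), "cpdag.csv", "bootstrap")
    emit(as.data.frame(bs$edge_frequency), "edge_frequency.csv", "bootstrap")
    if (!is.null(out_dir)) write_dot(bs$cpdag, file.path(out_dir, "cpdag.dot"))
    log_stage("bootstrap")
  }

  # -- oce -------------------------------------------------------------------
  if ("oce" %in% stages && length(config$interventions)) {
    fit <- bundle$fit %||% stop_named("run_pipeline: 'oce' needs the 'learn' stage")
    tabs <- boots <- list()
    for (pair in config$interventions) {
      key <- paste(pair, collapse = "_to_")
      tabs[[key]] <- oce_matrix(fit, pair[1], pair[2])
      boots[[key]] <- oce_bootstrap(bundle$ordinal, pair[1], pair[2],
                                    B = config$B, K = config$K,
                                    lambda = config$lambda, seed = seed,
                                    max_iter = config$max_iter,
                                    tol = config$tol)
      emit(tabs[[key]], sprintf("oce_%s.csv", key), "oce")
      emit(boots[[key]]$draws, sprintf("oce_bootstrap_%s.csv", key), "oce")
      emit(boots[[key]]$summary, sprintf("oce_summary_%s.csv", key), "oce")
    }
    bundle$oce_tables <- tabs
    bundle$oce_bootstraps <- boots
    log_stage("oce")
  }

  invisible(bundle)
}
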