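#' Ordinal column container
#'
#' Wraps an integer vector of ordered levels together with the number of
#' levels and the discretization method that produced it. Levels are
#' 0-based: a column with `n_levels = L` takes values in `0, ..., L - 1`,
#' matching the convention that the l-th ordered category carries the
#' numeric label `l - 1`.
#'
#' @param levels integer vector of level codes in `0:(n_levels - 1)`.
#' @param n_levels number of ordered categories (>= 2 for downstream
#'   modelling; 1 is representable but degenerate).
#' @param source character tag: one of `"qtf"`, `"native"`, `"equal_width"`,
#'   `"equal_frequency"`, `"kmeans"`.
#' @param meta optional list of method metadata (thresholds, warnings, ...).
#' @return An object of class `ordinal_column`.
#' @export
ordinal_column <- function(levels, n_levels, source = "native", meta = list()) {
  levels <- as.integer(levels)
  if (anyNA(levels)) stop_named("ordinal_column: NA levels are not allowed")
  if (any(levels < 0L) || any(levels >= n_levels)) {
    stop_named("ordinal_column: levels outside 0..%d", n_levels - 1L)
  }
  structure(
    list(levels = levels, n_levels = as.integer(n_levels),
         source = source, meta = meta),
    class = "ordinal_column"
  )
}

#' @export
print.ordinal_column <- function(x, ...) {
  cat(sprintf("<ordinal_column> n = %d, levels = %d, source = %s\n",
              length(x$levels), x$n_levels, x$source))
  tab <- level_proportions(x)
  print(round(tab, 4))
  invisible(x)
}

#' Level occupancy proportions
#'
#' Proportion of observations at each level `0:(n_levels-1)`; the partition
#' property guarantees these sum to 1.
#'
#' @param column an [ordinal_column].
#' @return Named numeric vector of length `n_levels` summing to 1.
#' @export
level_proportions <- function(column) {
  stopifnot(inherits(column, "ordinal_column"))
  counts <- tabulate(column$levels + 1L, nbins = column$n_levels)
  stats::setNames(counts / length(column$levels),
                  as.character(seq_len(column$n_levels) - 1L))
}

#' Ordinal dataset container
#'
#' An integer matrix of 0-based level codes with per-column level counts.
#'
#' @param x integer matrix or data.frame of level codes (records x variables).
#' @param n_levels optional integer vector of level counts per column;
#'   defaults to `max(column) + 1`.
#' @return Object of class `ordinal_dataset`: the integer matrix with an
#'   `n_levels` attribute.
#' @export
ordinal_dataset <- function(x, n_levels = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (anyNA(x)) stop_named("ordinal_dataset: NA values are not allowed")
  if (any(x < 0L)) stop_named("ordinal_dataset: negative level codes")
  if (is.null(n_levels)) n_levels <- apply(x, 2L, max) + 1L
  n_levels <- as.integer(n_levels)
  if (length(n_levels) != ncol(x)) {
    stop_named("ordinal_dataset: n_levels length %d != %d columns",
               length(n_levels), ncol(x))
  }
  for (k in seq_len(ncol(x))) {
    if (any(x[, k] >= n_levels[k])) {
      stop_named("ordinal_dataset: column %s has codes >= n_levels", k)
    }
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  structure(x, n_levels = n_levels, class = c("ordinal_dataset", "matrix", "array"))
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat(sprintf("<ordinal_dataset> %d records x %d variables; levels: %s\n",
              nrow(x), ncol(x), paste(attr(x, "n_levels"), collapse = ", ")))
  invisible(x)
}
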