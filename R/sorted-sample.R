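#' Build a sorted, duplicate-aggregated sample for discretization
#'
#' Sorts the predictor values ascending and merges duplicates, tallying per
#' distinct value how many instances of each target class it carries. All
#' discretization routines in the package operate on this representation:
#' cut points can only fall between distinct predictor values, so equal
#' values are aggregated before any search.
#'
#' @param x Numeric vector of predictor values (finite, length >= 1).
#' @param y Target values: factor, character or integer vector of the same
#'   length as `x`. Levels are taken in first-appearance order unless `y` is
#'   already a factor, in which case its level order is kept.
#' @param levels Optional character vector fixing the target levels (useful
#'   when a fold does not contain every class).
#'
#' @return An object of class `sorted_sample`: a list with
#'   * `values` — strictly increasing distinct predictor values (length `n_distinct`),
#'   * `counts` — integer matrix `n_distinct` x `n_classes` of per-value class counts,
#'   * `n` — total instance count, `n_distinct` — distinct-value count,
#'   * `n_classes` — number of target classes, `levels` — class labels,
#'   * `gaps` — successive differences of `values`, `range` — total span.
#'
#' @examples
#' s <- sorted_sample(c(1.2, 1.4, 1.6, 3.7, 3.9, 4.1), c(0, 0, 0, 1, 1, 1))
#' s$n_distinct
#' @export
sorted_sample <- function(x, y, levels = NULL) {
  if (length(x) == 0L) abort("`x` must contain at least one value.")
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be finite numeric, without missing values.")
  }
  if (anyNA(y)) abort("`y` must not contain missing values.")

  if (is.factor(y)) {
    lev <- levels %||% base::levels(y)
    y <- as.character(y)
  } else {
    y <- as.character(y)
    lev <- levels %||% unique(y)
  }
  if (!all(y %in% lev)) {
    abort(paste0(
      "target value(s) not in the given levels: ",
      paste(setdiff(unique(y), lev), collapse = ", ")
    ))
  }

  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  vals <- unique(x)
  counts <- table(factor(match(x, vals)), factor(y, levels = lev))
  counts <- matrix(as.integer(counts), nrow = length(vals),
                   dimnames = NULL)

  structure(
    list(
      values = vals,
      counts = counts,
      n = length(x),
      n_distinct = length(vals),
      n_classes = length(lev),
      levels = lev,
      gaps = diff(vals),
      range = vals[length(vals)] - vals[1L]
    ),
    class = "sorted_sample"
  )
}

#' @export
print.sorted_sample <- function(x, ...) {
  cat(sprintf(
    "<sorted_sample> %d instances, %d distinct values, %d classes (%s)\n",
    x$n, x$n_distinct, x$n_classes, paste(x$levels, collapse = ", ")
  ))
  invisible(x)
}

#' Six-instance gene-expression example
#'
#' The canonical toy dataset used throughout the documentation: one
#' expression-level predictor and a binary phenotype, six instances with a
#' clean class boundary between 1.6 and 3.7 (midpoint 2.65).
#'
#' @return A tibble with columns `expression` (numeric) and `phenotype`
#'   (0 = healthy, 1 = diseased).
#' @examples
#' toy_expression_data()
#' @export
toy_expression_data <- function() {
  tibble::tibble(
    expression = c(1.2, 1.4, 1.6, 3.7, 3.9, 4.1),
    phenotype = c(0L, 0L, 0L, 1L, 1L, 1L)
  )
}

#' @rdname toy_expression_data
#' @return `toy_expression_sample()` returns the same data as a
#'   [sorted_sample()].
#' @export
toy_expression_sample <- function() {
  d <- toy_expression_data()
  sorted_sample(d$expression, d$phenotype)
}
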