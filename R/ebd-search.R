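# Score ties are resolved toward parsimony: within `tol`, fewer intervals
# win; among equal interval counts, the candidate whose final interval starts
# earlier (i.e. is longer) wins.
SCORE_TOL <- 1e-12

new_discretization <- function(boundaries, sample, log_score, method,
                               params = NULL, extra = list()) {
  boundaries <- as.integer(boundaries)
  W <- length(boundaries)
  starts <- c(1L, head(boundaries, -1L) + 1L)
  counts <- t(vapply(
    seq_len(W),
    function(i) colSums(sample$counts[starts[i]:boundaries[i], , drop = FALSE]),
    numeric(sample$n_classes)
  ))
  cuts <- if (W > 1L) {
    ends <- boundaries[-W]
    # snap to 15 significant digits so decimal midpoints (e.g. 2.65) are
    # represented by the double nearest the decimal, not by accumulated
    # floating-point residue one ulp above it
    signif((sample$values[ends] + sample$values[ends + 1L]) / 2, 15)
  } else numeric(0)
  structure(
    c(list(
      boundaries = boundaries,
      n_intervals = W,
      cut_values = cuts,
      interval_counts = counts,
      log_score = log_score,
      method = method,
      levels = sample$levels,
      n_distinct = sample$n_distinct,
      value_range = range(sample$values),
      params = params
    ), extra),
    class = "discretization"
  )
}

#' @export
print.discretization <- function(x, ...) {
  cat(sprintf("<discretization> method = %s, %d interval(s)\n",
              x$method, x$n_intervals))
  if (x$n_intervals > 1L) {
    cat("  cut points:", paste(signif(x$cut_values, 6), collapse = ", "), "\n")
  }
  if (!is.null(x$log_score) && is.finite(x$log_score)) {
    cat(sprintf("  log score: %.6f\n", x$log_score))
  }
  invisible(x)
}

#' @export
tidy.discretization <- function(x, ...) {
  tibble::tibble(
    interval = seq_len(x$n_intervals) - 1L,
    lower = c(-Inf, x$cut_values),
    upper = c(x$cut_values, Inf),
    n = rowSums(x$interval_counts),
    !!!setNames(
      lapply(seq_along(x$levels), function(j) x$interval_counts[, j]),
      paste0("n_", x$levels)
    )
  )
}

#' @export
glance.discretization <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_intervals = x$n_intervals,
    n_cuts = x$n_intervals - 1L,
    log_score = x$log_score %||% NA_real_
  )
}

# TRUE if candidate (score, interval count, final-interval start) beats the
# incumbent under the score-then-parsimony ordering.
candidate_beats <- function(cand_score, cand_nint, cand_b,
                            best_score, best_nint, best_b, tol = SCORE_TOL) {
  if (cand_score > best_score + tol) return(TRUE)
  if (cand_score < best_score - tol) return(FALSE)
  if (cand_nint != best_nint) return(cand_nint < best_nint)
  cand_b < best_b
}

#' Optimal Bayesian discretization by dynamic programming
#'
#' Finds the discretization maximizing the Bayesian score (structure prior
#' times per-interval Dirichlet-multinomial marginal likelihood) exactly, in
#' `O(n_classes * n_distinct^2)` time. The recurrence works over prefixes of
#' the sorted distinct values: `V[a]`, the best log score of any
#' discretization of positions `1..a`, is the maximum over final-interval
#' starts `b` of `V[b-1]` plus the log score of `b..a` as one interval. All
#' arithmetic is in log space; log-gamma terms are computed directly.
#'
#' @param sample A [sorted_sample()].
#' @param params An [ebd_params()] (defaults: `lambda = 0.5`, uniform
#'   Dirichlet `alpha = 1`).
#' @return A `discretization` object; fields include `boundaries` (end
#'   positions of each interval in the distinct-value sequence),
#'   `cut_values` (midpoints between flanking distinct values),
#'   `interval_counts`, `log_score`, and the search accounting fields
#'   `dp_prefixes_stored` (number of prefix-optimal discretizations
#'   materialized, one per distinct value) and `dp_inner_ops` (total inner
#'   loop iterations).
#' @examples
#' ebd_discretize(toy_expression_sample())
#' @export
ebd_discretize <- function(sample, params = ebd_params()) {
  stopifnot(inherits(sample, "sorted_sample"))
  stopifnot(inherits(params, "ebd_params"))
  np <- sample$n_distinct
  J <- sample$n_classes
  alpha <- expand_alpha(params$alpha, J)
  a0 <- sum(alpha)
  lg_alpha <- sum(lgamma(alpha))

  # interior cut priors and the cumulative log no-cut products
  if (np > 1L) {
    p_cut <- 1 - exp(-params$lambda * sample$gaps / sample$range)
    log_cut <- log(p_cut)
    Q <- c(0, cumsum(log1p(-p_cut)))        # Q[k+1] = sum log(1-p) over gaps 1..k
  } else {
    log_cut <- numeric(0)
    Q <- 0
  }

  V <- numeric(np + 1L)      # V[a+1] = best prefix log score; V[1] = 0
  nint <- integer(np + 1L)
  back <- integer(np)
  inner_ops <- 0L

  for (a in seq_len(np)) {
    # class counts of segment b..a for b = a, a-1, ..., 1 (row order)
    cs <- apply(sample$counts[a:1, , drop = FALSE], 2L, cumsum)
    if (a == 1L) cs <- matrix(cs, nrow = 1L)
    nseg <- rowSums(cs)
    ml <- lgamma(a0) - lgamma(a0 + nseg) +
      rowSums(lgamma(sweep(cs, 2L, alpha, "+"))) - lg_alpha
    b_seq <- a:1
    edge <- if (a == np) 0 else log_cut[a]
    composite <- V[b_seq] + (Q[a] - Q[b_seq]) + edge + ml
    inner_ops <- inner_ops + a

    best_b <- Inf; best_score <- -Inf; best_n <- 0L
    for (i in seq_along(b_seq)) {
      b <- b_seq[i]
      if (candidate_beats(composite[i], nint[b] + 1L, b,
                          best_score, best_n, best_b)) {
        best_b <- b; best_score <- composite[i]; best_n <- nint[b] + 1L
      }
    }
    V[a + 1L] <- best_score
    nint[a + 1L] <- best_n
    back[a] <- as.integer(best_b)
  }

  boundaries <- integer(0)
  a <- np
  while (a >= 1L) {
    boundaries <- c(a, boundaries)
    a <- back[a] - 1L
  }

  new_discretization(
    boundaries, sample, V[np + 1L], "ebd", params,
    extra = list(dp_prefixes_stored = np, dp_inner_ops = inner_ops)
  )
}

#' Enumerate all cut-point patterns
#'
#' Every subset of the `n_distinct - 1` interior gaps defines one
#' discretization, so there are `2^(n_distinct-1)` patterns in total.
#'
#' @param n_distinct Number of distinct predictor values (>= 1).
#' @return A logical matrix with one row per pattern and one column per
#'   interior gap (`TRUE` = cut in that gap); `2^(n_distinct-1)` rows.
#' @examples
#' nrow(enumerate_cut_patterns(6))  # 32
#' @export
enumerate_cut_patterns <- function(n_distinct) {
  if (length(n_distinct) != 1L || n_distinct < 1 ||
      n_distinct != round(n_distinct)) {
    abort("`n_distinct` must be a single integer >= 1.")
  }
  if (n_distinct > 25) abort("too many patterns to enumerate (n_distinct > 25).")
  g <- n_distinct - 1L
  if (g == 0L) return(matrix(logical(0), nrow = 1L, ncol = 0L))
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), g),
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  m
}

#' Exhaustive-search discretization (oracle)
#'
#' Scores every one of the `2^(n_distinct-1)` cut-point patterns with
#' [ebd_log_score()] and returns the best under the same tie-break rule as
#' [ebd_discretize()]. Exponential in the number of distinct values; used to
#' certify the dynamic program's optimality on small samples.
#'
#' @inheritParams ebd_discretize
#' @param cap Refuse samples with more distinct values than this.
#' @return A `discretization` object.
#' @export
brute_force_discretize <- function(sample, params = ebd_params(), cap = 16) {
  stopifnot(inherits(sample, "sorted_sample"))
  np <- sample$n_distinct
  if (np > cap) {
    abort(sprintf("n_distinct = %d exceeds the exhaustive-search cap (%d).",
                  np, cap))
  }
  patterns <- enumerate_cut_patterns(np)
  best <- NULL
  for (r in seq_len(nrow(patterns))) {
    boundaries <- c(which(patterns[r, ]), np)
    sc <- ebd_log_score(boundaries, sample, params)
    cand_b <- if (length(boundaries) > 1L)
      boundaries[length(boundaries) - 1L] + 1L else 1L
    if (is.null(best) ||
        candidate_beats(sc, length(boundaries), cand_b,
                        best$score, length(best$boundaries), best$b)) {
      best <- list(boundaries = boundaries, score = sc, b = cand_b)
    }
  }
  new_discretization(best$boundaries, sample, best$score, "ebd", params)
}
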