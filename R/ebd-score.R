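#' Hyperparameters for the Bayesian discretization score
#'
#' Bundles the two prior choices of the Bayesian score: `lambda`, the mean of
#' a Poisson process giving the expected number of cut points over the full
#' range of the predictor (the structure prior), and `alpha`, the Dirichlet
#' pseudo-counts per class within each interval (the parameter prior).
#'
#' The default `lambda = 0.5` encodes a prior expectation midway between zero
#' and one cut point per variable, which matches what entropy-based
#' discretization typically produces on high-dimensional omics data. The
#' default `alpha = 1` (all classes) is the uniform prior over per-interval
#' class distributions.
#'
#' @param lambda Positive scalar, expected total number of cut points.
#' @param alpha Dirichlet hyperparameters: a single positive scalar recycled
#'   across classes, or a positive vector of length `n_classes`.
#'
#' @return An object of class `ebd_params`.
#' @examples
#' ebd_params()
#' ebd_params(lambda = 1, alpha = c(2, 2))
#' @export
ebd_params <- function(lambda = 0.5, alpha = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    abort("`lambda` must be a single positive number.")
  }
  if (!is.numeric(alpha) || length(alpha) < 1L || any(!is.finite(alpha)) ||
      any(alpha <= 0)) {
    abort("`alpha` must be positive.")
  }
  structure(list(lambda = lambda, alpha = alpha), class = "ebd_params")
}

#' @export
print.ebd_params <- function(x, ...) {
  cat(sprintf("<ebd_params> lambda = %g, alpha = %s\n",
              x$lambda, paste(format(x$alpha), collapse = ", ")))
  invisible(x)
}

# Expand a scalar/short alpha to one pseudo-count per class.
expand_alpha <- function(alpha, n_classes) {
  if (length(alpha) == 1L) return(rep(alpha, n_classes))
  if (length(alpha) != n_classes) {
    abort(sprintf("`alpha` has length %d but there are %d classes.",
                  length(alpha), n_classes))
  }
  alpha
}

#' Prior probability of a cut in one gap
#'
#' Probability, under a Poisson process with total mean `lambda` spread over
#' the predictor's range in proportion to gap width, of at least one cut
#' point landing in gap `k` (between the `k`-th and `(k+1)`-th distinct
#' values): `1 - exp(-lambda * gap_k / range)`. The boundary gaps `k = 0`
#' (below the smallest value) and `k = n_distinct` (above the largest) have
#' prior probability 1, so the outermost interval edges are always present.
#'
#' @param k Gap index, `0..n_distinct`.
#' @param sample A [sorted_sample()].
#' @param lambda Positive scalar structure-prior mean.
#' @return A probability in `[0, 1]`.
#' @examples
#' s <- toy_expression_sample()
#' prior_cut(3, s, lambda = 0.5)  # the wide 1.6 -> 3.7 gap
#' @export
prior_cut <- function(k, sample, lambda) {
  stopifnot(inherits(sample, "sorted_sample"))
  np <- sample$n_distinct
  if (length(k) != 1L || k != round(k) || k < 0 || k > np) {
    abort(sprintf("`k` must be a single integer in 0..%d.", np))
  }
  if (k == 0 || k == np) return(1)
  if (np == 1L) abort("a single-distinct-value sample has no interior gaps.")
  1 - exp(-lambda * sample$gaps[k] / sample$range)
}

#' Log structure prior of one interval
#'
#' Natural log of the prior probability that the values at positions
#' `b..a` form one interval: no cut in any internal gap, times a cut (or the
#' range boundary, probability 1, when `a = n_distinct`) at its right edge.
#' Interval priors multiply independently across a discretization.
#'
#' @param b,a Start and end positions into the distinct-value sequence,
#'   `1 <= b <= a <= n_distinct`.
#' @inheritParams prior_cut
#' @return Log-probability (non-positive).
#' @export
interval_log_prior <- function(b, a, sample, lambda) {
  stopifnot(inherits(sample, "sorted_sample"))
  np <- sample$n_distinct
  if (b > a) abort("`b` must be <= `a`.")
  if (b < 1 || a > np) abort("interval out of bounds.")
  inner <- if (a > b) {
    sum(log1p(-(1 - exp(-lambda * sample$gaps[b:(a - 1L)] / sample$range))))
  } else 0
  edge <- if (a == np) 0 else log(prior_cut(a, sample, lambda))
  inner + edge
}

#' Log marginal likelihood of one interval
#'
#' The Dirichlet-multinomial marginal likelihood of the class counts in one
#' interval, with the multinomial parameters integrated out against a
#' Dirichlet prior with pseudo-counts `alpha`:
#' `Gamma(a.) / Gamma(a. + n.) * prod_j Gamma(a_j + n_j) / Gamma(a_j)`,
#' where `a. = sum(alpha)` and `n. = sum(counts)`. With all `alpha = 1` this
#' reduces to `(J-1)! / (n. + J - 1)! * prod_j n_j!`.
#'
#' @param counts Non-negative integer class-count vector with positive total.
#' @param alpha Positive Dirichlet hyperparameters, recycled if scalar.
#' @return Log-probability.
#' @examples
#' interval_log_marginal(c(3, 0), 1)  # log(0.25)
#' @export
interval_log_marginal <- function(counts, alpha = 1) {
  if (any(counts < 0) || sum(counts) <= 0) {
    abort("`counts` must be non-negative with a positive total.")
  }
  alpha <- expand_alpha(alpha, length(counts))
  a0 <- sum(alpha)
  lgamma(a0) - lgamma(a0 + sum(counts)) +
    sum(lgamma(alpha + counts) - lgamma(alpha))
}

#' Log Bayesian score of a discretization
#'
#' Recomputes, non-incrementally, the log score of a discretization model
#' against a sample: the sum over intervals of the log structure prior
#' ([interval_log_prior()]) and the log Dirichlet-multinomial marginal
#' likelihood ([interval_log_marginal()]) of the interval's class counts.
#' The score is the log numerator of the model posterior; the evidence term,
#' constant across discretizations, is dropped.
#'
#' @param model A `discretization` object (or a bare integer vector of
#'   interval end positions whose last element is `n_distinct`).
#' @param sample The [sorted_sample()] the model discretizes.
#' @param params An [ebd_params()] object.
#' @return The log score (a single number).
#' @export
ebd_log_score <- function(model, sample, params = ebd_params()) {
  stopifnot(inherits(sample, "sorted_sample"))
  boundaries <- if (inherits(model, "discretization")) model$boundaries else
    as.integer(model)
  np <- sample$n_distinct
  if (length(boundaries) < 1L || boundaries[length(boundaries)] != np ||
      is.unsorted(boundaries, strictly = TRUE) || boundaries[1L] < 1L) {
    abort("`boundaries` must be strictly increasing end positions, last = n_distinct.")
  }
  alpha <- expand_alpha(params$alpha, sample$n_classes)
  starts <- c(1L, head(boundaries, -1L) + 1L)
  total <- 0
  for (i in seq_along(boundaries)) {
    b <- starts[i]; a <- boundaries[i]
    cnt <- colSums(sample$counts[b:a, , drop = FALSE])
    total <- total + interval_log_prior(b, a, sample, params$lambda) +
      interval_log_marginal(cnt, alpha)
  }
  total
}
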