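# Random sorted samples for property-style tests. Values are drawn so that
# distinct counts are exact; classes are assigned uniformly.
random_sample <- function(n_distinct, n_classes, seed,
                          reps_range = 1:3) {
  set.seed(seed)
  values <- sort(runif(n_distinct, 0, 10))
  # guarantee strict increase even under unlucky draws
  values <- values + seq_len(n_distinct) * 1e-6
  reps <- sample(reps_range, n_distinct, replace = TRUE)
  x <- rep(values, reps)
  y <- sample.int(n_classes, length(x), replace = TRUE) - 1L
  # ensure every class index stays < n_classes but not necessarily all present
  sorted_sample(x, y, levels = as.character(0:(n_classes - 1L)))
}

# Direct (non-log) factorial-ratio Dirichlet-multinomial marginal for
# uniform alpha = 1; independent of the lgamma-based implementation.
direct_marginal_uniform <- function(counts) {
  J <- length(counts)
  n <- sum(counts)
  factorial(J - 1) / factorial(n + J - 1) * prod(factorial(counts))
}

# Prior-only log score of a cut-pattern (marginal likelihood forced to 1),
# composed straight from prior_cut values rather than interval_log_prior.
prior_only_log_score <- function(boundaries, sample, lambda) {
  np <- sample$n_distinct
  interior <- setdiff(seq_len(np - 1L), integer(0))
  cuts <- boundaries[boundaries < np]
  total <- 0
  for (k in seq_len(np - 1L)) {
    p <- prior_cut(k, sample, lambda)
    total <- total + if (k %in% cuts) log(p) else log(1 - p)
  }
  total
}
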