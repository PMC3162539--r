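toy <- toy_expression_sample()

test_that("cut prior follows the distance-weighted Poisson form", {
  expect_equal(prior_cut(0, toy, 0.5), 1)
  expect_equal(prior_cut(6, toy, 0.5), 1)
  # wide 1.6 -> 3.7 gap: d = 2.1, range = 2.9
  expect_equal(prior_cut(3, toy, 0.5), 1 - exp(-0.5 * 2.1 / 2.9),
               tolerance = 1e-12)
  expect_equal(prior_cut(3, toy, 0.5), 0.30378, tolerance = 1e-4)
  # narrow 0.2 gap
  expect_equal(prior_cut(1, toy, 0.5), 1 - exp(-0.5 * 0.2 / 2.9),
               tolerance = 1e-12)
  expect_equal(prior_cut(1, toy, 0.5), 0.033895, tolerance = 1e-4)
  expect_error(prior_cut(7, toy, 0.5), "0\\.\\.6")
  single <- sorted_sample(c(2, 2), c(0, 1))
  expect_equal(prior_cut(0, single, 0.5), 1)
  expect_equal(prior_cut(1, single, 0.5), 1)
})

test_that("interval prior composes no-cut factors with an edge cut", {
  p1 <- prior_cut(1, toy, 0.5)
  p2 <- prior_cut(2, toy, 0.5)
  p3 <- prior_cut(3, toy, 0.5)
  # positions 1..3: no cut in gaps 1 and 2, cut in gap 3
  expect_equal(interval_log_prior(1, 3, toy, 0.5),
               log((1 - p1) * (1 - p2) * p3), tolerance = 1e-12)
  # final single-value interval: empty product times boundary prior 1
  expect_equal(interval_log_prior(6, 6, toy, 0.5), 0)
  # whole sample as one interval: product over all five gaps, edge prior 1
  all_p <- vapply(1:5, prior_cut, numeric(1), sample = toy, lambda = 0.5)
  expect_equal(interval_log_prior(1, 6, toy, 0.5), sum(log(1 - all_p)),
               tolerance = 1e-12)
  expect_error(interval_log_prior(4, 2, toy, 0.5), "<=")
})

test_that("uniform-prior marginal likelihood matches factorial arithmetic", {
  expect_equal(interval_log_marginal(c(1, 0), 1), log(1 / 2), tolerance = 1e-12)
  expect_equal(interval_log_marginal(c(3, 0), 1), log(0.25), tolerance = 1e-12)
  expect_equal(interval_log_marginal(c(3, 3), 1), log(36 / 5040),
               tolerance = 1e-12)
  expect_error(interval_log_marginal(c(0, 0), 1), "positive total")
  expect_error(interval_log_marginal(c(1, 1), c(1, 1, 1)), "length")
})

test_that("log-space marginal agrees with direct factorial ratios (n <= 30)", {
  set.seed(11)
  for (rep in 1:50) {
    J <- sample(2:4, 1)
    counts <- as.vector(stats::rmultinom(1, sample(1:30, 1), rep(1, J)))
    if (sum(counts) == 0) next
    expect_equal(exp(interval_log_marginal(counts, 1)),
                 direct_marginal_uniform(counts),
                 tolerance = 1e-9)
  }
})

test_that("non-uniform alpha follows the general Dirichlet-multinomial form", {
  counts <- c(2, 1)
  alpha <- c(3, 0.5)
  expected <- lgamma(3.5) - lgamma(3.5 + 3) +
    (lgamma(3 + 2) - lgamma(3)) + (lgamma(0.5 + 1) - lgamma(0.5))
  expect_equal(interval_log_marginal(counts, alpha), expected, tolerance = 1e-12)
})

test_that("the model score decomposes exactly over intervals", {
  params <- ebd_params()
  # single-interval model: one-term decomposition
  expect_equal(ebd_log_score(6L, toy, params),
               interval_log_prior(1, 6, toy, 0.5) +
                 interval_log_marginal(c(3, 3), 1),
               tolerance = 1e-12)
  # two-interval class-boundary split beats the single interval:
  # the marginal-likelihood ratio 0.25^2 / (36/5040) = 8.75 outweighs the
  # prior cost of the extra cut
  s2 <- ebd_log_score(c(3L, 6L), toy, params)
  s1 <- ebd_log_score(6L, toy, params)
  expect_gt(s2, s1)
  expect_equal(exp(interval_log_marginal(c(3, 0), 1)) ^ 2 /
                 exp(interval_log_marginal(c(3, 3), 1)), 8.75,
               tolerance = 1e-9)
  # decomposability on random models
  set.seed(5)
  for (rep in 1:20) {
    s <- random_sample(sample(3:9, 1), sample(2:3, 1), seed = 100 + rep)
    np <- s$n_distinct
    cuts <- sort(sample(seq_len(np - 1L), sample(0:(np - 1L), 1)))
    boundaries <- c(cuts, np)
    starts <- c(1L, head(boundaries, -1L) + 1L)
    parts <- sum(vapply(seq_along(boundaries), function(i) {
      cnt <- colSums(s$counts[starts[i]:boundaries[i], , drop = FALSE])
      interval_log_prior(starts[i], boundaries[i], s, 0.5) +
        interval_log_marginal(cnt, 1)
    }, numeric(1)))
    expect_equal(ebd_log_score(boundaries, s, params), parts,
                 tolerance = 1e-12)
  }
  expect_error(ebd_log_score(c(2L, 5L), toy, params), "n_distinct")
})
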