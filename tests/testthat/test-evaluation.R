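test_that("accuracy counts matches", {
  expect_equal(accuracy(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(accuracy(c(1, 1), c(0, 0)), 0)
  expect_equal(accuracy(c(1, 0, 1, 1), c(1, 1, 1, 1)), 0.75)
  expect_error(accuracy(1:3, 1:2), "equal-length")
})

test_that("binary AUC is the Mann-Whitney statistic with half-ties", {
  expect_equal(binary_auc(c(0.9, 0.8), c(TRUE, FALSE)), 1)
  expect_equal(binary_auc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)),
               0.5)
  expect_equal(binary_auc(c(0.9, 0.4, 0.6), c(TRUE, FALSE, TRUE)), 1)
  expect_equal(binary_auc(c(0.9, 0.4, 0.6), c(TRUE, TRUE, FALSE)), 0.5)
  expect_error(binary_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # brute-force pair counting oracle
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    pos <- scores[labels]; neg <- scores[!labels]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(binary_auc(scores, labels), mean(pairs), tolerance = 1e-12)
  }
})

test_that("Hand-Till AUC reduces to binary AUC and averages class pairs", {
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    p1 <- runif(n)
    proba <- cbind(pos = p1, neg = 1 - p1)
    labels <- c("pos", "neg", sample(c("pos", "neg"), n - 2, replace = TRUE))
    expect_equal(hand_till_auc(proba, labels),
                 binary_auc(proba[, "pos"], labels == "pos"),
                 tolerance = 1e-12)
  }
  # perfect three-class probabilities give AUC 1
  proba <- diag(3)[rep(1:3, each = 2), ]
  colnames(proba) <- c("a", "b", "c")
  labels <- rep(c("a", "b", "c"), each = 2)
  expect_equal(hand_till_auc(proba, labels), 1)
  # hand-listed three-class toy against exhaustive pairwise computation
  proba <- matrix(c(0.6, 0.3, 0.1,
                    0.5, 0.2, 0.3,
                    0.2, 0.5, 0.3,
                    0.4, 0.4, 0.2,
                    0.1, 0.2, 0.7,
                    0.3, 0.3, 0.4), ncol = 3, byrow = TRUE)
  colnames(proba) <- c("a", "b", "c")
  labels <- c("a", "a", "b", "b", "c", "c")
  pair_auc <- function(i, j) {
    sel <- labels %in% c(i, j)
    (binary_auc(proba[sel, i], labels[sel] == i) +
       binary_auc(proba[sel, j], labels[sel] == j)) / 2
  }
  manual <- mean(c(pair_auc("a", "b"), pair_auc("a", "c"), pair_auc("b", "c")))
  expect_equal(hand_till_auc(proba, labels), manual, tolerance = 1e-12)
  expect_error(hand_till_auc(proba, rep("a", 6)), "absent")
})

test_that("robustness is the test/train percentage ratio", {
  expect_equal(robustness(0.6, 0.8), 75)
  expect_equal(robustness(0.7, 0.7), 100)
  expect_equal(robustness(0.9, 0.6), 150)
  expect_error(robustness(0.5, 0), "positive")
})

test_that("set similarity matches the chance-corrected closed form", {
  # r equals its hypergeometric expectation -> 0
  expect_equal(set_similarity(paste0("v", 1:4), paste0("v", c(1, 2, 5, 6, 7)), 10),
               (2 - 4 * 5 / 10) / (4 - 0))
  expect_equal(set_similarity(paste0("v", 1:4), paste0("v", c(3, 4, 5, 6, 7)), 10),
               0)
  expect_equal(set_similarity(character(0), paste0("v", 1:3), 10), 0)
  expect_equal(set_similarity(paste0("v", 1:10), paste0("v", 1:10), 10), 0)
  expect_equal(set_similarity(c("a", "b"), c("a", "b"), 10), 0.8)
})

test_that("set similarity is symmetric and bounded on random legal inputs", {
  set.seed(77)
  vars <- paste0("v", 1:12)
  for (rep in 1:100) {
    ki <- sample(0:12, 1); kj <- sample(0:12, 1)
    si <- sample(vars, ki); sj <- sample(vars, kj)
    a <- set_similarity(si, sj, 12)
    b <- set_similarity(sj, si, 12)
    expect_equal(a, b, tolerance = 1e-12)
    expect_gte(a, -1)
    expect_lte(a, 1)
  }
})

test_that("stability averages all fold pairs within a replicate", {
  same <- replicate(10, c("v1", "v2"), simplify = FALSE)
  st <- stability(list(same), n_vars = 10)
  expect_equal(st$overall, 0.8)           # every one of the 45 pairs is 0.8
  expect_equal(ncol(utils::combn(10, 2)), 45L)
  none <- replicate(10, character(0), simplify = FALSE)
  expect_equal(stability(list(none), n_vars = 10)$overall, 0)
  # overall is the mean over replicates
  mixed <- stability(list(same, none), n_vars = 10)
  expect_equal(mixed$overall, mean(c(0.8, 0)))
  expect_error(stability(list(list(c("a")))), "2 folds")
})

test_that("interval statistics cover the three complexity summaries", {
  mk <- function(W) structure(list(n_intervals = W), class = "discretization")
  st <- interval_stats(lapply(c(1L, 1L, 2L, 3L), mk))
  expect_equal(unlist(st), c(fraction_trivial = 0.5,
                             mean_intervals_selected = 2.5,
                             mean_intervals = 1.75))
  st2 <- interval_stats(lapply(c(1L, 1L), mk))
  expect_equal(st2$fraction_trivial, 1)
  expect_true(is.na(st2$mean_intervals_selected))
  expect_equal(st2$mean_intervals, 1)
  st3 <- interval_stats(lapply(c(2L, 2L), mk))
  expect_equal(unlist(st3), c(fraction_trivial = 0,
                              mean_intervals_selected = 2,
                              mean_intervals = 2))
})

test_that("signed-rank test matches exact enumeration and wilcox.test", {
  # all-positive differences 1..6: W+ = 21; exact two-sided p = 2/64
  res <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$statistic, 21)
  d <- c(1, 2, 3, 4, 5, 6)
  signs <- enumerate_cut_patterns(7)       # all 64 sign patterns over 6 items
  r <- rank(abs(d))
  w_obs <- sum(r)
  w_all <- apply(signs, 1L, function(s) sum(r[s]))
  p_exact <- 2 * mean(w_all >= w_obs)
  expect_equal(p_exact, 0.03125)
  expect_lt(res$p_value, 0.05)
  # antisymmetric pairs give Z = 0
  a <- c(1, 2, 3, 4, 5, 9)
  res0 <- wilcoxon_signed_rank(c(a, a * 2), c(a * 2, a))
  expect_equal(res0$z, 0)
  # agrees with the reference implementation (normal approx, no continuity)
  set.seed(55)
  x <- rnorm(24); y <- rnorm(24, 0.4)
  mine <- wilcoxon_signed_rank(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE, correct = FALSE))
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(wilcoxon_signed_rank(1:3, 1:3), "zero")
})
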