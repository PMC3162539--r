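toy <- toy_expression_sample()

test_that("interval codes follow the equal-or-greater convention and clamp", {
  m <- ebd_discretize(toy)
  expect_equal(apply_model(m, c(1.6, 3.7)), c(0L, 1L))
  expect_equal(apply_model(m, 2.65), 1L)       # on the cut -> upper interval
  expect_equal(apply_model(m, c(-100, 100)), c(0L, 1L))  # out-of-range clamps
  # trivial model maps everything to 0
  s1 <- sorted_sample(c(1, 2), c(0, 0), levels = c("0", "1"))
  expect_equal(apply_model(ebd_discretize(s1), c(-5, 0, 5)), c(0L, 0L, 0L))
  expect_error(apply_model(m, c(1, NA)), "finite")
})

test_that("codes are monotone and training totals are reproduced", {
  set.seed(14)
  for (rep in 1:10) {
    s <- random_sample(sample(4:12, 1), 2, seed = 60 + rep)
    m <- ebd_discretize(s)
    v <- sort(runif(50, min(s$values) - 1, max(s$values) + 1))
    codes <- apply_model(m, v)
    expect_true(all(diff(codes) >= 0))
    expect_true(all(codes >= 0 & codes < m$n_intervals))
    # applying to the training values reproduces per-interval totals
    train_vals <- rep(s$values, rowSums(s$counts))
    tallied <- tabulate(apply_model(m, train_vals) + 1L, m$n_intervals)
    expect_equal(tallied, unname(rowSums(m$interval_counts)))
  }
})

test_that("delimited tables round-trip with dialect sniffing", {
  d <- toy_expression_data()
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d, csv)
  got <- read_table_data(csv, "phenotype")
  expect_equal(got$expression, d$expression)
  expect_equal(levels(got$phenotype), c("0", "1"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  wide <- tibble::as_tibble(setNames(as.list(as.data.frame(matrix(runif(30), 3))),
                                     paste0("v", 1:10)))
  wide$cls <- c("a", "b", "a")
  readr::write_tsv(wide, tsv)
  got2 <- read_table_data(tsv, "cls")
  expect_equal(ncol(got2), 11L)
  expect_true(all(vapply(got2[paste0("v", 1:10)], is.numeric, logical(1))))
})

test_that("bad tables produce located errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,cls", "1,2,a", "3,,b"), p)
  expect_error(read_table_data(p, "cls"), "column 'y', row 2")
  writeLines(c("x,cls", "q,a"), p)
  expect_error(read_table_data(p, "cls"), "column 'x', row 1")
  writeLines(c("x,cls"), p)
  expect_error(read_table_data(p, "cls"), "no rows")
  expect_error(read_table_data(p, "absent"), "not found|no rows")
})

test_that("model files round-trip exactly", {
  d <- toy_expression_data()
  fit <- discretize(d, "phenotype", method = "ebd")
  p <- withr::local_tempfile(fileext = ".json")
  write_model(fit, p)
  back <- read_model(p)
  expect_equal(back$models$expression$cut_values, 2.65, tolerance = 1e-15)
  expect_equal(back$method, "ebd")
  expect_equal(back$levels, c("0", "1"))
  expect_equal(back$params$lambda, 0.5)
  # codes agree bit-exactly
  v <- seq(0, 5, by = 0.01)
  expect_identical(apply_model(fit$models$expression, v),
                   apply_model(back$models$expression, v))
  # trivial model keeps an empty cut list
  d2 <- d; d2$flat <- rep(1.5, 6)
  fit2 <- discretize(d2, "phenotype")
  write_model(fit2, p)
  back2 <- read_model(p)
  expect_equal(back2$models$flat$n_intervals, 1L)
  expect_length(back2$models$flat$cut_values, 0)
})

test_that("malformed or mistagged model files are rejected", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", p)
  expect_error(read_model(p), "malformed")
  jsonlite::write_json(list(format = "bayesdisc-model", method = "mystery"),
                       p, auto_unbox = TRUE)
  expect_error(read_model(p), "unknown method")
  jsonlite::write_json(list(format = "other"), p, auto_unbox = TRUE)
  expect_error(read_model(p), "not a bayesdisc model")
})

test_that("data-frame discretization surfaces tidy summaries", {
  d <- toy_expression_data()
  d$noise <- c(0.21, 0.53, 0.11, 0.47, 0.30, 0.62)
  fit <- discretize(d, "phenotype", method = "ebd")
  td <- tidy(fit)
  expect_equal(nrow(td), 2L)
  expect_equal(td$n_intervals[td$variable == "expression"], 2L)
  g <- glance(fit)
  expect_equal(g$n_variables, 2L)
  codes <- apply_discretization(fit, d)
  expect_equal(nrow(codes), 6L)
  expect_true(all(codes$expression == c(0, 0, 0, 1, 1, 1)))
  expect_error(apply_discretization(fit, d[, "phenotype", drop = FALSE]),
               "lacks predictor")
  d_bad <- d; d_bad$phenotype <- c(0, 0, 0, 1, 1, 2)
  expect_error(apply_discretization(fit, d_bad), "unseen target")
})
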