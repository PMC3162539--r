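#' Train a discrete naive Bayes classifier
#'
#' Tallies class priors and per-variable conditional count tables
#' (interval code x class) from a discretized table. Variables discretized
#' to a single interval carry no information and are dropped from the model
#' — discretization doubles as feature selection. Add-one (Laplace)
#' smoothing is applied to both priors and conditionals at prediction time.
#'
#' @param codes A data frame of integer interval codes (as produced by
#'   [apply_discretization()]) plus the target column.
#' @param target Name of the target column.
#' @param n_intervals Named integer vector giving each variable's interval
#'   count `W`; defaults to `max(code) + 1` per column.
#' @param smoothing Pseudo-count added to every cell (default 1).
#' @return An `nb_model` object.
#' @export
nb_train <- function(codes, target, n_intervals = NULL, smoothing = 1) {
  if (!is.data.frame(codes) || nrow(codes) == 0L) {
    abort("`codes` must be a non-empty data frame.")
  }
  if (!target %in% names(codes)) abort(sprintf("target '%s' not found.", target))
  y <- codes[[target]]
  lev <- if (is.factor(y)) levels(y) else unique(as.character(y))
  y <- factor(as.character(y), levels = lev)
  vars <- setdiff(names(codes), target)
  if (is.null(n_intervals)) {
    n_intervals <- vapply(codes[vars], function(v) max(v) + 1L, integer(1))
  }
  keep <- vars[n_intervals[vars] > 1L]
  tables <- lapply(setNames(keep, keep), function(v) {
    tab <- table(factor(codes[[v]], levels = 0:(n_intervals[[v]] - 1L)), y)
    matrix(as.numeric(tab), nrow = n_intervals[[v]], dimnames = NULL)
  })
  structure(
    list(
      levels = lev,
      class_counts = as.numeric(table(y)),
      tables = tables,
      n_intervals = n_intervals[keep],
      smoothing = smoothing
    ),
    class = "nb_model"
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("<nb_model> %d class(es), %d predictive variable(s)\n",
              length(x$levels), length(x$tables)))
  invisible(x)
}

#' Posterior class probabilities from a naive Bayes model
#'
#' Applies Bayes' theorem under the conditional-independence assumption:
#' the posterior is proportional to the smoothed class prior times the
#' product over retained variables of the smoothed conditional probability
#' of the observed interval code. Computed in log space and normalized to
#' sum to one.
#'
#' @param model An `nb_model`.
#' @param codes Data frame (or named list/row) of interval codes covering
#'   the model's retained variables.
#' @return A numeric matrix, one row per instance, one column per class
#'   (named by class level); rows sum to 1.
#' @export
nb_predict_proba <- function(model, codes) {
  stopifnot(inherits(model, "nb_model"))
  codes <- tibble::as_tibble(as.list(codes))
  J <- length(model$levels)
  s <- model$smoothing
  n <- sum(model$class_counts)
  log_prior <- log(model$class_counts + s) - log(n + s * J)
  nr <- nrow(codes)
  if (nr == 0L) abort("`codes` has no rows.")
  log_post <- matrix(rep(log_prior, each = nr), nrow = nr)
  for (v in names(model$tables)) {
    tab <- model$tables[[v]]
    W <- nrow(tab)
    code <- codes[[v]]
    if (is.null(code)) abort(sprintf("codes lack variable '%s'.", v))
    if (any(code < 0 | code >= W)) {
      abort(sprintf("invalid interval code for variable '%s'.", v))
    }
    cond <- log(sweep(tab + s, 2L, colSums(tab) + s * W, "/"))
    log_post <- log_post + cond[code + 1L, , drop = FALSE]
  }
  log_post <- log_post - apply(log_post, 1L, max)
  p <- exp(log_post)
  p <- p / rowSums(p)
  colnames(p) <- model$levels
  p
}

#' Naive Bayes plug-in for the cross-validation harness
#'
#' The harness accepts any classifier honoring this contract: a list with
#' `train(codes, target, n_intervals)` returning an opaque model and
#' `predict(model, codes)` returning an instance x class probability
#' matrix. This constructor wraps [nb_train()] / [nb_predict_proba()].
#'
#' @param smoothing Laplace pseudo-count.
#' @return A classifier plug-in list.
#' @export
nb_classifier <- function(smoothing = 1) {
  list(
    name = "nb",
    train = function(codes, target, n_intervals) {
      nb_train(codes, target, n_intervals = n_intervals, smoothing = smoothing)
    },
    predict = function(model, codes) nb_predict_proba(model, codes)
  )
}
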