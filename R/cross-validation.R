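#' Stratified repeated cross-validation fold plan
#'
#' Builds `reps` independent stratified `folds`-fold partitions. Within each
#' replicate, instances of every class are shuffled and dealt round-robin
#' across folds, so each test fold contains at least one instance of every
#' class whenever every class has at least `folds` instances. Replicate `r`
#' is seeded with `seed + r`, making every fold assignment reproducible.
#'
#' @param y Class labels (factor or vector).
#' @param folds Number of folds `F` (default 10).
#' @param reps Number of replicates `R` (default 10).
#' @param seed Base integer seed.
#' @return A tibble with columns `replicate`, `fold`, `train` and `test`
#'   (list-columns of instance indices); `reps * folds` rows.
#' @export
make_fold_plan <- function(y, folds = 10, reps = 10, seed = 1) {
  y <- as.factor(y)
  n <- length(y)
  per_class <- table(y)
  if (any(per_class < folds)) {
    abort(sprintf(
      "class '%s' has %d instance(s), fewer than %d folds; use a smaller `folds`.",
      names(per_class)[which.min(per_class)], min(per_class), folds
    ))
  }
  plans <- purrr::map_dfr(seq_len(reps), function(r) {
    set.seed(seed + r)
    assignment <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
    purrr::map_dfr(seq_len(folds), function(f) {
      test <- which(assignment == f)
      tibble::tibble(
        replicate = r, fold = f,
        train = list(setdiff(seq_len(n), test)),
        test = list(test)
      )
    })
  })
  plans
}

#' Repeated cross-validated evaluation of a discretization method
#'
#' The full evaluation protocol: for each of `reps` stratified `folds`-fold
#' partitions, every predictor is discretized on the training fold only;
#' the learned intervals are applied to both folds; the variables with a
#' non-trivial discretization form that fold's selected set; a classifier
#' is trained on the discretized training fold and scored on both folds.
#' Accuracy, AUC (two-class or Hand-Till), and robustness are recorded per
#' train/test pair; selection stability is computed per replicate over all
#' fold pairs and averaged.
#'
#' @param data Data frame of numeric predictors plus a target column.
#' @param target Target column name.
#' @param method `"ebd"` or `"fi"`.
#' @param params [ebd_params()] for the Bayesian method.
#' @param folds,reps Cross-validation shape (default 10 x 10 = 100 pairs).
#' @param seed Base seed for the fold plan.
#' @param classifier A classifier plug-in (default [nb_classifier()]): a
#'   list with `train(codes, target, n_intervals)` and
#'   `predict(model, codes)` returning a probability matrix.
#' @return A `cv_report`: list with `folds` (per-pair tibble: accuracies,
#'   AUCs, robustness, number of selected variables), `stability`,
#'   `interval_stats` (averaged over pairs), and a `summary` tibble of
#'   aggregate means. [tidy()] returns the per-pair tibble, [glance()] the
#'   one-row aggregate.
#' @export
run_cv <- function(data, target, method = c("ebd", "fi"),
                   params = ebd_params(), folds = 10, reps = 10, seed = 1,
                   classifier = nb_classifier()) {
  method <- match.arg(method)
  if (!target %in% names(data)) abort(sprintf("target '%s' not found.", target))
  y <- data[[target]]
  plan <- make_fold_plan(y, folds = folds, reps = reps, seed = seed)
  vars <- setdiff(names(data), target)

  eval_pair <- function(train_idx, test_idx) {
    train <- data[train_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]
    fit <- discretize(train, target, method = method, params = params)
    W <- vapply(fit$models, function(m) m$n_intervals, integer(1))
    selected <- names(W)[W > 1L]
    codes_train <- apply_discretization(fit, train)
    codes_test <- apply_discretization(fit, test)
    model <- classifier$train(codes_train, target, W)
    p_train <- classifier$predict(model, codes_train[vars])
    p_test <- classifier$predict(model, codes_test[vars])
    y_train <- as.character(train[[target]])
    y_test <- as.character(test[[target]])
    acc_train <- accuracy(predict_labels(p_train), y_train)
    acc_test <- accuracy(predict_labels(p_test), y_test)
    list(
      selected = selected,
      stats = tibble::tibble(
        train_accuracy = acc_train,
        test_accuracy = acc_test,
        train_auc = hand_till_auc(p_train, y_train),
        test_auc = hand_till_auc(p_test, y_test),
        robustness = robustness(acc_test, acc_train),
        n_selected = length(selected)
      ),
      intervals = interval_stats(fit$models)
    )
  }

  results <- purrr::pmap(
    list(plan$replicate, plan$fold, plan$train, plan$test),
    function(r, f, tr, te) {
      res <- eval_pair(tr, te)
      res$stats <- dplyr::mutate(res$stats, replicate = r, fold = f,
                                 .before = 1L)
      res
    }
  )

  fold_stats <- purrr::map_dfr(results, "stats")
  sel_by_rep <- lapply(split(results, plan$replicate), function(rs) {
    lapply(rs, function(x) x$selected)
  })
  stab <- stability(sel_by_rep, n_vars = length(vars))
  int_stats <- purrr::map_dfr(results, "intervals") |>
    dplyr::summarise(dplyr::across(dplyr::everything(),
                                   ~ mean(.x, na.rm = TRUE)))

  summary <- tibble::tibble(
    method = method,
    n_pairs = nrow(fold_stats),
    accuracy = mean(fold_stats$test_accuracy),
    auc = mean(fold_stats$test_auc),
    robustness = mean(fold_stats$robustness),
    stability = stab$overall,
    fraction_trivial = int_stats$fraction_trivial,
    mean_intervals = int_stats$mean_intervals
  )

  structure(
    list(folds = fold_stats, stability = stab, interval_stats = int_stats,
         summary = summary, method = method,
         settings = list(folds = folds, reps = reps, seed = seed,
                         target = target, classifier = classifier$name)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d train/test pairs\n",
              x$method, nrow(x$folds)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @export
glance.cv_report <- function(x, ...) x$summary

#' Paired comparison of two cross-validation reports
#'
#' Wilcoxon signed-rank comparison of two methods evaluated on the same
#' fold plan (same seed), per evaluation measure, over the paired per-fold
#' values.
#'
#' @param report_a,report_b Two `cv_report`s from [run_cv()] with identical
#'   settings.
#' @param measures Which per-fold columns to compare.
#' @return A tibble: one row per measure with mean difference, `z`, and
#'   `p_value`.
#' @export
compare_cv <- function(report_a, report_b,
                       measures = c("test_accuracy", "test_auc", "robustness")) {
  stopifnot(inherits(report_a, "cv_report"), inherits(report_b, "cv_report"))
  if (nrow(report_a$folds) != nrow(report_b$folds)) {
    abort("reports have different numbers of fold pairs.")
  }
  purrr::map_dfr(measures, function(m) {
    a <- report_a$folds[[m]]
    b <- report_b$folds[[m]]
    wt <- if (all(a == b)) {
      tibble::tibble(statistic = NA_real_, z = 0, p_value = 1, n_nonzero = 0L)
    } else {
      wilcoxon_signed_rank(a, b)
    }
    tibble::tibble(
      measure = m,
      mean_a = mean(a), mean_b = mean(b),
      mean_difference = mean(a - b),
      z = wt$z, p_value = wt$p_value
    )
  })
}
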