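#' Map continuous values to interval codes
#'
#' Applies a learned discretization to new values. Codes run `0..W-1` from
#' the lowest interval up; a value equal to a cut point belongs to the upper
#' interval ("equal or greater"). Values outside the training range clamp to
#' the terminal intervals, which is the only behavior that never fails when
#' a model learned on a training fold is applied to a test fold.
#'
#' @param model A `discretization` object.
#' @param values Numeric vector (finite).
#' @return Integer vector of interval codes in `0..n_intervals-1`.
#' @examples
#' m <- ebd_discretize(toy_expression_sample())
#' apply_model(m, c(1.6, 2.65, 3.7))
#' @export
apply_model <- function(model, values) {
  stopifnot(inherits(model, "discretization"))
  if (anyNA(values) || any(!is.finite(values))) {
    abort("`values` must be finite, without missing values.")
  }
  if (model$n_intervals == 1L) return(rep(0L, length(values)))
  findInterval(values, model$cut_values)
}

#' Discretize every predictor of a data frame
#'
#' The main entry point for tabular data: fits one discretization per
#' numeric predictor column against the target column, using either the
#' Bayesian dynamic-programming method (`"ebd"`) or recursive entropy
#' minimization with MDL stopping (`"fi"`).
#'
#' @param data A data frame; all non-target columns must be numeric.
#' @param target Name of the categorical target column (string).
#' @param method `"ebd"` or `"fi"`.
#' @param params An [ebd_params()] (used by `"ebd"` only).
#' @return A `discretization_set`: a named list of `discretization` objects
#'   (one per predictor) with the target levels and method attached. Use
#'   [tidy()] for a per-variable summary tibble and
#'   [apply_discretization()] to code a data frame.
#' @examples
#' d <- toy_expression_data()
#' fit <- discretize(d, target = "phenotype")
#' tidy(fit)
#' @export
discretize <- function(data, target, method = c("ebd", "fi"),
                       params = ebd_params()) {
  method <- match.arg(method)
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!target %in% names(data)) {
    abort(sprintf("target column '%s' not found.", target))
  }
  y <- data[[target]]
  lev <- if (is.factor(y)) levels(y) else as.character(unique(y))
  vars <- setdiff(names(data), target)
  if (length(vars) == 0L) abort("no predictor columns.")
  models <- lapply(vars, function(v) {
    x <- data[[v]]
    if (!is.numeric(x)) abort(sprintf("predictor '%s' is not numeric.", v))
    s <- sorted_sample(x, y, levels = lev)
    if (method == "ebd") ebd_discretize(s, params) else fi_discretize(s)
  })
  names(models) <- vars
  structure(
    list(models = models, target = target, levels = lev,
         method = method, params = if (method == "ebd") params else NULL),
    class = "discretization_set"
  )
}

#' @export
print.discretization_set <- function(x, ...) {
  W <- vapply(x$models, function(m) m$n_intervals, integer(1))
  cat(sprintf(
    "<discretization_set> %s, %d predictor(s): %d non-trivial, %d trivial\n",
    x$method, length(W), sum(W > 1L), sum(W == 1L)
  ))
  invisible(x)
}

#' @export
tidy.discretization_set <- function(x, ...) {
  tibble::tibble(
    variable = names(x$models),
    method = x$method,
    n_intervals = unname(vapply(x$models, function(m) m$n_intervals, integer(1))),
    cut_values = unname(lapply(x$models, function(m) m$cut_values)),
    log_score = unname(vapply(x$models, function(m) m$log_score %||% NA_real_,
                              numeric(1)))
  )
}

#' @export
glance.discretization_set <- function(x, ...) {
  st <- interval_stats(x$models)
  tibble::tibble(
    method = x$method,
    n_variables = length(x$models),
    n_selected = sum(vapply(x$models, function(m) m$n_intervals, integer(1)) > 1L),
    fraction_trivial = st$fraction_trivial,
    mean_intervals_selected = st$mean_intervals_selected,
    mean_intervals = st$mean_intervals
  )
}

#' Apply a fitted discretization set to a data frame
#'
#' Codes every predictor of `data` with its fitted model via
#' [apply_model()]; the target column (if present) is carried through
#' unchanged.
#'
#' @param object A `discretization_set` from [discretize()].
#' @param data A data frame containing the same predictor columns.
#' @return A tibble of integer interval codes (plus the target column).
#' @export
apply_discretization <- function(object, data) {
  stopifnot(inherits(object, "discretization_set"))
  vars <- names(object$models)
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort(paste0("data lacks predictor column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(lapply(
    setNames(vars, vars),
    function(v) apply_model(object$models[[v]], data[[v]])
  ))
  if (object$target %in% names(data)) {
    y <- as.character(data[[object$target]])
    bad <- setdiff(unique(y), object$levels)
    if (length(bad)) {
      abort(paste0("unseen target value(s): ", paste(bad, collapse = ", ")))
    }
    out[[object$target]] <- factor(y, levels = object$levels)
  }
  out
}

#' Read a delimited dataset for discretization
#'
#' Reads a comma- or tab-separated file (dialect sniffed from the header
#' row), checks the target column exists, parses every other column as
#' numeric, and rejects missing cells — the Bayesian score's closed form
#' assumes complete data.
#'
#' @param path File path.
#' @param target Name of the target column.
#' @return A tibble; the target column is a factor with levels in
#'   first-appearance order.
#' @export
read_table_data <- function(path, target) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) abort("empty file.")
  delim <- if (grepl("\t", header)) "\t" else ","
  d <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(d) == 0L) abort("file has a header but no rows.")
  if (!target %in% names(d)) {
    abort(sprintf("target column '%s' not found (columns: %s).",
                  target, paste(names(d), collapse = ", ")))
  }
  for (v in setdiff(names(d), target)) {
    parsed <- suppressWarnings(as.numeric(d[[v]]))
    bad <- which(is.na(parsed) | is.na(d[[v]]))
    if (length(bad)) {
      abort(sprintf("missing or non-numeric value in column '%s', row %d.",
                    v, bad[1L]))
    }
    d[[v]] <- parsed
  }
  if (anyNA(d[[target]])) {
    abort(sprintf("missing value in target column '%s', row %d.",
                  target, which(is.na(d[[target]]))[1L]))
  }
  d[[target]] <- factor(d[[target]], levels = unique(d[[target]]))
  d
}

#' Serialize / deserialize discretization sets as JSON
#'
#' `write_model()` stores per-variable cut points (full precision), interval
#' counts, method, hyperparameters and target levels as structured JSON;
#' `read_model()` reconstructs a `discretization_set` whose interval codes
#' are bit-identical to the original's.
#'
#' @param object A `discretization_set`.
#' @param path File path for the JSON model file.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   a `discretization_set`.
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "discretization_set"))
  payload <- list(
    format = "bayesdisc-model",
    version = 1L,
    method = object$method,
    target = object$target,
    levels = as.list(object$levels),
    lambda = if (!is.null(object$params)) object$params$lambda else NULL,
    alpha = if (!is.null(object$params)) as.list(object$params$alpha) else NULL,
    variables = lapply(object$models, function(m) list(
      n_intervals = m$n_intervals,
      cut_values = as.list(m$cut_values),
      log_score = if (is.finite(m$log_score %||% NA_real_)) m$log_score else NULL,
      value_range = as.list(m$value_range)
    ))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("malformed model file '%s': %s",
                                      path, conditionMessage(e)))
  )
  if (!identical(payload$format, "bayesdisc-model")) {
    abort(sprintf("'%s' is not a bayesdisc model file.", path))
  }
  if (!payload$method %in% c("ebd", "fi")) {
    abort(sprintf("unknown method tag '%s' in '%s'.", payload$method, path))
  }
  lev <- unlist(payload$levels)
  models <- lapply(payload$variables, function(v) {
    cuts <- as.numeric(unlist(v$cut_values))
    if (is.null(cuts)) cuts <- numeric(0)
    structure(
      list(
        boundaries = NULL,
        n_intervals = as.integer(v$n_intervals),
        cut_values = cuts,
        interval_counts = NULL,
        log_score = if (is.null(v$log_score)) NA_real_ else v$log_score,
        method = payload$method,
        levels = lev,
        value_range = as.numeric(unlist(v$value_range))
      ),
      class = "discretization"
    )
  })
  names(models) <- names(payload$variables)
  params <- if (!is.null(payload$lambda)) {
    ebd_params(lambda = payload$lambda, alpha = as.numeric(unlist(payload$alpha)))
  } else NULL
  structure(
    list(models = models, target = payload$target, levels = lev,
         method = payload$method, params = params),
    class = "discretization_set"
  )
}
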