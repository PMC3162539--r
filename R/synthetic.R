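#' Specification for a synthetic discretization benchmark dataset
#'
#' Describes a dataset in the style of a high-dimensional omics matrix:
#' few instances, many predictors, a minority of informative predictors
#' whose values fall in class-dependent intervals, and the remainder
#' class-independent noise. The defaults mirror the regime the package is
#' aimed at: a two-class problem with one true cut per informative variable
#' and high (but imperfect) interval purity.
#'
#' Informative variables are generated class-first: the class label is
#' drawn from `class_probs`, then the value is drawn uniformly from the
#' class's own interval with probability `purity` (and from a uniformly
#' chosen other interval otherwise). A `margin` around every true cut is
#' excluded from sampling, so the gap containing the true cut is
#' recoverable and the predicate "recovered cut lies in the true gap" is
#' crisp. Noise variables are uniform on `value_range` regardless of class.
#'
#' @param n Number of instances.
#' @param class_probs Class probability vector (defines `J`).
#' @param n_informative Number of informative predictors.
#' @param n_noise Number of class-independent noise predictors.
#' @param true_cuts Numeric vector of true cut points shared by the
#'   informative predictors (length `J - 1` intervals are assigned to
#'   classes cyclically).
#' @param purity Probability that an informative value is drawn from its
#'   class's own interval (default 0.95).
#' @param value_range Range all values are drawn within.
#' @param margin Half-width of the exclusion zone around each true cut. The
#'   default is sized so that, at the default `n` and `purity`, the
#'   structure-prior cost of abandoning the margin gap for a typical
#'   data-spacing gap exceeds the marginal-likelihood gain of excluding a
#'   single mislabeled boundary point — i.e. the margin gap is wide enough
#'   that the optimal cut stays inside it (see the methods vignette).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n = 200, class_probs = c(0.5, 0.5),
                           n_informative = 1, n_noise = 0,
                           true_cuts = 0.5, purity = 0.95,
                           value_range = c(0, 1), margin = 0.1) {
  if (abs(sum(class_probs) - 1) > 1e-8) abort("`class_probs` must sum to 1.")
  if (n < length(class_probs)) abort("`n` must be at least the class count.")
  if (is.unsorted(true_cuts, strictly = TRUE)) {
    abort("`true_cuts` must be strictly increasing.")
  }
  if (any(true_cuts <= value_range[1L]) || any(true_cuts >= value_range[2L])) {
    abort("`true_cuts` must lie strictly inside `value_range`.")
  }
  if (purity < 0 || purity > 1) abort("`purity` must be in [0, 1].")
  edges <- c(value_range[1L], true_cuts, value_range[2L])
  if (any(diff(edges) <= 2 * margin)) {
    abort("`margin` leaves an empty interval; reduce it.")
  }
  structure(
    list(n = n, class_probs = class_probs, n_informative = n_informative,
         n_noise = n_noise, true_cuts = true_cuts, purity = purity,
         value_range = value_range, margin = margin),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic dataset with known cut-point structure
#'
#' Draws a dataset from a [synthetic_spec()] together with its ground
#' truth. All randomness flows from `seed`; each variable uses its own
#' derived seed, so individual variable streams are reproducible
#' independently of how many variables precede them.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A list with `data` (tibble: predictors `inf_*`, `noise_*`, and
#'   factor `class`) and `truth` (list: `informative` variable names,
#'   `true_cuts`, and `true_gaps`, a per-variable list of the realized data
#'   gap `[max below cut, min above cut]` flanking each true cut).
#' @export
generate_dataset <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  J <- length(spec$class_probs)
  set.seed(seed)
  cls <- sample.int(J, spec$n, replace = TRUE, prob = spec$class_probs)
  edges <- c(spec$value_range[1L], spec$true_cuts, spec$value_range[2L])
  n_int <- length(edges) - 1L
  lo <- edges[-length(edges)] + c(0, rep(spec$margin, n_int - 1L))
  hi <- edges[-1L] - c(rep(spec$margin, n_int - 1L), 0)
  interval_of_class <- ((seq_len(J) - 1L) %% n_int) + 1L

  draw_informative <- function(var_seed) {
    set.seed(var_seed)
    own <- interval_of_class[cls]
    use_own <- runif(spec$n) < spec$purity
    iv <- ifelse(use_own, own,
                 ((own - 1L + sample.int(n_int - 1L, spec$n, replace = TRUE))
                  %% n_int) + 1L)
    if (n_int == 1L) iv <- own
    runif(spec$n, lo[iv], hi[iv])
  }

  cols <- list()
  inf_names <- character(0)
  if (spec$n_informative > 0L) {
    inf_names <- sprintf("inf_%02d", seq_len(spec$n_informative))
    for (i in seq_len(spec$n_informative)) {
      cols[[inf_names[i]]] <- draw_informative(seed * 1000L + i)
    }
  }
  if (spec$n_noise > 0L) {
    noise_names <- sprintf("noise_%02d", seq_len(spec$n_noise))
    for (i in seq_len(spec$n_noise)) {
      set.seed(seed * 1000L + spec$n_informative + i)
      cols[[noise_names[i]]] <- runif(spec$n, spec$value_range[1L],
                                      spec$value_range[2L])
    }
  }
  data <- tibble::as_tibble(cols)
  data$class <- factor(paste0("c", cls), levels = paste0("c", seq_len(J)))

  true_gaps <- lapply(setNames(inf_names, inf_names), function(v) {
    x <- data[[v]]
    lapply(spec$true_cuts, function(cut) {
      below <- x[x < cut]; above <- x[x >= cut]
      if (!length(below) || !length(above)) return(c(NA_real_, NA_real_))
      c(max(below), min(above))
    })
  })

  list(
    data = data,
    truth = list(informative = inf_names, true_cuts = spec$true_cuts,
                 true_gaps = true_gaps)
  )
}

#' Did a discretization recover the true cut?
#'
#' A recovered cut value counts as correct when it falls strictly inside
#' the realized data gap flanking the true cut (the interval between the
#' largest observed value below the cut and the smallest at or above it).
#'
#' @param model A `discretization` object.
#' @param true_gap Length-2 numeric `(max below, min above)`.
#' @return `TRUE` iff the model has exactly one cut and it lies in the gap.
#' @export
cut_recovered <- function(model, true_gap) {
  if (model$n_intervals != 2L) return(FALSE)
  cut <- model$cut_values[1L]
  cut > true_gap[1L] && cut < true_gap[2L]
}
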