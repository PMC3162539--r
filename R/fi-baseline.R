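#' Class entropy of a count vector
#'
#' Shannon entropy, in bits, of the class proportions of a segment:
#' `-sum_j p_j log2(p_j)` with `0 log2 0 = 0`.
#'
#' @param counts Non-negative class-count vector with positive total.
#' @return Entropy in bits, in `[0, log2(n_classes)]`.
#' @examples
#' class_entropy(c(3, 3))  # 1
#' @export
class_entropy <- function(counts) {
  n <- sum(counts)
  if (n <= 0) abort("`counts` must have a positive total.")
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Entropy induced by a cut
#'
#' Weighted average of the class entropies of the two sub-segments created
#' by cutting a segment after position `cut` (positions are rows of the
#' segment's count matrix): `|S1|/|S| Ent(S1) + |S2|/|S| Ent(S2)`.
#'
#' @param cut Interior position: the left part is rows `1..cut`, the right
#'   part rows `cut+1..nrow`; `1 <= cut < nrow(counts)`.
#' @param counts Per-position class-count matrix of the segment.
#' @return Split entropy in bits; never exceeds the segment's own entropy.
#' @export
split_entropy <- function(cut, counts) {
  m <- nrow(counts)
  if (cut < 1 || cut >= m) abort("`cut` must split the segment into two non-empty parts.")
  left <- colSums(counts[seq_len(cut), , drop = FALSE])
  right <- colSums(counts[(cut + 1L):m, , drop = FALSE])
  n <- sum(left) + sum(right)
  (sum(left) / n) * class_entropy(left) + (sum(right) / n) * class_entropy(right)
}

#' MDLPC stopping criterion
#'
#' Decides whether the best cut of a segment is worth keeping under the
#' minimum-description-length principle: accept iff
#' `Gain > log2(N-1)/N + Delta/N` where `Gain = Ent(S) - Ent(C; S)`,
#' `N = |S|`, `Delta = log2(3^J - 2) - [J Ent(S) - J1 Ent(S1) - J2 Ent(S2)]`,
#' and `J`, `J1`, `J2` count the classes present in the whole segment and in
#' each part.
#'
#' @param cut Interior position of the candidate cut (row index).
#' @param counts Per-position class-count matrix of the segment.
#' @return `TRUE` to accept the cut, `FALSE` to stop recursion.
#' @export
mdl_accepts <- function(cut, counts) {
  m <- nrow(counts)
  total <- colSums(counts)
  left <- colSums(counts[seq_len(cut), , drop = FALSE])
  right <- colSums(counts[(cut + 1L):m, , drop = FALSE])
  N <- sum(total)
  ent_s <- class_entropy(total)
  ent_l <- class_entropy(left)
  ent_r <- class_entropy(right)
  gain <- ent_s - (sum(left) / N * ent_l + sum(right) / N * ent_r)
  J <- sum(total > 0)
  J1 <- sum(left > 0)
  J2 <- sum(right > 0)
  delta <- log2(3^J - 2) - (J * ent_s - J1 * ent_l - J2 * ent_r)
  gain > (log2(N - 1) / N + delta / N)
}

#' Recursive entropy-minimization discretization (Fayyad-Irani)
#'
#' Top-down greedy discretization: within each segment, the cut minimizing
#' the induced class entropy is selected (leftmost on ties); it is kept only
#' if it passes the MDLPC criterion ([mdl_accepts()]), in which case both
#' halves are discretized recursively. Cut values use the same
#' midpoint-between-distinct-values convention as [ebd_discretize()].
#'
#' @param sample A [sorted_sample()].
#' @param boundary_only If `TRUE`, restrict candidate cuts to class-boundary
#'   positions (gaps where the class mix changes); an optimization justified
#'   by the boundary-point theorem, identical results in practice.
#' @return A `discretization` object with `method = "fi"` and `log_score = NA`.
#' @examples
#' fi_discretize(toy_expression_sample())
#' @export
fi_discretize <- function(sample, boundary_only = FALSE) {
  stopifnot(inherits(sample, "sorted_sample"))
  np <- sample$n_distinct

  recurse <- function(from, to) {
    m <- to - from + 1L
    if (m < 2L) return(integer(0))
    seg <- sample$counts[from:to, , drop = FALSE]
    cand <- seq_len(m - 1L)
    if (boundary_only) {
      # keep gaps where the normalized class mix differs across the gap
      mix <- seg / rowSums(seg)
      changed <- rowSums(abs(mix[-1L, , drop = FALSE] -
                               mix[-m, , drop = FALSE])) > 0
      cand <- cand[changed]
      if (length(cand) == 0L) return(integer(0))
    }
    ents <- vapply(cand, split_entropy, numeric(1), counts = seg)
    best <- cand[which.min(ents)]
    if (!mdl_accepts(best, seg)) return(integer(0))
    cut_pos <- from + best - 1L          # global position of last value left of the cut
    c(recurse(from, cut_pos), cut_pos, recurse(cut_pos + 1L, to))
  }

  cuts <- recurse(1L, np)
  new_discretization(c(cuts, np), sample, NA_real_, "fi")
}
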