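#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement via the contingency-table formula
#' \deqn{ARI = (I - E) / (M - E)} with \eqn{I = \sum_{ij} C(n_{ij},2)},
#' \eqn{E = \sum_i C(a_i,2) \sum_j C(b_j,2) / C(n,2)} and
#' \eqn{M = (\sum_i C(a_i,2) + \sum_j C(b_j,2)) / 2}. Permutation-invariant
#' in the labels of either partition. When both partitions are identical —
#' including the degenerate single-cluster case, where the formula is 0/0 —
#' the index is defined as 1.
#'
#' @param a,b equal-length label vectors over the same subjects.
#' @return a number in \[-1, 1\].
#' @export
adjustedRandIndex <- function(a, b) {
  stopIf(length(a) == 0, "empty partitions")
  stopIf(length(a) != length(b), "partition lengths differ: %d vs %d",
         length(a), length(b))
  ct <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  I <- sum(ch2(ct))
  A <- sum(ch2(rowSums(ct)))
  B <- sum(ch2(colSums(ct)))
  E <- A * B / ch2(n)
  M <- (A + B) / 2
  # M == E only when both partitions are single-cluster or both are
  # all-singletons, i.e. structurally identical: score 1 by convention.
  if (abs(M - E) < .Machine$double.eps * max(1, M)) return(1)
  (I - E) / (M - E)
}
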