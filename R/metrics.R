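# External clustering agreement metrics.  All four are computed from the
# truth x prediction contingency table and are invariant to consistent
# relabeling of either partition.

check_partitions <- function(truth, pred) {
  if (length(truth) != length(pred))
    mvc_validation_error("truth and pred differ in length")
  if (length(truth) < 2) mvc_validation_error("need >= 2 spots")
  list(truth = canonicalize_labels(truth), pred = canonicalize_labels(pred))
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement corrected for chance under the permutation
#' model; 1 for identical partitions, ~0 for independent ones.
#'
#' @param truth,pred label vectors of equal length
#' @return scalar in `[-1, 1]`
#' @export
adjusted_rand_index <- function(truth, pred) {
  pp <- check_partitions(truth, pred)
  tab <- table(pp$truth, pp$pred)
  n <- length(pp$truth)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information (arithmetic-mean normalization)
#'
#' `I(T;P) / mean(H(T), H(P))`; 0 by convention when either partition has
#' a single cluster.
#'
#' @inheritParams adjusted_rand_index
#' @return scalar in `[0, 1]`
#' @export
normalized_mutual_information <- function(truth, pred) {
  pp <- check_partitions(truth, pred)
  tab <- table(pp$truth, pp$pred)
  n <- sum(tab)
  ht <- entropy_counts(rowSums(tab))
  hp <- entropy_counts(colSums(tab))
  if (ht == 0 || hp == 0) return(0)
  joint <- tab / n
  outer_p <- outer(rowSums(tab) / n, colSums(tab) / n)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer_p[nz]))
  mi / mean(c(ht, hp))
}

#' Homogeneity score
#'
#' `1 - H(T|P) / H(T)`: 1 when every predicted cluster contains members of
#' a single truth class; 1 by convention when the truth is a single class.
#'
#' @inheritParams adjusted_rand_index
#' @return scalar in `[0, 1]`
#' @export
homogeneity_score <- function(truth, pred) {
  pp <- check_partitions(truth, pred)
  tab <- table(pp$truth, pp$pred)
  n <- sum(tab)
  ht <- entropy_counts(rowSums(tab))
  if (ht == 0) return(1)
  # H(T|P) = sum_p P(p) * H(T | P = p)
  htp <- sum(vapply(seq_len(ncol(tab)), function(j) {
    cs <- tab[, j]
    sum(cs) / n * entropy_counts(cs)
  }, numeric(1)))
  1 - htp / ht
}

#' Purity
#'
#' Fraction of spots falling in their predicted cluster's majority truth
#' class.
#'
#' @inheritParams adjusted_rand_index
#' @return scalar in `(0, 1]`
#' @export
purity <- function(truth, pred) {
  pp <- check_partitions(truth, pred)
  tab <- table(pp$truth, pp$pred)
  sum(apply(tab, 2, max)) / sum(tab)
}

#' All four external metrics at once
#'
#' @inheritParams adjusted_rand_index
#' @return a `metric_report` list with `ari`, `nmi`, `hs`, `purity`,
#'   `n_spots`
#' @export
metric_report <- function(truth, pred) {
  structure(list(ari = adjusted_rand_index(truth, pred),
                 nmi = normalized_mutual_information(truth, pred),
                 hs = homogeneity_score(truth, pred),
                 purity = purity(truth, pred),
                 n_spots = length(truth)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("ARI %.3f | NMI %.3f | HS %.3f | Purity %.3f (n = %d)\n",
              x$ari, x$nmi, x$hs, x$purity, x$n_spots))
  invisible(x)
}
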