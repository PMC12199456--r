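## Entropy-based external clustering evaluation: homogeneity, completeness,
## and their harmonic mean (V-measure), computed from the class x cluster
## contingency table with natural-log entropies (the scores are ratios, so
## the base cancels).

.entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Homogeneity, completeness, and V-measure
#'
#' Compares a clustering against ground-truth classes. Homogeneity is 1 when
#' every cluster contains members of a single class; completeness is 1 when
#' all members of each class land in a single cluster. The V-measure is their
#' harmonic mean. All three lie in \[0, 1\] and are invariant to label
#' permutations. Conventions: `0 log 0 = 0`; homogeneity is 1 when the class
#' entropy is 0, completeness is 1 when the cluster entropy is 0, and the
#' V-measure is 0 when both scores are 0.
#'
#' @param truth_labels,cluster_labels equal-length label vectors.
#' @return list with `homogeneity`, `completeness`, `v_measure`.
#' @examples
#' v_measure(c(0, 0, 1, 1), c(1, 1, 1, 1))  # complete but inhomogeneous
#' @export
v_measure <- function(truth_labels, cluster_labels) {
  if (length(truth_labels) != length(cluster_labels)) {
    stop("label vectors must have equal length")
  }
  tab <- table(class = truth_labels, cluster = cluster_labels)
  n <- sum(tab)
  h_class <- .entropy(rowSums(tab))
  h_clust <- .entropy(colSums(tab))
  # conditional entropies from the joint table
  h_class_given_clust <- sum(vapply(seq_len(ncol(tab)), function(j) {
    cj <- tab[, j]
    if (sum(cj) == 0) 0 else sum(cj) / n * .entropy(cj)
  }, numeric(1)))
  h_clust_given_class <- sum(vapply(seq_len(nrow(tab)), function(i) {
    ci <- tab[i, ]
    if (sum(ci) == 0) 0 else sum(ci) / n * .entropy(ci)
  }, numeric(1)))
  h <- if (h_class == 0) 1 else 1 - h_class_given_clust / h_class
  c_ <- if (h_clust == 0) 1 else 1 - h_clust_given_class / h_clust
  v <- if (h + c_ == 0) 0 else 2 * h * c_ / (h + c_)
  list(homogeneity = h, completeness = c_, v_measure = v)
}
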