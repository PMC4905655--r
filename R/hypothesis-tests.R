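# The two binary lineage classifiers: depth difference (root distances)
# and independent clustering (within- vs between-group pairwise
# distances).  Both threshold a two-sided Welch t-test at alpha.

welch_p <- function(a, b) {
  # guard the degenerate constant-variance cases t.test() refuses
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Depth-difference classifier
#'
#' Tests whether two groups of cells sit at different depths of the
#' lineage tree by comparing their sets of root distances with a
#' two-sided Welch t-test; the classifier fires when `p <= alpha`.
#' When both groups are constant and equal the p-value is reported as 1.
#'
#' @param root_distances_A,root_distances_B Numeric vectors of per-cell
#'   root distances (each of length >= 2, see [root_distances()]).
#' @param alpha Significance threshold (default 0.05).
#' @return A list: `indicator` (0/1), `p_value`, and the two group means.
#' @export
depth_test <- function(root_distances_A, root_distances_B, alpha = 0.05) {
  stopifnot(length(root_distances_A) >= 2L, length(root_distances_B) >= 2L,
            alpha > 0, alpha < 1)
  p <- welch_p(root_distances_A, root_distances_B)
  list(indicator = as.integer(p <= alpha), p_value = p,
       mean_A = mean(root_distances_A), mean_B = mean(root_distances_B))
}

# distances for an explicit list of (i, j) index pairs
pair_distances <- function(table, pairs) {
  vapply(seq_len(nrow(pairs)), function(k)
    pairwise_distance(table, pairs[k, 1], pairs[k, 2]), numeric(1))
}

#' Independent-clustering classifier
#'
#' Tests whether two labeled cell groups are separated in the lineage tree
#' by comparing the within-group-A pairwise distances (unordered distinct
#' pairs of A) against the between-group distances (all A x B pairs) with
#' a two-sided Welch t-test; the classifier fires when `p <= alpha`.
#'
#' @param table A [mutation_table()].
#' @param labels Factor (or vector) of two group labels, one per row; the
#'   first level is group A.
#' @param alpha Significance threshold (default 0.05).
#' @return A list: `indicator` (0/1), `p_value`, `mean_within`
#'   (within-A mean distance), `mean_between` (A-B mean distance).
#' @export
clustering_test <- function(table, labels, alpha = 0.05) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2L, length(labels) == nrow(table),
            alpha > 0, alpha < 1)
  ia <- which(labels == levels(labels)[1])
  ib <- which(labels == levels(labels)[2])
  if (length(ia) < 2L || length(ib) < 1L)
    stop_with("invalid_spec", "group A needs >= 2 cells and group B >= 1")
  within <- pair_distances(table, t(utils::combn(ia, 2)))
  between <- pair_distances(table, as.matrix(expand.grid(ia, ib)))
  p <- welch_p(within, between)
  list(indicator = as.integer(p <= alpha), p_value = p,
       mean_within = mean(within), mean_between = mean(between))
}
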