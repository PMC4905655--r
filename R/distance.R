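# Absolute distance on mutation tables with missing entries, and triplet
# topology reconstruction.
#
# The distance between two samples averages |T_il - T_jl| over the loci
# with signal in BOTH samples; the denominator is the shared-loci count
# (not the panel size), so missing data rescales rather than shrinks the
# distance.  For SNV tables |.| is the mismatch indicator.

abs_diff <- function(a, b, kind) {
  if (kind == "SNV") as.numeric(a != b) else abs(a - b)
}

#' Absolute distance between two samples of a mutation table
#'
#' Mean of `|T_il - T_jl|` over the loci observed in both samples (STR:
#' repeat-count difference; SNV: 0/1 mismatch indicator).
#'
#' @param table A [mutation_table()].
#' @param i,j Row indices (or names) of the two samples; `i != j`.
#' @return A non-negative number.
#' @examples
#' tb <- mutation_table(rbind(c(12, NA, 7, 8, NA), c(10, NA, 7, 8, 11)), "STR")
#' pairwise_distance(tb, 1, 2)  # (|12-10| + 0 + 0) / 3 = 2/3
#' @export
pairwise_distance <- function(table, i, j) {
  a <- unclass(table)[i, ]; b <- unclass(table)[j, ]
  shared <- !is.na(a) & !is.na(b)
  if (!any(shared))
    stop_with("undefined_distance",
              "no locus with signal in both samples: distance undefined")
  mean(abs_diff(a[shared], b[shared], table_kind(table)))
}

#' Distance of a sample from the root of the tree
#'
#' Same absolute distance against the root genotype (the root has signal
#' at every locus), averaged over the sample's observed loci.  With the
#' default all-zero root this is the mean absolute offset and estimates
#' the cell's relative depth in the tree.
#'
#' @param table A [mutation_table()].
#' @param i Row index (or name) of the sample.
#' @param root Root genotype (default: all zeros).
#' @return A non-negative number.
#' @export
root_distance <- function(table, i, root = NULL) {
  a <- unclass(table)[i, ]
  obs <- !is.na(a)
  if (!any(obs))
    stop_with("undefined_distance", "sample has no observed locus")
  if (is.null(root)) root <- numeric(ncol(table))
  stopifnot(length(root) == ncol(table))
  mean(abs_diff(a[obs], root[obs], table_kind(table)))
}

#' Root distances of every sample in a table
#'
#' @inheritParams root_distance
#' @return Named numeric vector (one value per row).
#' @export
root_distances <- function(table, root = NULL) {
  vals <- unclass(table)
  if (any(rowSums(!is.na(vals)) == 0L))
    stop_with("undefined_distance", "a sample has no observed locus")
  if (is.null(root)) root <- numeric(ncol(vals))
  stopifnot(length(root) == ncol(vals))
  # column-major recycling of the root genotype across rows
  rootm <- rep(root, each = nrow(vals))
  d <- if (table_kind(table) == "SNV") (vals != rootm) + 0 else abs(vals - rootm)
  stats::setNames(rowMeans(d, na.rm = TRUE), rownames(vals))
}

#' All pairwise distances of a mutation table
#'
#' @param table A [mutation_table()].
#' @return A symmetric matrix with zero diagonal.  Pairs with no shared
#'   observed locus are `NA` and flagged in the `"undefined_pairs"`
#'   attribute.
#' @export
distance_matrix <- function(table) {
  M <- nrow(table)
  D <- matrix(0, M, M, dimnames = list(rownames(table), rownames(table)))
  undef <- NULL
  if (M > 1) {
    for (i in seq_len(M - 1)) {
      for (j in seq(i + 1, M)) {
        d <- tryCatch(pairwise_distance(table, i, j),
                      undefined_distance = function(e) NA_real_)
        if (is.na(d)) undef <- rbind(undef, c(i, j))
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  attr(D, "undefined_pairs") <- undef
  D
}

#' Reconstruct the topology of a triplet from its mutation table
#'
#' Neighbor joining on three taxa reduces to picking the pair with the
#' strictly smallest pairwise distance as the cherry.  Exact ties are
#' broken uniformly at random (a tie among all three picks each topology
#' with probability 1/3).
#'
#' @param table A 3-row [mutation_table()] with rows A, B, C.
#' @param seed Optional integer seed for the tie-break.
#' @return A list: `cherry` (`"AB"`, `"AC"` or `"BC"`, by row order),
#'   `distances` (named vector of the three pairwise distances),
#'   `tie` (was the minimum tied?).
#' @export
reconstruct_triplet <- function(table, seed = NULL) {
  if (nrow(table) != 3L)
    stop_with("invalid_table", "triplet reconstruction needs exactly 3 samples")
  d <- c(AB = pairwise_distance(table, 1, 2),
         AC = pairwise_distance(table, 1, 3),
         BC = pairwise_distance(table, 2, 3))
  mins <- which(d == min(d))
  pick <- if (length(mins) == 1L) mins else
    with_seed(seed, mins[sample.int(length(mins), 1L)])
  list(cherry = names(d)[pick], distances = d, tie = length(mins) > 1L)
}
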