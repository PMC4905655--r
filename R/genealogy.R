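# Genealogies of sampled cells.
#
# Full lineage trees at depth 40 would hold 2^40 cells, so only the
# genealogy induced on the sampled cells is simulated.  The underlying
# population is deterministically doubling: at g divisions below the root
# it holds min(2^g, cap) cells, each the child of cell floor(i/2) of the
# previous generation.  Sampled cells are assigned distinct individual
# indices and their ancestry is traced backwards; lineages whose ancestors
# collide coalesce.  This is exactly the induced subtree of distinct leaves
# of the (capped) complete binary division tree, so internal nodes are
# binary and all branch lengths are positive integers.  In the capped
# regime (population held at `cap`) each lineage picks a uniform parent, so
# a lineage pair coalesces there with probability 1/cap per generation.

new_genealogy <- function(parent, depth, label, root, leaf_ids) {
  structure(list(nodes = data.frame(id = seq_along(parent),
                                    parent = parent, depth = depth,
                                    label = label, stringsAsFactors = FALSE),
                 root = root, leaf_ids = leaf_ids),
            class = "sample_genealogy")
}

# Core backwards-coalescent builder.  `leaf_depths[i]` is the depth of leaf
# i; leaves join the backward process at their own depth (heterochronous
# sampling: a cell sampled at depth X is never an ancestor of one sampled
# deeper).  Returns a sample_genealogy rooted at depth 0.
coalesce_genealogy <- function(leaf_depths, labels, cap = 2^20) {
  n_leaf <- length(leaf_depths)
  stopifnot(n_leaf >= 2L, all(leaf_depths >= 1L), length(labels) == n_leaf,
            cap >= 1, cap <= 2^30)
  cap <- 2^floor(log2(cap))   # power of 2 so each generation halves or is capped
  pop <- function(g) min(2^g, cap)

  parent <- rep(NA_integer_, n_leaf)
  depth <- as.integer(leaf_depths)
  label <- as.character(labels)
  new_node <- function(d) {
    parent[length(parent) + 1L] <<- NA_integer_
    depth[length(depth) + 1L] <<- as.integer(d)
    label[length(label) + 1L] <<- NA_character_
    length(parent)
  }

  active_id <- integer(0)
  active_idx <- numeric(0)
  for (g in seq(max(leaf_depths), 1L)) {
    join <- which(leaf_depths == g)
    if (length(join)) {
      if (length(active_idx) + length(join) > pop(g))
        stop_with("invalid_genealogy",
                  sprintf("cannot place %d lineages in a population of %g at depth %d",
                          length(active_idx) + length(join), pop(g), g))
      repeat {  # distinct indices, also distinct from lineages already present
        idx <- sample.int(pop(g), length(join)) - 1
        if (!any(idx %in% active_idx)) break
      }
      active_id <- c(active_id, join)
      active_idx <- c(active_idx, idx)
    }
    if (pop(g - 1L) == pop(g)) {
      # capped regime: uniform parent choice; redraw the (astronomically
      # rare) generations with a 3-way collision to keep nodes binary
      repeat {
        par_idx <- sample.int(pop(g - 1L), length(active_id), replace = TRUE) - 1
        if (max(tabulate(match(par_idx, unique(par_idx)))) <= 2L) break
      }
    } else {
      par_idx <- floor(active_idx / 2)
    }
    dup_vals <- unique(par_idx[duplicated(par_idx)])
    for (v in dup_vals) {
      children <- active_id[par_idx == v]
      nd <- new_node(g - 1L)
      parent[children] <- nd
      keep <- par_idx != v
      active_id <- c(active_id[keep], nd)
      par_idx <- c(par_idx[keep], v)
    }
    active_idx <- par_idx
  }
  if (length(active_id) > 1L)
    stop_with("invalid_genealogy", "coalescence did not complete at the root")
  root <- active_id
  if (depth[root] > 0L) {      # MRCA below depth 0: add the trunk to the root
    r0 <- new_node(0L)
    parent[root] <- r0
    root <- r0
  }
  new_genealogy(parent, depth, label, root, seq_len(n_leaf))
}

#' Sample the genealogy of n cells from a doubling population
#'
#' Draws the ancestral tree of `n` cells sampled at `total_depth` divisions
#' below a single founder, under a deterministically doubling population
#' capped at `cap` cells.  Equivalent to sampling `n` distinct leaves of the
#' complete binary division tree and taking their induced ancestry, so the
#' result is a rooted tree with binary internal nodes and integer branch
#' lengths, rooted at depth 0.
#'
#' @param n Number of sampled cells (>= 2).
#' @param total_depth Divisions from root to the sampled cells (>= 1).
#' @param cap Population size cap (rounded down to a power of 2).
#' @param labels Optional leaf labels (default `"c1"`, `"c2"`, ...).
#' @param seed Optional integer seed.
#' @return A `sample_genealogy`: node table (id, parent, depth, label),
#'   root id, and leaf ids.
#' @examples
#' g <- sample_coalescent_genealogy(8, 6, seed = 1)
#' genealogy_depths(g)
#' @export
sample_coalescent_genealogy <- function(n, total_depth, cap = 2^20,
                                        labels = NULL, seed = NULL) {
  n <- as.integer(n); total_depth <- as.integer(total_depth)
  if (is.na(n) || n < 2L) stop_with("invalid_genealogy", "`n` must be >= 2")
  if (is.na(total_depth) || total_depth < 1L)
    stop_with("invalid_genealogy", "`total_depth` must be >= 1")
  if (is.null(labels)) labels <- paste0("c", seq_len(n))
  with_seed(seed, coalesce_genealogy(rep(total_depth, n), labels, cap = cap))
}

#' Leaf depths of a genealogy
#' @param genealogy A `sample_genealogy`.
#' @return Named integer vector of leaf depths.
#' @export
genealogy_depths <- function(genealogy) {
  stopifnot(inherits(genealogy, "sample_genealogy"))
  nd <- genealogy$nodes
  stats::setNames(nd$depth[genealogy$leaf_ids], nd$label[genealogy$leaf_ids])
}

# Depth of the most recent common ancestor of two leaves (by label or id).
mrca_depth <- function(genealogy, a, b) {
  nd <- genealogy$nodes
  id_of <- function(x) if (is.character(x)) nd$id[match(x, nd$label)] else x
  anc <- function(id) {
    path <- id
    while (!is.na(nd$parent[id])) { id <- nd$parent[id]; path <- c(path, id) }
    path
  }
  common <- intersect(anc(id_of(a)), anc(id_of(b)))
  max(nd$depth[common])
}

#' @export
print.sample_genealogy <- function(x, ...) {
  cat(sprintf("<sample_genealogy> %d leaves, %d nodes, max depth %d\n",
              length(x$leaf_ids), nrow(x$nodes), max(x$nodes$depth)))
  invisible(x)
}

#' Convert a sample genealogy to an ape "phylo" tree
#'
#' Branch lengths are integer division counts.  A root-level trunk (root
#' with a single child) is preserved as a root edge.
#'
#' @param x A `sample_genealogy`.
#' @param ... Unused.
#' @return An [ape][ape::read.tree] `phylo` object.
#' @method as.phylo sample_genealogy
#' @export
as.phylo.sample_genealogy <- function(x, ...) {
  nd <- x$nodes
  leaf <- x$leaf_ids
  internal <- setdiff(nd$id, leaf)
  # root must be the first internal node for a valid phylo numbering
  internal <- c(x$root, setdiff(internal, x$root))
  new_id <- integer(nrow(nd))
  new_id[leaf] <- seq_along(leaf)
  new_id[internal] <- length(leaf) + seq_along(internal)
  has_parent <- !is.na(nd$parent)
  edge <- cbind(new_id[nd$parent[has_parent]], new_id[nd$id[has_parent]])
  len <- nd$depth[has_parent] - nd$depth[nd$parent[has_parent]]
  tr <- structure(list(edge = edge, edge.length = as.numeric(len),
                       tip.label = nd$label[leaf],
                       Nnode = length(internal)),
                  class = "phylo", order = "cladewise")
  ape::collapse.singles(tr)
}

#' Write a genealogy to a Newick file
#' @param genealogy A `sample_genealogy`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_genealogy <- function(genealogy, path) {
  ape::write.tree(as.phylo.sample_genealogy(genealogy), file = path)
  invisible(path)
}

#' Evolve genotypes along a genealogy
#'
#' Starting from the all-zero root genotype, mutations accumulate along
#' every edge (k divisions = k applications of the per-division model,
#' simulated with the closed-form fast path of [propagate()]).
#'
#' @param genealogy A `sample_genealogy`.
#' @param model A [mutation_model()].
#' @param seed Optional integer seed.
#' @return A [mutation_table()] of true (pre-dropout) genotypes, one row
#'   per leaf, labeled by the genealogy's leaf labels.
#' @export
evolve_genotypes <- function(genealogy, model, seed = NULL) {
  stopifnot(inherits(genealogy, "sample_genealogy"),
            inherits(model, "mutation_model"))
  nd <- genealogy$nodes
  ord <- order(nd$depth)
  with_seed(seed, {
    geno <- vector("list", nrow(nd))
    for (id in nd$id[ord]) {
      if (is.na(nd$parent[id])) {
        geno[[id]] <- root_genotype(model)
      } else {
        k <- nd$depth[id] - nd$depth[nd$parent[id]]
        geno[[id]] <- propagate(geno[[nd$parent[id]]], k, model)
      }
    }
    values <- do.call(rbind, geno[genealogy$leaf_ids])
    rownames(values) <- nd$label[genealogy$leaf_ids]
    colnames(values) <- paste0("L", seq_len(model$n_loci))
    mutation_table(values, kind = model$kind, validate = FALSE)
  })
}
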