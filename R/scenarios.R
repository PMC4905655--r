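# The three lineage scenarios: triplet reconstruction, depth difference
# between two cell groups, and independent subclones, plus their matched
# null constructions.

#' Scenario specifications
#'
#' Constructors for the three lineage questions and their nulls:
#'
#' * `triplet_spec(X)`: a rooted triplet in which every edge segment spans
#'   `X` divisions — internal node at depth `X`, all three leaves at depth
#'   `2X`; the true cherry is the pair below the internal node.
#' * `depth_groups_spec(X, Y, nA, nB)`: group A sampled at depth `X`,
#'   group B at depth `X + Y`, both embedded in one shared genealogy.
#' * `subclone_spec(X, Y, nA, nB)`: two clone founders at depth `X`
#'   (coalescing within the first `X` divisions), each clone sampled `Y`
#'   divisions below its founder.
#' * `equal_depth_null_spec(X, nA, nB)`: both groups drawn from one
#'   genealogy at the same depth `X`, labels assigned at random — the null
#'   for the depth test.
#' * `mixed_clone_null_spec(depth, nA, nB)`: one well-mixed clone randomly
#'   partitioned into two labeled groups — the null for the clustering
#'   test.
#'
#' @param X,Y Edge depths in cell divisions (integers >= 1).
#' @param nA,nB Cells sampled per group/clone (>= 2).
#' @param depth Total depth of the single clone in the mixed null.
#' @return A scenario spec object.
#' @name scenario_specs
NULL

#' @rdname scenario_specs
#' @export
triplet_spec <- function(X) {
  X <- as.integer(X)
  if (is.na(X) || X < 1L) stop_with("invalid_spec", "`X` must be >= 1")
  structure(list(X = X), class = c("triplet_spec", "scenario_spec"))
}

check_groups <- function(X, Y, nA, nB) {
  v <- c(X = X, Y = Y, nA = nA, nB = nB)
  if (anyNA(v) || X < 1L || Y < 1L || nA < 2L || nB < 2L)
    stop_with("invalid_spec", "need X >= 1, Y >= 1, nA >= 2, nB >= 2")
}

#' @rdname scenario_specs
#' @export
depth_groups_spec <- function(X, Y, nA, nB) {
  X <- as.integer(X); Y <- as.integer(Y); nA <- as.integer(nA); nB <- as.integer(nB)
  check_groups(X, Y, nA, nB)
  structure(list(X = X, Y = Y, nA = nA, nB = nB),
            class = c("depth_groups_spec", "scenario_spec"))
}

#' @rdname scenario_specs
#' @export
subclone_spec <- function(X, Y, nA, nB) {
  X <- as.integer(X); Y <- as.integer(Y); nA <- as.integer(nA); nB <- as.integer(nB)
  check_groups(X, Y, nA, nB)
  structure(list(X = X, Y = Y, nA = nA, nB = nB),
            class = c("subclone_spec", "scenario_spec"))
}

#' @rdname scenario_specs
#' @export
equal_depth_null_spec <- function(X, nA, nB) {
  X <- as.integer(X); nA <- as.integer(nA); nB <- as.integer(nB)
  if (anyNA(c(X, nA, nB)) || X < 1L || nA < 2L || nB < 2L)
    stop_with("invalid_spec", "need X >= 1, nA >= 2, nB >= 2")
  structure(list(X = X, nA = nA, nB = nB),
            class = c("equal_depth_null_spec", "scenario_spec"))
}

#' @rdname scenario_specs
#' @export
mixed_clone_null_spec <- function(depth, nA, nB) {
  depth <- as.integer(depth); nA <- as.integer(nA); nB <- as.integer(nB)
  if (anyNA(c(depth, nA, nB)) || depth < 1L || nA < 2L || nB < 2L)
    stop_with("invalid_spec", "need depth >= 1, nA >= 2, nB >= 2")
  structure(list(depth = depth, nA = nA, nB = nB),
            class = c("mixed_clone_null_spec", "scenario_spec"))
}

#' Simulate a triplet tree and its true genotypes
#'
#' Topology: root -> internal node after `X` divisions; leaves A and B each
#' `X` divisions below the internal node; leaf C `2X` divisions directly
#' below the root.  All leaves are equidistant from the root and the true
#' cherry is AB.  With `blind = TRUE` the three leaf names are permuted at
#' random (the returned `cherry` follows the permutation), so downstream
#' reconstruction cannot exploit the fixed construction order.
#'
#' @param spec A [triplet_spec()].
#' @param model A [mutation_model()].
#' @param blind Permute leaf labels at random?
#' @param seed Optional integer seed.
#' @return A list: `table` (3-row [mutation_table()] of true genotypes),
#'   `cherry` (one of `"AB"`, `"AC"`, `"BC"`), `genealogy`.
#' @examples
#' sim <- simulate_triplet(triplet_spec(5), mutation_model("STR", 1e-2, 100), seed = 1)
#' sim$cherry
#' @export
simulate_triplet <- function(spec, model, blind = FALSE, seed = NULL) {
  stopifnot(inherits(spec, "triplet_spec"), inherits(model, "mutation_model"))
  X <- spec$X
  with_seed(seed, {
    # nodes: 1 = A, 2 = B, 3 = C (leaves), 4 = root, 5 = internal
    gen <- new_genealogy(parent = c(5L, 5L, 4L, NA, 4L),
                         depth = c(2L * X, 2L * X, 2L * X, 0L, X),
                         label = c("A", "B", "C", NA, NA),
                         root = 4L, leaf_ids = 1:3)
    tab <- evolve_genotypes(gen, model)
    cherry <- "AB"
    if (blind) {
      perm <- sample(c("A", "B", "C"))          # new name of original A, B, C
      cherry <- paste(sort(perm[1:2]), collapse = "")
      rownames(tab) <- perm
      tab <- tab[order(rownames(tab)), , drop = FALSE]
    }
    list(table = tab, cherry = cherry, genealogy = gen)
  })
}

#' Simulate two cell groups sampled at different depths
#'
#' Group A cells are sampled at depth `X`, group B cells at depth `X + Y`,
#' with all lineages embedded in one shared doubling-population genealogy
#' rooted at depth 0 (a sampled cell is never an ancestor of another).
#'
#' @param spec A [depth_groups_spec()].
#' @param model A [mutation_model()].
#' @param cap Population cap for the genealogy.
#' @param seed Optional integer seed.
#' @return A list: `table` (true genotypes), `labels` (factor `A`/`B` per
#'   row), `depths` (true depth per row), `genealogy`.
#' @export
simulate_depth_groups <- function(spec, model, cap = 2^20, seed = NULL) {
  stopifnot(inherits(spec, "depth_groups_spec"), inherits(model, "mutation_model"))
  with_seed(seed, {
    depths <- c(rep(spec$X, spec$nA), rep(spec$X + spec$Y, spec$nB))
    labels <- c(paste0("A", seq_len(spec$nA)), paste0("B", seq_len(spec$nB)))
    gen <- coalesce_genealogy(depths, labels, cap = cap)
    tab <- evolve_genotypes(gen, model)
    list(table = tab,
         labels = factor(rep(c("A", "B"), c(spec$nA, spec$nB))),
         depths = stats::setNames(depths, labels),
         genealogy = gen)
  })
}

#' Simulate the equal-depth null for the depth test
#'
#' All `nA + nB` cells are sampled at the same depth `X` from one shared
#' genealogy and the group labels are assigned by random permutation, so
#' any depth signal between the labeled groups is spurious.
#'
#' @param spec An [equal_depth_null_spec()].
#' @inheritParams simulate_depth_groups
#' @return As [simulate_depth_groups()] (all true depths equal `X`).
#' @export
simulate_equal_depth_null <- function(spec, model, cap = 2^20, seed = NULL) {
  stopifnot(inherits(spec, "equal_depth_null_spec"), inherits(model, "mutation_model"))
  with_seed(seed, {
    n <- spec$nA + spec$nB
    gen <- sample_coalescent_genealogy(n, spec$X, cap = cap)
    tab <- evolve_genotypes(gen, model)
    labels <- factor(sample(rep(c("A", "B"), c(spec$nA, spec$nB))))
    list(table = tab, labels = labels,
         depths = stats::setNames(rep(spec$X, n), rownames(tab)),
         genealogy = gen)
  })
}

#' Simulate two subclones separated at depth X
#'
#' Two founder cells at depth `X` (their lineages coalesce within the
#' first `X` divisions); each clone is then sampled `Y` divisions below its
#' founder through an independent within-clone doubling genealogy, so every
#' sampled cell sits at total depth `X + Y`.
#'
#' @param spec A [subclone_spec()].
#' @inheritParams simulate_depth_groups
#' @return A list: `table`, `labels` (factor `A`/`B`), `genealogy`.
#' @export
simulate_subclones <- function(spec, model, cap = 2^20, seed = NULL) {
  stopifnot(inherits(spec, "subclone_spec"), inherits(model, "mutation_model"))
  with_seed(seed, {
    founders <- coalesce_genealogy(rep(spec$X, 2L), c("fA", "fB"), cap = cap)
    parent <- founders$nodes$parent
    depth <- founders$nodes$depth
    label <- rep(NA_character_, length(parent))   # founders become internal
    graft <- function(clone_label, n_cells, founder_id) {
      sub <- coalesce_genealogy(rep(spec$Y, n_cells),
                                paste0(clone_label, seq_len(n_cells)), cap = cap)
      offset <- length(parent)
      keep <- sub$nodes$id != sub$root
      map <- integer(nrow(sub$nodes))
      map[sub$root] <- founder_id
      map[keep] <- offset + seq_len(sum(keep))
      parent <<- c(parent, map[sub$nodes$parent[keep]])
      depth <<- c(depth, sub$nodes$depth[keep] + spec$X)
      label <<- c(label, sub$nodes$label[keep])
      # grafted ids: map of the kept nodes, in their original order
      leaf_pos <- map[sub$leaf_ids]
      leaf_pos
    }
    # clone subtree roots sit at relative depth 0 = the founder cells
    leavesA <- graft("A", spec$nA, founder_id = 1L)
    leavesB <- graft("B", spec$nB, founder_id = 2L)
    gen <- new_genealogy(parent, depth, label, root = founders$root,
                         leaf_ids = c(leavesA, leavesB))
    tab <- evolve_genotypes(gen, model)
    list(table = tab,
         labels = factor(rep(c("A", "B"), c(spec$nA, spec$nB))),
         genealogy = gen)
  })
}

#' Simulate the mixed-clone null for the clustering test
#'
#' One well-mixed clone of `nA + nB` cells at the given depth, randomly
#' partitioned into two labeled groups: the labels carry no lineage
#' information.
#'
#' @param spec A [mixed_clone_null_spec()].
#' @inheritParams simulate_depth_groups
#' @return A list: `table`, `labels` (factor `A`/`B`), `genealogy`.
#' @export
simulate_mixed_clone_null <- function(spec, model, cap = 2^20, seed = NULL) {
  stopifnot(inherits(spec, "mixed_clone_null_spec"), inherits(model, "mutation_model"))
  with_seed(seed, {
    n <- spec$nA + spec$nB
    gen <- sample_coalescent_genealogy(n, spec$depth, cap = cap)
    tab <- evolve_genotypes(gen, model)
    labels <- factor(sample(rep(c("A", "B"), c(spec$nA, spec$nB))))
    list(table = tab, labels = labels, genealogy = gen)
  })
}
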