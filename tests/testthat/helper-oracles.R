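# Independent oracles used across the suite.  These deliberately
# re-derive quantities by brute force, without touching the package's own
# computation paths.

# Shared-loci absolute distance by an explicit double loop.
oracle_pairwise <- function(values, i, j, kind = "STR") {
  values <- unname(values)
  total <- 0; n <- 0
  for (l in seq_len(ncol(values))) {
    a <- values[i, l]; b <- values[j, l]
    if (!is.na(a) && !is.na(b)) {
      total <- total + if (kind == "SNV") as.numeric(a != b) else abs(a - b)
      n <- n + 1
    }
  }
  if (n == 0) return(NA_real_)
  total / n
}

# Forward simulation of the doubling-population genealogy: sample n
# distinct leaves of the complete binary tree of the given depth and read
# a random pair's coalescence depth off the common prefix of their paths.
oracle_pair_coalescence_depth <- function(n, depth) {
  leaves <- sample.int(2^depth, n) - 1L
  pair <- sample(leaves, 2)
  x <- bitwXor(pair[1], pair[2])
  depth - (floor(log2(x)) + 1L)
}

# Cherry of a triplet via full neighbor joining with the (perfectly
# observed, all-zero) root included as outgroup.  Returns NA when the NJ
# quartet is unresolved.
oracle_nj_cherry <- function(table) {
  vals <- rbind(unclass(table), root = 0)
  D <- matrix(0, 4, 4, dimnames = list(rownames(vals), rownames(vals)))
  for (i in 1:3) for (j in (i + 1):4) {
    D[i, j] <- D[j, i] <- oracle_pairwise(vals, i, j, attr(table, "kind"))
  }
  tr <- ape::nj(as.dist(D))
  tips <- setdiff(tr$tip.label, "root")
  rooted <- ape::root(tr, outgroup = "root", resolve.root = TRUE)
  all3 <- ape::getMRCA(rooted, tips)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    if (ape::getMRCA(rooted, tips[pair]) != all3)
      return(paste(sort(tips[pair]), collapse = ""))
  }
  NA_character_
}

random_str_table <- function(M, N, missing = 0.3) {
  v <- matrix(sample(-3:3, M * N, replace = TRUE), M, N)
  v[matrix(runif(M * N) < missing, M, N)] <- NA
  dimnames(v) <- list(LETTERS[seq_len(M)], paste0("L", seq_len(N)))
  mutation_table(v, "STR")
}
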