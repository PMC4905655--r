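test_that("triplet simulation: symmetric depths, AB cherry, rate-0 degenerate case", {
  m <- mutation_model("STR", 0, 50)
  sim <- simulate_triplet(triplet_spec(7), m, seed = 1)
  expect_identical(unname(genealogy_depths(sim$genealogy)), rep(14L, 3))
  expect_identical(sim$cherry, "AB")
  expect_true(all(unclass(sim$table) == 0))       # no mutations at rate 0

  m2 <- mutation_model("STR", 1e-2, 1e4)
  sim2 <- simulate_triplet(triplet_spec(20), m2, seed = 2)
  expect_identical(mrca_depth(sim2$genealogy, "A", "B"), 20L)
  expect_identical(mrca_depth(sim2$genealogy, "A", "C"), 0L)
})

test_that("high-signal triplets are reconstructed nearly always", {
  m <- mutation_model("STR", 1e-2, 1e4)   # 10k loci keeps the oracle-limit check fast
  acc <- triplet_accuracy(triplet_spec(20), model = m, dropout = NULL, noise = NULL,
                          n_reps = 200, seed = 3)
  expect_gte(acc, 0.99)
})

test_that("blinded triplets still carry a recoverable truth label", {
  m <- mutation_model("STR", 1e-2, 5000)
  hits <- vapply(1:50, function(s) {
    sim <- simulate_triplet(triplet_spec(20), m, blind = TRUE, seed = s)
    expect_setequal(rownames(sim$table), c("A", "B", "C"))
    reconstruct_triplet(sim$table)$cherry == sim$cherry
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # blinding randomizes which label pair is the cherry
  labs <- vapply(1:60, function(s)
    simulate_triplet(triplet_spec(2), m, blind = TRUE, seed = s)$cherry, character(1))
  expect_gt(length(unique(labs)), 1L)
})

test_that("depth-group scenario places groups at depths X and X+Y in one tree", {
  m <- mutation_model("STR", 1e-3, 2000)
  sim <- simulate_depth_groups(depth_groups_spec(6, 4, 5, 7), m, seed = 4)
  expect_identical(unname(sim$depths), c(rep(6L, 5), rep(10L, 7)))
  expect_identical(unname(genealogy_depths(sim$genealogy)), unname(sim$depths))
  expect_identical(as.character(sim$labels), rep(c("A", "B"), c(5, 7)))
  expect_identical(sum(is.na(sim$genealogy$nodes$parent)), 1L)

  # mean root distance difference ~ expected |walk| displacement for Y extra divisions
  m2 <- mutation_model("STR", 0.01, 5e4)
  sims <- lapply(1:6, function(s)
    simulate_depth_groups(depth_groups_spec(10, 20, 4, 4), m2, seed = 10 + s))
  gap <- mean(vapply(sims, function(s) {
    rd <- root_distances(s$table)
    mean(rd[s$labels == "B"]) - mean(rd[s$labels == "A"])
  }, numeric(1)))
  # B cells took 20 more divisions: with small per-locus totals the extra
  # displacement is close to the extra expected mutation count 20 * p
  expect_lt(abs(gap - 20 * 0.01), 0.04)
})

test_that("equal-depth null scrambles labels over one shared genealogy", {
  m <- mutation_model("STR", 1e-3, 500)
  sim <- simulate_equal_depth_null(equal_depth_null_spec(8, 6, 6), m, seed = 5)
  expect_identical(unname(genealogy_depths(sim$genealogy)), rep(8L, 12))
  expect_identical(sort(as.vector(table(sim$labels))), c(6L, 6L))
})

test_that("subclone scenario: founders at depth X, leaves at X+Y, clones separate", {
  m <- mutation_model("STR", 0, 100)
  sim <- simulate_subclones(subclone_spec(3, 5, 2, 2), m, seed = 6)
  expect_identical(unname(genealogy_depths(sim$genealogy)), rep(8L, 4))
  expect_true(all(unclass(sim$table) == 0))      # rate 0: identical genotypes
  expect_lte(mrca_depth(sim$genealogy, "A1", "B1"), 3L)
  expect_gte(mrca_depth(sim$genealogy, "A1", "A2"), 3L)

  # strong within-clone signal separates clones nearly always
  m2 <- mutation_model("STR", 1e-2, 5000)
  hits <- vapply(1:100, function(s) {
    sm <- simulate_subclones(subclone_spec(2, 20, 4, 4), m2, seed = s)
    D <- distance_matrix(sm$table)
    ia <- which(sm$labels == "A"); ib <- which(sm$labels == "B")
    within <- c(D[ia, ia][upper.tri(D[ia, ia])], D[ib, ib][upper.tri(D[ib, ib])])
    mean(D[ia, ib]) > mean(within)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("expected pairwise distance increases with divergence time", {
  m <- mutation_model("STR", 0.01, 3000)
  stats <- withr::with_seed(7, replicate(500, {
    d <- sample(3:25, 1)                 # spread divergence times widely
    g <- sample_coalescent_genealogy(2, d)
    tab <- evolve_genotypes(g, m)
    c(2 * (d - mrca_depth(g, 1, 2)), pairwise_distance(tab, 1, 2))
  }))
  expect_gt(cor(stats[1, ], stats[2, ], method = "spearman"), 0.9)
})

test_that("scenario specs validate their fields", {
  expect_error(triplet_spec(0), class = "invalid_spec")
  expect_error(depth_groups_spec(5, 0, 4, 4), class = "invalid_spec")
  expect_error(subclone_spec(0, 5, 4, 4), class = "invalid_spec")
  expect_error(mixed_clone_null_spec(5, 1, 4), class = "invalid_spec")
})
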