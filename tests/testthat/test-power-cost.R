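test_that("with no mutational signal the depth classifier fires at about alpha", {
  m <- mutation_model("STR", 0, 1000)     # only noise separates the groups
  rate <- estimate_power(depth_groups_spec(10, 5, 10, 10), model = m,
                         n_reps = 300, seed = 1)
  # correct-direction requirement halves the two-sided false-positive rate
  expect_lt(rate, 0.07)
  expect_gt(rate, 0.001)
})

test_that("extreme scenarios are detected nearly always", {
  m <- mutation_model("STR", 1e-2, 5000)
  pw <- estimate_power(depth_groups_spec(5, 30, 10, 10), model = m,
                       dropout = NULL, noise = NULL, n_reps = 100, seed = 2)
  expect_gte(pw, 0.99)
})

test_that("detection power is nondecreasing in the number of loci", {
  m <- mutation_model("STR", 1e-4, 1)
  loci <- c(500, 2000, 8000)
  pw <- vapply(loci, function(L)
    as.numeric(estimate_power(depth_groups_spec(40, 10, 2, 2), n_cells = 40,
                              n_loci = L, model = m, n_reps = 150, seed = 3)),
    numeric(1))
  mc <- 2 * sqrt(0.25 / 150)     # two-sided MC slack per estimate
  expect_true(all(diff(pw) > -mc))
  expect_gt(pw[3], pw[1])
})

test_that("triplet accuracy rises from the 1/3 baseline with informative loci", {
  m <- mutation_model("STR", 1e-3, 1)
  acc <- vapply(c(200, 1000, 5000), function(L)
    as.numeric(triplet_accuracy(triplet_spec(10), n_loci = L, model = m,
                                n_reps = 300, seed = 4)), numeric(1))
  mc <- 2 * sqrt(0.25 / 300)
  expect_true(all(diff(acc) > -mc))
  expect_gt(acc[3], 0.9)
  expect_gt(acc[1], 1 / 3)
})

test_that("power grids are deterministic given their seed", {
  m <- mutation_model("STR", 1e-3, 1)
  g1 <- power_grid(depth_groups_spec(10, 10, 2, 2), cells = c(10, 20),
                   loci = c(200, 800), model = m, n_reps = 20, seed = 5)
  g2 <- power_grid(depth_groups_spec(10, 10, 2, 2), cells = c(10, 20),
                   loci = c(200, 800), model = m, n_reps = 20, seed = 5)
  expect_identical(g1$power, g2$power)
  expect_true(all(g1$power >= 0 & g1$power <= 1))
})

fake_grid <- function(power, cells, loci) {
  structure(list(power = power, cells = as.integer(cells),
                 loci = as.integer(loci), n_reps = 1000L),
            class = "power_grid")
}

test_that("contours interpolate linearly along the loci axis", {
  g <- fake_grid(matrix(c(0.90, 1.00), 2, 1), cells = 50, loci = c(10000, 20000))
  ct <- extract_contour(g, 0.95)
  expect_equal(ct$n_loci, 15000)
  # an all-1 grid touches the level at the smallest loci value everywhere
  g2 <- fake_grid(matrix(1, 3, 2), cells = c(10, 20), loci = c(100, 200, 400))
  ct2 <- extract_contour(g2, 0.95)
  expect_equal(ct2$n_loci, c(100, 100))
  # unattainable level -> empty contour with a warning
  g3 <- fake_grid(matrix(0.5, 2, 2), cells = c(10, 20), loci = c(100, 200))
  expect_warning(ct3 <- extract_contour(g3, 0.95), "not attained")
  expect_identical(nrow(ct3), 0L)
})

test_that("contour loci are nonincreasing in cells on a monotone grid", {
  pw <- outer(seq(0.2, 1, length.out = 6), seq(0, 0.4, length.out = 5), function(a, b)
    pmin(1, a + b))
  g <- fake_grid(pw, cells = c(10, 25, 50, 100, 200),
                 loci = c(1, 2, 4, 8, 16, 32) * 1000)
  ct <- extract_contour(g, 0.95)
  expect_true(all(diff(ct$n_loci) <= 0))
})

test_that("isotonic smoothing tames Monte-Carlo jitter before interpolation", {
  g <- fake_grid(matrix(c(0.80, 0.93, 0.91, 0.99), 4, 1), cells = 10,
                 loci = c(1000, 2000, 3000, 4000) )
  ct <- extract_contour(g, 0.95)
  # smoothed column is 0.80, 0.92, 0.92, 0.99: crossing between 3000 and 4000
  expect_gt(ct$n_loci, 3000)
  expect_lt(ct$n_loci, 4000)
})

test_that("the linear cost model prices designs as loci + cells", {
  cm <- cost_model("STR")
  expect_equal(total_cost(cm, 0, 0), 0)
  expect_equal(total_cost(cm, 65000, 90), 1550)
  expect_equal(cost_model("SNV")$cost_per_locus, 1e-4)
  expect_equal(cm$cost_per_cell / cm$cost_per_locus, 1000)
})

test_that("cost optimization returns the contour argmin with fewest-cells ties", {
  cm <- cost_model("STR")
  ct <- data.frame(n_cells = c(50, 90, 200), n_loci = c(120000, 65000, 35000))
  best <- optimize_cost(ct, cm)
  expect_equal(best$n_cells, 90)
  expect_equal(best$cost, 1550)
  one <- optimize_cost(data.frame(n_cells = 10, n_loci = 100), cm)
  expect_equal(one$n_cells, 10)
  tie <- optimize_cost(data.frame(n_cells = c(10, 20), n_loci = c(2000, 1000)), cm)
  expect_equal(tie$n_cells, 10)    # equal cost, fewer cells wins
  expect_error(optimize_cost(data.frame(n_cells = integer(0), n_loci = numeric(0)),
                             cm), class = "empty_contour")
})

test_that("grid argmin recovers the analytic optimum of a continuous contour", {
  # loci(c) = 1e6 / c with costs (0.01, 10): f(c) = 1e4/c + 10c,
  # minimized at c* = sqrt(1e3) ~ 31.6 with f(c*) = 2 sqrt(1e5) ~ 632.5
  cells <- 1:200
  ct <- data.frame(n_cells = cells, n_loci = 1e6 / cells)
  best <- optimize_cost(ct, cost_model("STR"))
  expect_true(best$n_cells %in% c(31, 32))
  expect_lt(abs(best$cost - 2 * sqrt(1e5)), 1)
  # doubling the cell cost moves the optimum to fewer cells, never cheaper
  best2 <- optimize_cost(ct, cost_model("STR", cost_per_cell = 20))
  expect_lt(best2$n_cells, best$n_cells)
  expect_gt(best2$cost, best$cost)
})
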