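test_that("dropout keeps everything at p = q = 1 and nothing at p = 0", {
  tab <- mutation_table(matrix(1:20, 4, 5), "STR")
  all_on <- apply_dropout(tab, dropout_model(rep(1, 4), rep(1, 5)), seed = 1)
  expect_identical(unclass(all_on), unclass(tab))
  all_off <- apply_dropout(tab, dropout_model(rep(0, 4), rep(1, 5)), seed = 2)
  expect_true(all(is.na(all_off)))
})

test_that("entries survive dropout with probability p_i * q_j and are never altered", {
  M <- 100; N <- 100
  tab <- mutation_table(matrix(7L, M, N), "STR")
  out <- apply_dropout(tab, dropout_model(rep(0.8, M), rep(0.5, N)), seed = 3)
  n <- M * N
  expect_lt(abs(mean(!is.na(out)) - 0.4), 3 * sqrt(0.4 * 0.6 / n))
  expect_true(all(out[!is.na(out)] == 7L))
})

test_that("STR noise shifts observed entries by one unit at the stated rate", {
  tab <- mutation_table(matrix(0L, 200, 500), "STR")
  out <- apply_noise(tab, noise_model(str_shift_prob = 1), seed = 4)
  expect_true(all(abs(unclass(out)) == 1))

  s <- 0.01
  out <- apply_noise(tab, noise_model(str_shift_prob = s), seed = 5)
  n <- length(tab)
  expect_lt(abs(mean(out != 0) - s), 3 * sqrt(s * (1 - s) / n))
  expect_lt(abs(mean(unclass(out))), 3 * sqrt(s / n))

  expect_identical(unclass(apply_noise(tab, noise_model(0, 0), seed = 6)),
                   unclass(tab))
})

test_that("noise never resurrects missing entries; SNV errors hit other categories", {
  v <- matrix(c(0L, NA, 2L, NA, 1L, 3L), 2, 3)
  tab <- mutation_table(v, "SNV")
  out <- apply_noise(tab, noise_model(snv_error_prob = 1), seed = 7)
  expect_identical(is.na(out), is.na(v))
  obs <- !is.na(v)
  expect_true(all(out[obs] != v[obs]))
  expect_true(all(out[obs] %in% 0:3))
})

test_that("dropout log-likelihood matches direct arithmetic and is scale invariant", {
  expect_identical(dropout_log_likelihood(rep(1, 2), rep(1, 3),
                                          matrix(1L, 2, 3)), 0)
  expect_equal(dropout_log_likelihood(0.5, 0.5, matrix(0L, 1, 1)), log(0.75))
  withr::with_seed(8, {
    for (r in 1:10) {
      M <- sample(2:6, 1); N <- sample(2:8, 1)
      p <- runif(M, 0.1, 0.9); q <- runif(N, 0.1, 0.9)
      x <- matrix(rbinom(M * N, 1, 0.6), M, N)
      c0 <- runif(1, max(q), 1 / max(p))   # keeps both c*p and q/c in [0,1]
      expect_equal(dropout_log_likelihood(c0 * p, q / c0, x),
                   dropout_log_likelihood(p, q, x))
    }
  })
})

test_that("future enhancement scales signal by 1.25 (capped) and halves noise", {
  out <- enhance_future(dropout_model(c(0.4, 0.9), c(0.5, 1)),
                        noise_model(0.005, 1e-4))
  expect_equal(out$dropout$p, c(0.5, 1))
  expect_equal(out$dropout$q, c(0.625, 1))
  expect_equal(out$noise$str_shift_prob, 0.0025)
  expect_equal(out$noise$snv_error_prob, 5e-5)
  # prior variant carries the boost into its draws
  pr <- enhance_future(dropout_prior(), noise_model())$dropout
  expect_equal(pr$boost, 1.25)
  dm <- draw_dropout(pr, 500, 2, seed = 9)
  base <- draw_dropout(dropout_prior(), 500, 2, seed = 9)
  expect_equal(dm$p, pmin(1, 1.25 * base$p))
})

test_that("calibration fixtures are fast, seeded, and moment-consistent", {
  t0 <- Sys.time()
  fx <- generate_calibration_fixture(seed = 10)        # default 167 x 1000
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_identical(dim(fx$signal), c(167L, 1000L))
  expect_identical(fx$signal, generate_calibration_fixture(seed = 10)$signal)
  # grand mean ~ E[p] * E[q] = 0.8 * 0.5; Beta draws dominate the spread
  n_eff <- 167 + 1000
  expect_lt(abs(mean(fx$signal) - 0.4), 3 * sqrt(0.05 / n_eff) + 0.01)
  expect_equal(mean(fx$signal), mean(outer(fx$truth$p, fx$truth$q)),
               tolerance = 0.01)
})

test_that("distortion composes dropout then noise without reviving dropouts", {
  m <- mutation_model("STR", 1e-3, 2000)
  tab <- evolve_genotypes(sample_coalescent_genealogy(5, 10, seed = 11), m, seed = 12)
  out <- distort_table(tab, dropout_prior(), noise_model(0.5), seed = 13)
  expect_s3_class(out, "mutation_table")
  expect_gt(mean(is.na(out)), 0.2)
  # signal table marks exactly the missing pattern
  expect_identical(signal_table(out) == 0L, is.na(out))
})

test_that("duplicate inconsistency rate recovers the noise scale", {
  truth <- mutation_table(matrix(0L, 80, 2000), "STR")
  s <- 0.02
  d1 <- apply_noise(apply_dropout(truth, dropout_model(rep(0.9, 80), rep(0.8, 2000)),
                                  seed = 14), noise_model(s), seed = 15)
  d2 <- apply_noise(apply_dropout(truth, dropout_model(rep(0.9, 80), rep(0.8, 2000)),
                                  seed = 16), noise_model(s), seed = 17)
  rate <- estimate_str_noise(d1, d2)
  # each duplicate shifts independently: P(differ) = 2s(1-s) + s^2/2
  expected <- 2 * s * (1 - s) + s^2 / 2
  expect_lt(abs(rate - expected), 3 * sqrt(expected / sum(!is.na(d1) & !is.na(d2))))
  # and the rate is exactly the shared-loci disagreement fraction
  both <- !is.na(d1) & !is.na(d2)
  expect_equal(rate, mean(d1[both] != d2[both]))
})
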