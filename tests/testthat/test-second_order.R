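test_that("pair correlation: empty rings give zero, a single pair gives the hand value", {
  w <- c(0, 0, 100, 100)
  m <- stem_map(c(40, 50), c(50, 50), c("a", "a"), c(10, 10), window = w)
  g <- pair_correlation(m, "a", r = c(3, 5, 7, 20))
  expect_equal(g$value, c(0, 0, 0, 0))
  # three trees, one contributing pair at distance 3 (both orders)
  m3 <- stem_map(c(10, 10, 50), c(10, 13, 50), rep("a", 3), rep(10, 3),
                 window = w)
  g3 <- pair_correlation(m3, "a", r = 3, ring_width = 1)
  lam <- 3 / 1e4
  w_pair <- 1e4 / ((100 - 0) * (100 - 3))
  expect_equal(g3$value,
               2 * w_pair / (2 * pi * 3 * 1 * lam^2 * 1e4),
               tolerance = 1e-12)
  expect_equal(g3$pair_count, 2L)
  expect_error(pair_correlation(m3, "a", ring_width = 0), "positive")
})

test_that("g is NA below half the ring width and warns beyond the scale limit", {
  m <- rand_map(30, seed = 2, window = c(0, 0, 100, 100))
  g <- pair_correlation(m, "all", r = c(0.25, 1, 5), ring_width = 1)
  expect_true(is.na(g$value[1]))
  expect_false(anyNA(g$value[-1]))
  expect_warning(pair_correlation(m, "all", r = seq(1, 40)), "1/4")
})

test_that("bivariate K: zero when patterns are distant, exact for one pair", {
  w <- c(0, 0, 100, 100)
  m <- stem_map(c(10, 90), c(10, 90), c("a", "b"), c(10, 10), window = w)
  k <- ripley_k12(m, "a", "b", r = c(5, 10))
  expect_equal(k$value, c(0, 0))
  m2 <- stem_map(c(47.5, 52.5), c(50, 50), c("a", "b"), c(10, 10),
                 window = w)
  k2 <- ripley_k12(m2, "a", "b", r = 10)
  w_pair <- 1e4 / ((100 - 5) * 100)
  expect_equal(k2$value, w_pair / (1e-4 * 1e-4 * 1e4), tolerance = 1e-12)
})

test_that("g and K are symmetric in species order under translation correction", {
  m <- rand_map(60, n_species = 2, window = c(0, 0, 80, 80), seed = 5)
  g_ab <- pair_correlation(m, "A", "B", r = 1:15)
  g_ba <- pair_correlation(m, "B", "A", r = 1:15)
  expect_equal(g_ab$value, g_ba$value, tolerance = 1e-12)
  k_ab <- ripley_k12(m, "A", "B", r = 1:15)
  k_ba <- ripley_k12(m, "B", "A", r = 1:15)
  expect_equal(k_ab$value, k_ba$value, tolerance = 1e-12)
})

test_that("nearest-neighbour distribution: toy value, range and monotonicity", {
  w <- c(0, 0, 100, 100)
  m <- stem_map(c(50, 20, 50), c(50, 50, 60), c("a", "a", "b"),
                rep(10, 3), window = w)
  d <- nn_distribution_d12(m, "a", "b", r = 10)
  expect_equal(d$value, 0.5)
  # below the minimum a-to-b distance the estimate is 0
  expect_equal(nn_distribution_d12(m, "a", "b", r = 5)$value, 0)
  # uncorrected empirical CDF is nondecreasing and reaches 1
  m2 <- rand_map(40, n_species = 2, window = c(0, 0, 30, 30), seed = 6)
  d2 <- nn_distribution_d12(m2, "A", "B", r = seq(0.5, 40, by = 0.5),
                            correction = "none")
  expect_true(all(diff(d2$value) >= 0))
  expect_true(all(d2$value >= 0 & d2$value <= 1))
  expect_equal(max(d2$value), 1)
})

test_that("estimators agree with brute-force oracles on small maps", {
  for (s in 1:3) {
    m <- rand_map(sample(20:50, 1), n_species = 2, seed = 10 + s)
    r <- 1:10
    expect_equal(pair_correlation(m, "all", r = r)$value, bf_g(m, r),
                 tolerance = 1e-10)
    expect_equal(ripley_k12(m, "A", "B", r = r)$value,
                 bf_k12(m, "A", "B", r), tolerance = 1e-10)
    expect_equal(nn_distribution_d12(m, "A", "B", r = r)$value,
                 bf_d12(m, "A", "B", r), tolerance = 1e-10)
  }
})

test_that("closed-form CSR expectations evaluate correctly", {
  expect_equal(csr_expectation("g", r = c(1, 5, 10)), rep(1, 3))
  expect_equal(csr_expectation("K12", r = 10), 100 * pi)
  expect_equal(csr_expectation("D12", r = 0, lambda2 = 0.1), 0)
  expect_equal(csr_expectation("D12", r = 1, lambda2 = 0.1),
               1 - exp(-0.1 * pi))
  expect_error(csr_expectation("g", r = -1), "non-negative")
  expect_error(csr_expectation("D12", r = 1), "lambda2")
})
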