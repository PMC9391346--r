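make_est <- function(kind, r, value) {
  structure(list(kind = kind, r = r, value = value,
                 pair_count = rep(1L, length(r)), meta = list()),
            class = "second_order")
}

test_that("scheme axes are z-scores against the simulated null summary", {
  r <- 1:3
  # five fixed pseudo-simulations per statistic
  sims_k <- matrix(c(10, 12, 14, 16, 18), 5, 3)
  sims_d <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5), 5, 3)
  null <- list(r = r,
               mean_k = colMeans(sims_k), sd_k = apply(sims_k, 2, sd),
               mean_d = colMeans(sims_d), sd_d = apply(sims_d, 2, sd),
               nsim = 5)
  obs_k <- make_est("K12", r, c(14, 14 + 2 * sd(sims_k[, 1]), 20))
  obs_d <- make_est("D12", r, c(0.3, 0.3, 0.45))
  ax <- scheme_axes(obs_k, obs_d, null)
  expect_equal(ax$M[1], 0)
  expect_equal(ax$M[2], 2)
  expect_equal(ax$M[3], (20 - 14) / sd(sims_k[, 1]))
  expect_equal(ax$P[1], 0)
  expect_equal(ax$P[3], (0.45 - 0.3) / sd(sims_d[, 1]))
  # zero null SD -> undefined axis
  null$sd_k <- c(0, null$sd_k[2:3])
  ax0 <- scheme_axes(obs_k, obs_d, null)
  expect_true(is.na(ax0$M[1]))
  # mismatched grids refuse to combine
  bad <- make_est("K12", 1:4, rep(1, 4))
  expect_error(scheme_axes(bad, obs_d, null), "grids differ")
})

test_that("classification reproduces the five-type truth table", {
  # (P, M): origin -> 0; quadrants -> I to IV
  expect_equal(as.character(classify_association(0, 0)), "0")
  expect_equal(as.character(classify_association(-5, -5)), "I")
  expect_equal(as.character(classify_association(-5, 5)), "II")
  expect_equal(as.character(classify_association(5, 5)), "III")
  expect_equal(as.character(classify_association(5, -5)), "IV")
  # inside-box values are type 0 regardless of sign
  expect_equal(as.character(classify_association(2.33, -2.33)), "0")
  # a coordinate exactly 0 outside the box counts as positive
  expect_equal(as.character(classify_association(0, 5)), "III")
  expect_equal(as.character(classify_association(5, 0)), "III")
  # undefined axes propagate NA
  expect_true(is.na(classify_association(NA, 5)))
  # exhaustive and mutually exclusive over a sign grid
  grid <- expand.grid(P = c(-5, -1, 0, 1, 5), M = c(-5, -1, 0, 1, 5))
  types <- classify_association(grid$P, grid$M)
  expect_false(anyNA(types))
})

test_that("forced attraction and segregation are classified III and I at short range", {
  w <- c(0, 0, 100, 100)
  set.seed(31)
  p1 <- simulate_csr(150, w)
  # attraction: second species displaced 0.5 m from the first
  p2 <- p1 + 0.5
  p2 <- pmin(pmax(p2, 0), 100)
  m_att <- stem_map(c(p1[, 1], p2[, 1]), c(p1[, 2], p2[, 2]),
                    rep(c("A", "B"), each = 150), rep(10, 300), window = w)
  tr <- run_scheme(m_att, "A", "B", r = 1:10, null = "csr", nsim = 99,
                   seed = 1)
  expect_true(all(as.character(tr$type[1:3]) == "III"))
  # segregation: species confined to opposite half-windows
  q1 <- cbind(runif(150, 0, 45), runif(150, 0, 100))
  q2 <- cbind(runif(150, 55, 100), runif(150, 0, 100))
  m_seg <- stem_map(c(q1[, 1], q2[, 1]), c(q1[, 2], q2[, 2]),
                    rep(c("A", "B"), each = 150), rep(10, 300), window = w)
  tr2 <- run_scheme(m_seg, "A", "B", r = 1:10, null = "csr", nsim = 99,
                    seed = 2)
  # at r = 1 the null expectation is so small that a zero count may not
  # leave the acceptance box; from 2 m the deficit is unambiguous
  expect_true(all(as.character(tr2$type[2:8]) == "I"))
})

test_that("independent patterns are mostly type 0 under their own null", {
  w <- c(0, 0, 100, 100)
  set.seed(17)
  p1 <- simulate_csr(200, w); p2 <- simulate_csr(200, w)
  m <- stem_map(c(p1[, 1], p2[, 1]), c(p1[, 2], p2[, 2]),
                rep(c("A", "B"), each = 200), rep(10, 400), window = w)
  tr <- run_scheme(m, "A", "B", r = 1:25, null = "csr", nsim = 199,
                   seed = 3)
  expect_gte(mean(tr$type == "0", na.rm = TRUE), 0.8)
})
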