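test_that("four nearest neighbours: cross geometry, ties, and small-map error", {
  # centre of a cross with arms at distance 1 and corners farther away
  m <- stem_map(c(5, 6, 4, 5, 5, 9, 9), c(5, 5, 5, 6, 4, 9, 1),
                rep("a", 7), rep(10, 7), window = c(0, 0, 10, 10))
  rec <- four_nearest_neighbors(m, 1)
  expect_setequal(rec$neighbors, 2:5)
  expect_true(all(diff(rec$distances) >= 0))
  # two candidates at identical distance for the 4th slot -> lower id wins
  m2 <- stem_map(c(5, 6, 4, 5, 8, 2), c(5, 5, 5, 6, 5, 5),
                 rep("a", 6), rep(10, 6), window = c(0, 0, 10, 10))
  rec2 <- four_nearest_neighbors(m2, 1)
  expect_setequal(rec2$neighbors, c(2, 3, 4, 5))
  m3 <- rand_map(4, seed = 1)
  expect_error(four_nearest_neighbors(m3, 1), "at least 5")
})

test_that("neighbour search agrees with the all-pairs oracle on small maps", {
  for (s in 1:5) {
    m <- rand_map(sample(10:50, 1), seed = s)
    for (i in sample(n_trees(m), 5)) {
      expect_equal(four_nearest_neighbors(m, i)$neighbors, bf_nn4(m, i))
    }
  }
})

test_that("uniform angle index follows the min-angle gap convention", {
  expect_equal(uniform_angle_index(fake_record(c(0, 90, 180, 270))), 0)
  # gaps 10,10,10,330 -> angles 10,10,10,30: all below 72
  expect_equal(uniform_angle_index(fake_record(c(0, 10, 20, 30))), 1)
  # gaps 60,120,90,90 -> one angle below 72
  expect_equal(uniform_angle_index(fake_record(c(0, 60, 180, 270))), 0.25)
  # unsorted azimuth input is sorted internally
  expect_equal(uniform_angle_index(fake_record(c(180, 0, 270, 60))), 0.25)
})

test_that("uniform angle index is invariant under global rotation", {
  set.seed(21)
  n <- 40
  ang <- runif(1, 0, 2 * pi)
  x <- runif(n, 30, 70); y <- runif(n, 30, 70)
  rx <- 50 + cos(ang) * (x - 50) - sin(ang) * (y - 50)
  ry <- 50 + sin(ang) * (x - 50) + cos(ang) * (y - 50)
  w <- c(0, 0, 100, 100)
  m1 <- stem_map(x, y, rep("a", n), rep(10, n), window = w)
  m2 <- stem_map(rx, ry, rep("a", n), rep(10, n), window = w)
  u1 <- vapply(1:n, function(i)
    uniform_angle_index(four_nearest_neighbors(m1, i)), 0)
  u2 <- vapply(1:n, function(i)
    uniform_angle_index(four_nearest_neighbors(m2, i)), 0)
  expect_equal(u1, u2)
})

test_that("mingling and dominance indices count neighbours as defined", {
  m <- stem_map(c(5, 6, 4, 5, 5), c(5, 5, 5, 6, 4),
                c("a", "a", "a", "a", "a"), c(30, 10, 12, 14, 16),
                window = c(0, 0, 10, 10))
  rec <- four_nearest_neighbors(m, 1)
  expect_equal(mingling_index(rec, m$species), 0)
  expect_equal(mingling_index(rec, c("a", "b", "b", "b", "b")), 1)
  expect_equal(mingling_index(rec, c("a", "a", "a", "b", "b")), 0.5)
  # reference dbh 30 dominates all four neighbours
  expect_equal(neighborhood_comparison_index(rec, m$dbh), 0)
  expect_equal(neighborhood_comparison_index(rec, c(5, 10, 12, 14, 16)), 1)
  # one exact tie counts toward "not smaller"
  expect_equal(neighborhood_comparison_index(rec, c(14, 10, 12, 13, 14)),
               0.25)
})

test_that("all indices live on the five-point scale over random maps", {
  m <- rand_map(80, n_species = 4, window = c(0, 0, 100, 100), seed = 4)
  tab <- structural_indices(m, buffer = 5)
  vals <- c(tab$U, tab$M, tab$N)
  expect_true(all(abs(vals * 4 - round(vals * 4)) < 1e-9))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("edge filter flags buffer trees and rejects absurd buffers", {
  m <- stem_map(c(2, 50, 97), c(50, 50, 50), rep("a", 3), rep(10, 3),
                window = c(0, 0, 100, 100))
  expect_equal(edge_filter(m, 5), c(TRUE, FALSE, TRUE))
  expect_equal(edge_filter(m, 0), rep(FALSE, 3))
  expect_error(edge_filter(m, 50), "too large")
})

test_that("index distributions are relative frequencies with the right mean", {
  tab <- data.frame(tree = 1:4, species = "a", dbh = 10,
                    U = c(0, 0, 1, 1), M = 0, N = 0,
                    edge_excluded = FALSE)
  d <- index_distribution(tab, "U", "a")
  expect_equal(sum(d$frequencies), 1)
  expect_equal(unname(d$frequencies[c(1, 5)]), c(0.5, 0.5))
  expect_equal(d$mean, 0.5)
  tab1 <- tab[3, ]; tab1$U <- 0.25
  d1 <- index_distribution(tab1, "U", "a")
  expect_equal(unname(d1$frequencies[2]), 1)
  expect_equal(d1$mean, 0.25)
  tab$edge_excluded <- TRUE
  expect_error(index_distribution(tab, "U", "a"), "no included")
})
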