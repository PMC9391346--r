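test_that("constructor validates coordinates, marks and window", {
  expect_s3_class(stem_map(1:3, 1:3, c("a", "b", "a"), c(10, 20, 30),
                           window = c(0, 0, 100, 100)), "stem_map")
  expect_error(stem_map(1, 1, "a", 10, window = c(0, 0, 0, 100)),
               "positive width")
  expect_error(stem_map(c(1, 101), c(1, 1), c("a", "a"), c(10, 10),
                        window = c(0, 0, 100, 100)),
               "row: 2")
  expect_error(stem_map(1, 1, "a", 0, window = c(0, 0, 10, 10)),
               "strictly positive")
  expect_error(stem_map(1:2, 1:3, c("a", "b", "a"), c(10, 20, 30),
                        window = c(0, 0, 100, 100)),
               "equal length")
  # boundary trees are kept
  m <- stem_map(c(0, 100), c(0, 100), c("a", "b"), c(10, 10),
                window = c(0, 0, 100, 100))
  expect_equal(n_trees(m), 2L)
})

test_that("read_stem_map enforces columns, filters small stems and reports", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,species,dbh", "10,10,Bp,12.5", "20,30,Pk,4.0",
               "50,50,Bp,30"), f)
  expect_message(m <- read_stem_map(f, window = c(0, 0, 100, 100)),
                 "dropped 1")
  expect_equal(n_trees(m), 2L)
  expect_equal(attr(m, "n_dropped"), 1L)

  writeLines(c("x,y,species,dbh", "10,10,Bp,12.5", "20,30,Pk,6.0",
               "50,50,Bp,30"), f)
  m <- read_stem_map(f, window = c(0, 0, 100, 100))
  expect_equal(n_trees(m), 3L)

  writeLines(c("x,y,species,dbh", "101,10,Bp,12.5"), f)
  expect_error(read_stem_map(f, window = c(0, 0, 100, 100)), "row: 1")

  writeLines(c("x,y,dbh", "1,1,10"), f)
  expect_error(read_stem_map(f), "species")

  writeLines(c("x,y,species,dbh", "oops,1,Bp,10"), f)
  expect_error(read_stem_map(f), "non-numeric")
})

test_that("write + re-read round-trips a stem map exactly", {
  m <- rand_map(40, seed = 7, window = c(0, 0, 60, 60))
  f <- withr::local_tempfile(fileext = ".csv")
  write_stem_map(m, f)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  m2 <- read_stem_map(f, min_dbh = 0,
                      window = unlist(meta$window))
  expect_equal(m2$x, m$x)
  expect_equal(m2$y, m$y)
  expect_equal(m2$species, m$species)
  expect_equal(m2$dbh, m$dbh)
  expect_equal(m2$window, m$window)
})

test_that("intensity is count over window area", {
  p <- simulate_csr(500, c(0, 0, 100, 100), seed = 1)
  m <- stem_map(p[, 1], p[, 2], rep("Pk", 500), rep(10, 500),
                window = c(0, 0, 100, 100))
  expect_equal(intensity(m), 0.05)
  expect_error(intensity(m, "Bp"), "no trees")
  # the 571-stems-per-hectare case
  p <- simulate_csr(571, c(0, 0, 100, 100), seed = 2)
  m <- stem_map(p[, 1], p[, 2], rep("Pk", 571), rep(10, 571),
                window = c(0, 0, 100, 100))
  expect_equal(intensity(m, "Pk"), 0.0571)
})

test_that("subplot assignment covers the window with half-open closed-top cells", {
  m <- stem_map(c(0, 100, 50, 19.999), c(0, 100, 50, 0),
                rep("a", 4), rep(10, 4), window = c(0, 0, 100, 100))
  cells <- subplot_assignment(m, 20)
  expect_equal(cells$n_cells, 25L)
  expect_equal(c(cells$ix[1], cells$iy[1]), c(0L, 0L))
  expect_equal(c(cells$ix[2], cells$iy[2]), c(4L, 4L))  # closed top edge
  expect_equal(cells$ix[4], 0L)
  expect_error(subplot_assignment(m, 0), "positive")
  expect_warning(subplot_assignment(m, 30), "ragged")
  # per-cell counts sum to the tree count
  big <- rand_map(200, seed = 3, window = c(0, 0, 100, 100))
  cl <- subplot_assignment(big, 20)
  expect_equal(sum(tabulate(cl$cell, cl$n_cells)), 200L)
  expect_true(all(cl$cell >= 1 & cl$cell <= cl$n_cells))
})
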