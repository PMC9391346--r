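# Independent brute-force oracles, written as plain double loops so they
# share no code path with the package's vectorised estimators.

rand_map <- function(n, n_species = 3, window = c(0, 0, 50, 50),
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stem_map(runif(n, window[1], window[3]), runif(n, window[2], window[4]),
           sample(LETTERS[seq_len(n_species)], n, replace = TRUE),
           runif(n, 5, 40), window = window)
}

trans_w <- function(dx, dy, window) {
  lx <- window[3] - window[1]; ly <- window[4] - window[2]
  (lx * ly) / ((lx - abs(dx)) * (ly - abs(dy)))
}

bf_g <- function(map, r, h = 1) {
  n <- n_trees(map); W <- window_area(map); lam <- n / W
  vapply(r, function(rk) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dx <- map$x[i] - map$x[j]; dy <- map$y[i] - map$y[j]
      d <- sqrt(dx^2 + dy^2)
      if (abs(d - rk) <= h / 2) s <- s + trans_w(dx, dy, map$window)
    }
    s / (2 * pi * rk * h * lam^2 * W)
  }, 0)
}

bf_k12 <- function(map, sa, sb, r) {
  ia <- which(map$species == sa); ib <- which(map$species == sb)
  W <- window_area(map)
  la <- length(ia) / W; lb <- length(ib) / W
  vapply(r, function(rk) {
    s <- 0
    for (i in ia) for (j in ib) {
      if (i == j) next
      dx <- map$x[i] - map$x[j]; dy <- map$y[i] - map$y[j]
      if (sqrt(dx^2 + dy^2) <= rk) s <- s + trans_w(dx, dy, map$window)
    }
    s / (la * lb * W)
  }, 0)
}

bf_d12 <- function(map, sa, sb, r) {
  ia <- which(map$species == sa); ib <- which(map$species == sb)
  w <- map$window
  vapply(r, function(rk) {
    num <- 0L; den <- 0L
    for (i in ia) {
      bd <- min(map$x[i] - w[1], w[3] - map$x[i],
                map$y[i] - w[2], w[4] - map$y[i])
      if (bd < rk) next
      nnd <- Inf
      for (j in ib) {
        if (j == i) next
        d <- sqrt((map$x[i] - map$x[j])^2 + (map$y[i] - map$y[j])^2)
        nnd <- min(nnd, d)
      }
      den <- den + 1L
      if (nnd <= rk) num <- num + 1L
    }
    if (den == 0L) NA_real_ else num / den
  }, 0)
}

bf_gamma <- function(map, r, h = 1) {
  n <- n_trees(map)
  s2 <- var(map$dbh)
  vapply(r, function(rk) {
    num <- 0; den <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dx <- map$x[i] - map$x[j]; dy <- map$y[i] - map$y[j]
      d <- sqrt(dx^2 + dy^2)
      if (abs(d - rk) <= h / 2) {
        w <- trans_w(dx, dy, map$window)
        num <- num + w * 0.5 * (map$dbh[i] - map$dbh[j])^2
        den <- den + w
      }
    }
    if (den == 0) NA_real_ else num / den / s2
  }, 0)
}

# sorted-form Gini: G = (2 sum_i i v_(i)) / (n sum v) - (n + 1) / n
bf_gini_sorted <- function(v) {
  v <- sort(v); n <- length(v)
  2 * sum(seq_len(n) * v) / (n * sum(v)) - (n + 1) / n
}

bf_nn4 <- function(map, i) {
  d <- sqrt((map$x - map$x[i])^2 + (map$y - map$y[i])^2)
  cand <- setdiff(seq_len(n_trees(map)), i)
  cand[order(d[cand], cand)][1:4]
}

# neighbour record built directly (for index-arithmetic tests)
fake_record <- function(azimuth_deg, reference = 1L,
                        neighbors = 2:5) {
  list(reference = reference, neighbors = neighbors,
       distances = rep(1, 4), azimuths = azimuth_deg * pi / 180)
}
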