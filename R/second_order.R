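# Pair machinery shared by the second-order statistics and the mark
# variogram. All estimators use ordered pairs and, under the translation
# edge correction, weight each pair by |W| / ((Lx - |dx|)(Ly - |dy|)) —
# the reciprocal of the proportion of translations of the window that keep
# both endpoints inside it.

# Ordered pairs between two coordinate sets. For `same = TRUE` the two sets
# are the same pattern and self-pairs are excluded. Pairs farther than dmax
# are dropped immediately to bound memory. Returns d (distance), w (edge
# weight) and the pair indices.
cross_pairs <- function(ax, ay, bx, by, window, same, dmax,
                        correction = c("translation", "none")) {
  correction <- match.arg(correction)
  dx <- outer(ax, bx, "-")
  dy <- outer(ay, by, "-")
  d <- sqrt(dx^2 + dy^2)
  keep <- d <= dmax
  if (same) {
    diag(keep) <- FALSE
  }
  idx <- which(keep, arr.ind = TRUE)
  d <- d[keep]
  if (correction == "translation") {
    sides <- window_sides(window)
    w <- (sides[1L] * sides[2L]) /
      ((sides[1L] - abs(dx[keep])) * (sides[2L] - abs(dy[keep])))
  } else {
    w <- rep(1, length(d))
  }
  list(d = d, w = w, i = idx[, 1L], j = idx[, 2L])
}

second_order_estimate <- function(kind, r, value, pair_count, meta) {
  structure(list(kind = kind, r = r, value = value,
                 pair_count = pair_count, meta = meta),
            class = "second_order")
}

#' @export
print.second_order <- function(x, ...) {
  cat(sprintf("Second-order estimate %s: %d distances in [%g, %g] m (%s correction)\n",
              x$kind, length(x$r), min(x$r), max(x$r),
              x$meta$correction %||% "none"))
  invisible(x)
}

#' @export
as.data.frame.second_order <- function(x, ...) {
  data.frame(r = x$r, value = x$value, pair_count = x$pair_count)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.second_order <- function(x, ...) {
  graphics::plot(x$r, x$value, type = "l", xlab = "r (m)", ylab = x$kind,
                 ...)
  ref <- switch(x$kind, g11 = , g12 = 1, K12 = NA, D12 = NA, NA)
  if (!is.na(ref)) graphics::abline(h = ref, lty = 2)
  invisible(x)
}

check_r_scale <- function(r, window) {
  lim <- min(window_sides(window)) / 4
  if (max(r) > lim) {
    warning(sprintf("max(r) = %g m exceeds 1/4 of the smaller plot dimension (%g m); estimates at large r are unreliable",
                    max(r), lim))
  }
}

#' Pair correlation function (ring estimator, translation correction)
#'
#' Non-cumulative second-order statistic: the expected density of (other)
#' points at distance r from a typical point, divided by the intensity.
#' Under complete spatial randomness g(r) = 1; g > 1 indicates aggregation
#' and g < 1 regularity at scale r. The bivariate version replaces "other
#' points of the same pattern" by points of a second species; g12 = 1 then
#' means independence, > 1 positive and < 1 negative association.
#'
#' The estimator counts ordered pairs whose distance falls in a ring of
#' width `ring_width` centred on each r, weights them by the translation
#' edge correction, and normalises by `2 pi r * ring_width * lambda_a *
#' lambda_b * |W|` (with `lambda^2` in the univariate case). Values at
#' `r < ring_width / 2` are reported as `NA`: the ring then overlaps zero
#' distance and the 1/(2 pi r) normalisation is unstable below stem scale.
#'
#' @param map A `stem_map`.
#' @param sp_a Species of the first pattern, or `"all"`.
#' @param sp_b Species of the second pattern; defaults to `sp_a`
#'   (univariate).
#' @param r Distance grid in metres; default `1:25` univariate, `1:30`
#'   bivariate. A warning is issued beyond 1/4 of the smaller plot
#'   dimension.
#' @param ring_width Ring (bin) width in metres, default 1.
#' @param correction `"translation"` (default) or `"none"`.
#' @return A `second_order` object (kind `"g11"` or `"g12"`).
#' @examples
#' pts <- simulate_csr(200, c(0, 0, 100, 100), seed = 7)
#' m <- stem_map(pts[, 1], pts[, 2], rep("A", 200), rep(10, 200),
#'               window = c(0, 0, 100, 100))
#' g <- pair_correlation(m, "A")
#' mean(g$value[g$r >= 5])  # close to 1 under CSR
#' @export
pair_correlation <- function(map, sp_a = "all", sp_b = sp_a, r = NULL,
                             ring_width = 1,
                             correction = c("translation", "none")) {
  correction <- match.arg(correction)
  if (ring_width <= 0) stop("ring_width must be positive")
  same <- identical(sp_a, sp_b)
  if (is.null(r)) r <- if (same) seq_len(25) else seq_len(30)
  check_r_scale(r, map$window)
  a <- subset_species(map, sp_a)
  b <- subset_species(map, sp_b)
  if (n_trees(a) < 2L || n_trees(b) < 2L) {
    stop("need at least 2 trees in each pattern")
  }
  W <- window_area(map)
  lam_a <- n_trees(a) / W
  lam_b <- n_trees(b) / W
  p <- cross_pairs(a$x, a$y, b$x, b$y, map$window, same,
                   dmax = max(r) + ring_width / 2, correction = correction)
  value <- pc <- numeric(length(r))
  for (k in seq_along(r)) {
    sel <- abs(p$d - r[k]) <= ring_width / 2
    pc[k] <- sum(sel)
    value[k] <- sum(p$w[sel]) /
      (2 * pi * r[k] * ring_width * lam_a * lam_b * W)
  }
  value[r < ring_width / 2] <- NA_real_
  second_order_estimate(if (same) "g11" else "g12", r, value, pc,
                        list(species = c(sp_a, sp_b),
                             ring_width = ring_width,
                             correction = correction,
                             lambda = c(lam_a, lam_b)))
}

#' Bivariate Ripley K function
#'
#' Cumulative second-order statistic: `lambda_b * K12(r)` is the expected
#' number of pattern-b points within distance r of a typical pattern-a
#' point. Under independence of the two patterns its expectation is
#' `pi r^2`.
#'
#' @inheritParams pair_correlation
#' @param sp_a,sp_b Species labels of the two patterns (may be equal, in
#'   which case self-pairs are excluded).
#' @param r Distance grid, default `1:30`.
#' @return A `second_order` object (kind `"K12"`).
#' @export
ripley_k12 <- function(map, sp_a, sp_b, r = seq_len(30),
                       correction = c("translation", "none")) {
  correction <- match.arg(correction)
  check_r_scale(r, map$window)
  same <- identical(sp_a, sp_b)
  a <- subset_species(map, sp_a)
  b <- subset_species(map, sp_b)
  if (n_trees(a) < 1L || n_trees(b) < 1L) stop("empty pattern")
  W <- window_area(map)
  lam_a <- n_trees(a) / W
  lam_b <- n_trees(b) / W
  p <- cross_pairs(a$x, a$y, b$x, b$y, map$window, same,
                   dmax = max(r), correction = correction)
  ord <- order(p$d)
  d_s <- p$d[ord]
  w_cum <- cumsum(p$w[ord])
  idx <- findInterval(r, d_s)
  value <- ifelse(idx > 0L, w_cum[pmax(idx, 1L)], 0) / (lam_a * lam_b * W)
  pc <- idx
  second_order_estimate("K12", r, as.numeric(value), as.integer(pc),
                        list(species = c(sp_a, sp_b),
                             correction = correction,
                             lambda = c(lam_a, lam_b)))
}

#' Bivariate nearest-neighbour distribution function D12
#'
#' Empirical distribution, over pattern-a trees, of the distance to the
#' nearest pattern-b tree. With the reduced-sample border correction only
#' a-trees at least r from every window edge contribute at distance r
#' (their nearest-b distance cannot be censored by the boundary); with
#' `correction = "none"` the plain empirical CDF over all a-trees is
#' returned (monotone by construction, but negatively biased near the
#' boundary).
#'
#' @inheritParams ripley_k12
#' @param correction `"reduced"` (reduced-sample border correction,
#'   default) or `"none"`.
#' @return A `second_order` object (kind `"D12"`); values in `[0, 1]`,
#'   `NA` where no a-tree qualifies.
#' @export
nn_distribution_d12 <- function(map, sp_a, sp_b, r = seq_len(30),
                                correction = c("reduced", "none")) {
  correction <- match.arg(correction)
  same <- identical(sp_a, sp_b)
  a <- subset_species(map, sp_a)
  b <- subset_species(map, sp_b)
  if (n_trees(a) < 1L || n_trees(b) < 1L) stop("empty pattern")
  if (same && n_trees(b) < 2L) stop("need 2 trees for same-species D")
  dm <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
  if (same) diag(dm) <- Inf
  nnd <- apply(dm, 1L, min)
  w <- map$window
  bdist <- pmin(a$x - w[1L], w[3L] - a$x, a$y - w[2L], w[4L] - a$y)
  value <- pc <- numeric(length(r))
  for (k in seq_along(r)) {
    inc <- if (correction == "reduced") bdist >= r[k] else rep(TRUE, length(nnd))
    pc[k] <- sum(inc)
    value[k] <- if (pc[k] > 0L) mean(nnd[inc] <= r[k]) else NA_real_
  }
  second_order_estimate("D12", r, value, as.integer(pc),
                        list(species = c(sp_a, sp_b),
                             correction = correction,
                             lambda = c(n_trees(a), n_trees(b)) /
                               window_area(map)))
}

#' Closed-form expectations under complete spatial randomness
#'
#' Reference values of the second-order statistics when the pattern(s) are
#' homogeneous Poisson and independent: `g(r) = 1`, `K12(r) = pi r^2`, and
#' `D12(r) = 1 - exp(-lambda2 pi r^2)` where `lambda2` is the intensity of
#' the second pattern.
#'
#' @param kind One of `"g"`, `"K12"`, `"D12"`.
#' @param r Distances in metres (non-negative).
#' @param lambda2 Intensity of the second pattern (trees per m^2); required
#'   for `"D12"`.
#' @return Numeric vector of expectations along `r`.
#' @export
csr_expectation <- function(kind = c("g", "K12", "D12"), r, lambda2 = NULL) {
  kind <- match.arg(kind)
  if (any(r < 0)) stop("r must be non-negative")
  switch(kind,
         g = rep(1, length(r)),
         K12 = pi * r^2,
         D12 = {
           if (is.null(lambda2) || lambda2 <= 0) {
             stop("lambda2 > 0 required for D12")
           }
           1 - exp(-lambda2 * pi * r^2)
         })
}
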