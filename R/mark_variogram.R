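# Pair structure reused across random-labelling permutations: distances,
# translation weights and, per r-bin, the indices of contributing pairs.
mark_pair_structure <- function(map, r, ring_width, correction) {
  p <- cross_pairs(map$x, map$y, map$x, map$y, map$window, same = TRUE,
                   dmax = max(r) + ring_width / 2, correction = correction)
  bins <- lapply(r, function(rk) which(abs(p$d - rk) <= ring_width / 2))
  list(pairs = p, bins = bins)
}

mark_vario_values <- function(structure, marks, sigma2) {
  p <- structure$pairs
  t_pair <- 0.5 * (marks[p$i] - marks[p$j])^2
  vapply(structure$bins, function(sel) {
    if (length(sel) == 0L) return(NA_real_)
    sum(p$w[sel] * t_pair[sel]) / sum(p$w[sel]) / sigma2
  }, 0)
}

#' Normalised mark variogram of tree diameters
#'
#' For every distance ring, the translation-weighted mean of the test
#' function `(m_i - m_j)^2 / 2` over tree pairs in the ring, normalised by
#' the sample variance of the marks. Independent marks give values near 1
#' at every distance; positive autocorrelation (similar diameters among
#' close neighbours) pushes the variogram below 1 at short range, and
#' size segregation (dissimilar close neighbours) above 1.
#'
#' @param map A `stem_map`.
#' @param species Species label or `"all"`.
#' @param r Distance grid in metres (default `1:25`).
#' @param ring_width Ring width in metres (default 1).
#' @param correction `"translation"` (default) or `"none"`.
#' @return A `mark_variogram` object: list with `r`, `gamma`, `sigma2`
#'   (sample mark variance, n-1 denominator), `pair_count` and `meta`.
#'   Rings with no pairs yield `NA`.
#' @examples
#' pts <- simulate_csr(300, c(0, 0, 100, 100), seed = 3)
#' m <- stem_map(pts[, 1], pts[, 2], rep("A", 300),
#'               rlnorm(300, log(12), 0.4), window = c(0, 0, 100, 100))
#' mv <- mark_variogram(m)
#' mean(mv$gamma[mv$r >= 5])  # near 1: marks independent of locations
#' @export
mark_variogram <- function(map, species = "all", r = seq_len(25),
                           ring_width = 1,
                           correction = c("translation", "none")) {
  correction <- match.arg(correction)
  sub <- subset_species(map, species)
  if (n_trees(sub) < 2L) stop("need at least 2 trees with marks")
  sigma2 <- stats::var(sub$dbh)
  if (sigma2 == 0) stop("zero mark variance: all diameters equal")
  str <- mark_pair_structure(sub, r, ring_width, correction)
  gamma <- mark_vario_values(str, sub$dbh, sigma2)
  if (all(is.na(gamma))) stop("no pairs in any distance ring")
  structure(list(r = r, gamma = gamma, sigma2 = sigma2,
                 pair_count = vapply(str$bins, length, 0L),
                 meta = list(species = species, ring_width = ring_width,
                             correction = correction)),
            class = "mark_variogram")
}

#' @export
print.mark_variogram <- function(x, ...) {
  cat(sprintf("Mark variogram (%s): %d distances, sigma_m^2 = %.3f cm^2\n",
              x$meta$species, length(x$r), x$sigma2))
  invisible(x)
}

#' @export
as.data.frame.mark_variogram <- function(x, ...) {
  data.frame(r = x$r, gamma = x$gamma, pair_count = x$pair_count)
}

#' @export
plot.mark_variogram <- function(x, ...) {
  graphics::plot(x$r, x$gamma, type = "l", xlab = "r (m)",
                 ylab = expression(gamma[m](r)), ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Random-labelling envelope for the mark variogram
#'
#' Tests independence of tree diameters from tree locations: the analysed
#' trees' positions are held fixed and their DBH marks are permuted
#' uniformly at random `nsim` times; the mark variogram is recomputed per
#' permutation and pointwise rank envelopes returned. The pair structure
#' (distances, edge weights, ring membership) is invariant under
#' relabelling, so it is computed once.
#'
#' @inheritParams mark_variogram
#' @param nsim,rank,seed Passed to [envelope()].
#' @return An `envelope_result` for the mark variogram.
#' @export
random_labeling_envelope <- function(map, species = "all", r = seq_len(25),
                                     ring_width = 1,
                                     correction = c("translation", "none"),
                                     nsim = 499, rank = NULL, seed = NULL) {
  correction <- match.arg(correction)
  sub <- subset_species(map, species)
  obs <- mark_variogram(sub, "all", r = r, ring_width = ring_width,
                        correction = correction)
  str <- mark_pair_structure(sub, r, ring_width, correction)
  marks <- sub$dbh
  sigma2 <- stats::var(marks)
  sim_fn <- function() {
    mark_vario_values(str, sample(marks), sigma2)
  }
  observed <- list(r = r, value = obs$gamma)
  envelope(observed, sim_fn, nsim = nsim, rank = rank, seed = seed,
           null_model = sprintf("random labelling (%s)", species))
}
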