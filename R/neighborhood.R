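#' Four nearest neighbours of a reference tree
#'
#' The distance-independent structural indices describe each tree through
#' its four nearest neighbours. Distance ties are broken by the smaller tree
#' index so the neighbour set is deterministic.
#'
#' @param map A `stem_map` with at least 5 trees.
#' @param reference Integer index of the reference tree.
#' @return A list with `reference`, integer `neighbors` (4 indices),
#'   `distances` (nondecreasing, metres) and `azimuths` (radians in
#'   `[0, 2*pi)` measured from the positive x-axis).
#' @export
four_nearest_neighbors <- function(map, reference) {
  n <- n_trees(map)
  if (n < 5L) stop("need at least 5 trees for four nearest neighbours")
  if (reference < 1L || reference > n) stop("reference index out of range")
  dx <- map$x - map$x[reference]
  dy <- map$y - map$y[reference]
  d <- sqrt(dx^2 + dy^2)
  ord <- order(d, seq_len(n))
  ord <- ord[ord != reference][1:4]
  az <- atan2(dy[ord], dx[ord]) %% (2 * pi)
  list(reference = as.integer(reference), neighbors = as.integer(ord),
       distances = d[ord], azimuths = az)
}

#' Uniform angle index of one neighbourhood
#'
#' Sorts the four neighbours by azimuth, forms the four successive circular
#' gaps (summing to 360 degrees), takes each reference angle as the smaller
#' angle between adjacent neighbour rays (`min(gap, 360 - gap)`), and
#' returns the fraction of the four angles smaller than the standard angle.
#' Values near 0 indicate regular spacing around the reference tree, values
#' near 1 strong clumping; about 0.5 is expected under complete spatial
#' randomness.
#'
#' @param record A neighbour record from [four_nearest_neighbors()].
#' @param alpha0 Standard angle in degrees (default 72, the conventional
#'   value 360/(k+1) for k = 4 neighbours).
#' @return U in `{0, 0.25, 0.5, 0.75, 1}`.
#' @export
uniform_angle_index <- function(record, alpha0 = 72) {
  az <- sort(record$azimuths) * 180 / pi
  gaps <- diff(c(az, az[1L] + 360))
  ang <- pmin(gaps, 360 - gaps)
  mean(ang < alpha0)
}

#' Mingling index of one neighbourhood
#'
#' Fraction of the four nearest neighbours belonging to a species other
#' than the reference tree's; 0 = fully conspecific surroundings, 1 = fully
#' heterospecific.
#'
#' @param record A neighbour record from [four_nearest_neighbors()].
#' @param species Character vector of species labels for all trees in the
#'   map the record was built from.
#' @return M in `{0, 0.25, 0.5, 0.75, 1}`.
#' @export
mingling_index <- function(record, species) {
  mean(species[record$neighbors] != species[record$reference])
}

#' Neighbourhood comparison (dominance) index of one neighbourhood
#'
#' Fraction of the four nearest neighbours whose DBH is at least the
#' reference tree's (equality counts as "not smaller"). 0 means the
#' reference dominates all its neighbours; 1 means all neighbours are at
#' least as large.
#'
#' @param record A neighbour record from [four_nearest_neighbors()].
#' @param dbh Numeric vector of DBH values for all trees in the map.
#' @return N in `{0, 0.25, 0.5, 0.75, 1}`.
#' @export
neighborhood_comparison_index <- function(record, dbh) {
  mean(dbh[record$neighbors] >= dbh[record$reference])
}

#' Flag trees within a buffer of the window edge
#'
#' Trees closer than `buffer` to any window edge are flagged; downstream the
#' flagged trees are excluded as reference trees (their neighbour set may be
#' censored by the plot boundary) but remain available as neighbours.
#'
#' @param map A `stem_map`.
#' @param buffer Buffer width in metres, `0 <= buffer <` half the smaller
#'   window dimension.
#' @return Logical vector, `TRUE` for flagged (edge) trees.
#' @export
edge_filter <- function(map, buffer = 5) {
  if (buffer < 0) stop("buffer must be non-negative")
  w <- map$window
  if (buffer >= min(window_sides(w)) / 2) {
    stop("buffer too large: would exclude the whole plot interior")
  }
  (map$x - w[1L]) < buffer | (w[3L] - map$x) < buffer |
    (map$y - w[2L]) < buffer | (w[4L] - map$y) < buffer
}

#' Per-tree structural index table
#'
#' Computes the uniform angle index U, mingling index M and neighbourhood
#' comparison index N for every tree from its four nearest neighbours.
#' Trees within `buffer` of the window edge are flagged `edge_excluded`;
#' they still serve as neighbours of interior trees.
#'
#' @param map A `stem_map` with at least 5 trees.
#' @param alpha0 Standard angle in degrees for U (default 72).
#' @param buffer Edge buffer in metres (default 5); `0` disables edge
#'   exclusion.
#' @return A `data.frame` with columns `tree`, `species`, `dbh`, `U`, `M`,
#'   `N`, `edge_excluded`.
#' @examples
#' m <- generate_stem_map(preset_disturbed(), seed = 1)
#' tab <- structural_indices(m)
#' index_distribution(tab, "M", species = "Bp")
#' @export
structural_indices <- function(map, alpha0 = 72, buffer = 5) {
  n <- n_trees(map)
  if (n < 5L) stop("need at least 5 trees")
  edge <- if (buffer > 0) edge_filter(map, buffer) else rep(FALSE, n)
  U <- M <- N <- numeric(n)
  for (i in seq_len(n)) {
    rec <- four_nearest_neighbors(map, i)
    U[i] <- uniform_angle_index(rec, alpha0)
    M[i] <- mingling_index(rec, map$species)
    N[i] <- neighborhood_comparison_index(rec, map$dbh)
  }
  data.frame(tree = seq_len(n), species = map$species, dbh = map$dbh,
             U = U, M = M, N = N, edge_excluded = edge,
             stringsAsFactors = FALSE)
}

#' Frequency distribution of a structural index
#'
#' Relative frequencies of one index over the five-point scale
#' `{0, 0.25, 0.5, 0.75, 1}` plus the mean, for one species (or all),
#' over trees not excluded by the edge filter.
#'
#' @param table A table from [structural_indices()].
#' @param which One of `"U"`, `"M"`, `"N"`.
#' @param species A species label or `"all"`.
#' @return A list with `frequencies` (named numeric over the five classes,
#'   summing to 1), `mean` and `n`.
#' @export
index_distribution <- function(table, which = c("U", "M", "N"),
                               species = "all") {
  which <- match.arg(which)
  keep <- !table$edge_excluded
  if (!identical(species, "all")) keep <- keep & table$species == species
  v <- table[[which]][keep]
  if (length(v) == 0L) stop("no included trees for this selection")
  classes <- c(0, 0.25, 0.5, 0.75, 1)
  freq <- vapply(classes, function(cl) mean(abs(v - cl) < 1e-9), 0)
  names(freq) <- format(classes)
  list(frequencies = freq, mean = mean(v), n = length(v))
}
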