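#' Gini index of size inequality
#'
#' Mean absolute difference over all ordered pairs, normalised by twice the
#' mean: `G = sum_i sum_j |v_i - v_j| / (2 n^2 vbar)`. In stand-structure
#' work this is usually applied to per-tree basal areas, where it measures
#' the concentration of growing stock among stems (0 = perfect equality).
#'
#' @param values Numeric vector of non-negative sizes, `n >= 2`, not all
#'   zero.
#' @return The Gini index in `[0, 1)`.
#' @examples
#' gini_index(c(1, 2, 3, 4))   # 0.25
#' gini_index(c(0, 7))         # 0.5, two-point maximal inequality
#' @export
gini_index <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("gini_index needs at least two values")
  if (any(values < 0)) stop("values must be non-negative")
  vbar <- mean(values)
  if (vbar == 0) stop("values must not be all zero")
  sum(abs(outer(values, values, "-"))) / (2 * n^2 * vbar)
}

basal_area_m2 <- function(dbh_cm) pi * (dbh_cm / 200)^2

#' Per-species stand structure summary
#'
#' For each species: tree count, density (trees/ha), mean, maximum and
#' sample (n-1) standard deviation of DBH (cm), basal area (m^2/ha; the
#' cross-sectional area of a stem of diameter d cm is `pi * (d/200)^2` m^2),
#' the proportion of all stems, and the Gini index of size inequality.
#'
#' @param map A `stem_map`.
#' @param gini_on Compute the Gini index on per-tree `"basal_area"`
#'   (default, the usual forest-structure convention) or on `"dbh"`.
#' @return A `data.frame`, one row per species, ordered by descending basal
#'   area.
#' @export
species_summary <- function(map, gini_on = c("basal_area", "dbh")) {
  gini_on <- match.arg(gini_on)
  if (n_trees(map) == 0L) stop("empty stem map")
  area_ha <- window_area(map) / 1e4
  n_total <- n_trees(map)
  sp <- sort(unique(map$species))
  rows <- lapply(sp, function(s) {
    d <- map$dbh[map$species == s]
    g <- if (length(d) >= 2L) {
      gini_index(if (gini_on == "basal_area") basal_area_m2(d) else d)
    } else NA_real_
    data.frame(
      species = s,
      n = length(d),
      mean_dbh = mean(d),
      max_dbh = max(d),
      sd_dbh = if (length(d) >= 2L) stats::sd(d) else NA_real_,
      basal_area = sum(basal_area_m2(d)) / area_ha,
      density = length(d) / area_ha,
      proportion = length(d) / n_total,
      gini = g,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(-out$basal_area), , drop = FALSE]
}

#' Importance value of a species
#'
#' One-third of the sum of relative density (share of stems), relative
#' frequency (the species' subplot occurrence frequency divided by the sum
#' of occurrence frequencies over all species) and relative dominance
#' (share of basal area). Importance values over all species sum to 1.
#'
#' @param map A `stem_map`.
#' @param species A species label present in the map.
#' @param cell_size Subplot cell size in metres used for the frequency
#'   component (default 20).
#' @return The importance value in `[0, 1]`.
#' @export
importance_value <- function(map, species, cell_size = 20) {
  iv <- importance_values(map, cell_size = cell_size)
  if (!species %in% iv$species) stop(sprintf("species '%s' absent", species))
  iv$iv[iv$species == species]
}

#' Importance values of all species
#'
#' @inheritParams importance_value
#' @return A `data.frame` with columns `species`, `rel_density`,
#'   `rel_frequency`, `rel_dominance`, `iv`, sorted by descending `iv`.
#' @export
importance_values <- function(map, cell_size = 20) {
  sp <- sort(unique(map$species))
  cells <- subplot_assignment(map, cell_size)
  ba <- basal_area_m2(map$dbh)
  occ <- vapply(sp, function(s)
    length(unique(cells$cell[map$species == s])) / cells$n_cells, 0)
  rel_den <- vapply(sp, function(s) sum(map$species == s), 0) / n_trees(map)
  rel_frq <- occ / sum(occ)
  rel_dom <- vapply(sp, function(s) sum(ba[map$species == s]), 0) / sum(ba)
  out <- data.frame(species = sp, rel_density = rel_den,
                    rel_frequency = rel_frq, rel_dominance = rel_dom,
                    iv = (rel_den + rel_frq + rel_dom) / 3,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$iv, -out$rel_dominance, out$species), , drop = FALSE]
}

#' DBH class histogram for one species
#'
#' Counts stems in half-open diameter classes
#' `[origin + k w, origin + (k+1) w)` starting at the census threshold.
#'
#' @param map A `stem_map`.
#' @param species Species label.
#' @param bin_width Class width in cm (default 2).
#' @param origin Lower bound of the first class in cm (default 5).
#' @return A `data.frame` with columns `lower`, `upper`, `count`; counts sum
#'   to the species' tree count.
#' @export
dbh_histogram <- function(map, species, bin_width = 2, origin = 5) {
  if (bin_width <= 0) stop("bin_width must be positive")
  d <- map$dbh[map$species == species]
  if (length(d) == 0L) stop(sprintf("species '%s' absent", species))
  if (any(d < origin)) stop("dbh values below the histogram origin")
  k <- floor((d - origin) / bin_width)
  kmax <- max(k)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  data.frame(lower = origin + (0:kmax) * bin_width,
             upper = origin + (1:(kmax + 1L)) * bin_width,
             count = counts)
}
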