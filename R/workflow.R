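# Orchestration of the full plot analysis: stand summary, structural
# indices, univariate pattern analysis with CSR envelopes, all pairwise
# bivariate association schemes, and mark variograms with random-labelling
# envelopes, each stage written to CSV with a JSON metadata sidecar.

#' Rank species by importance value and select the dominant ones
#'
#' @param map A `stem_map`.
#' @param k Number of species to return (default 4).
#' @param cell_size Subplot size for the frequency component (default 20).
#' @return Character vector of the top `k` species labels, by descending
#'   importance value (ties broken by descending basal area, then label).
#' @export
select_dominant_species <- function(map, k = 4, cell_size = 20) {
  iv <- importance_values(map, cell_size = cell_size)
  if (nrow(iv) < k) {
    stop(sprintf("only %d species present, cannot select %d", nrow(iv), k))
  }
  iv$species[seq_len(k)]
}

write_csv_with_meta <- function(df, path, meta) {
  utils::write.csv(df, path, row.names = FALSE)
  meta$package <- "stemspat"
  meta$version <- as.character(utils::packageVersion("stemspat"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a second-order estimate, envelope, scheme trajectory or mark
#' variogram to CSV + JSON metadata
#'
#' @param x A `second_order`, `envelope_result`, `scheme_trajectory` or
#'   `mark_variogram` object.
#' @param path Output CSV path; a `<path>.json` sidecar carries the
#'   metadata (species, correction, nsim, rank, coverage, seed as
#'   applicable).
#' @return `path`, invisibly.
#' @export
export_result <- function(x, path) {
  meta <- if (inherits(x, "second_order")) c(list(kind = x$kind), x$meta)
    else if (inherits(x, "envelope_result"))
      list(null_model = x$null_model, nsim = x$nsim, rank = x$rank,
           coverage = x$coverage, seed = x$seed)
    else if (inherits(x, "scheme_trajectory"))
      list(sp1 = x$meta$sp1, sp2 = x$meta$sp2, null = x$meta$null,
           nsim = x$meta$nsim, threshold = x$threshold, seed = x$meta$seed)
    else if (inherits(x, "mark_variogram"))
      c(x$meta, list(sigma2 = x$sigma2))
    else stop("unsupported object")
  meta$thomas_fit <- NULL
  write_csv_with_meta(as.data.frame(x), path, meta)
}

#' Run the complete stem-map analysis pipeline
#'
#' Sequences every stage of the plot analysis for the `k` dominant species
#' (by importance value): the per-species stand-structure summary and DBH
#' histograms, the structural-index table and its per-species
#' distributions, the univariate pair correlation with conditioned-CSR
#' envelopes, all ordered species-pair association schemes under the
#' antecedent null, and per-species mark variograms with random-labelling
#' envelopes. Every output file carries the seed, nsim, rank and package
#' version in its JSON sidecar, and a rerun with the same seed reproduces
#' all numbers.
#'
#' @param map A `stem_map` (e.g. from [read_stem_map()] or
#'   [generate_stem_map()]).
#' @param out_dir Output directory (created if needed).
#' @param k Number of dominant species analysed (default 4, capped at the
#'   number present).
#' @param r_uni,r_biv Univariate and bivariate distance grids (defaults
#'   `1:25` and `1:30`).
#' @param ring_width Ring width for g and the mark variogram (default 1).
#' @param nsim,rank Envelope settings (defaults 499 and the ~95% rank).
#' @param scheme_null `"thomas"` or `"csr"` null for the association
#'   scheme and bivariate envelopes.
#' @param seed Integer seed controlling all randomisation.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_full_analysis <- function(map, out_dir, k = 4, r_uni = seq_len(25),
                              r_biv = seq_len(30), ring_width = 1,
                              nsim = 499, rank = NULL,
                              scheme_null = c("thomas", "csr"),
                              seed = 1L) {
  scheme_null <- match.arg(scheme_null)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  k <- min(k, length(unique(map$species)))
  paths <- list()
  meta0 <- list(seed = seed, nsim = nsim, rank = rank)

  message("stage 1/5: stand structure (", n_trees(map), " trees)")
  dom <- select_dominant_species(map, k)
  summ <- species_summary(map)
  paths$summary <- write_csv_with_meta(
    summ, file.path(out_dir, "species_summary.csv"),
    c(meta0, list(stage = "stand_structure", dominant = dom)))
  hists <- do.call(rbind, lapply(dom, function(s)
    cbind(species = s, dbh_histogram(map, s))))
  paths$histograms <- write_csv_with_meta(
    hists, file.path(out_dir, "dbh_histograms.csv"),
    c(meta0, list(stage = "stand_structure")))

  message("stage 2/5: structural indices")
  tab <- structural_indices(map)
  paths$indices <- write_csv_with_meta(
    tab, file.path(out_dir, "structural_indices.csv"),
    c(meta0, list(stage = "neighborhood")))
  dist_rows <- do.call(rbind, lapply(dom, function(s) {
    do.call(rbind, lapply(c("U", "M", "N"), function(w) {
      d <- index_distribution(tab, w, s)
      data.frame(species = s, index = w,
                 class = c(0, 0.25, 0.5, 0.75, 1),
                 frequency = as.numeric(d$frequencies),
                 mean = d$mean, n = d$n)
    }))
  }))
  paths$index_distributions <- write_csv_with_meta(
    dist_rows, file.path(out_dir, "index_distributions.csv"),
    c(meta0, list(stage = "neighborhood")))

  message("stage 3/5: univariate pair correlation with CSR envelopes")
  for (i in seq_along(dom)) {
    s <- dom[i]
    env <- csr_envelope(map, s, r = r_uni, ring_width = ring_width,
                        nsim = nsim, rank = rank, seed = seed + i)
    paths[[paste0("g_", s)]] <- export_result(
      env, file.path(out_dir, sprintf("g_csr_%s.csv", s)))
  }

  message("stage 4/5: bivariate association schemes (", scheme_null,
          " null)")
  pairs <- utils::combn(dom, 2L)
  for (j in seq_len(ncol(pairs))) {
    sp1 <- pairs[1L, j]; sp2 <- pairs[2L, j]
    tr <- run_scheme(map, sp1, sp2, r = r_biv, null = scheme_null,
                     nsim = nsim, seed = seed + 100L + j)
    paths[[paste0("scheme_", sp1, "_", sp2)]] <- export_result(
      tr, file.path(out_dir, sprintf("scheme_%s_%s.csv", sp1, sp2)))
  }

  message("stage 5/5: mark variograms with random-labelling envelopes")
  for (i in seq_along(dom)) {
    s <- dom[i]
    if (sum(map$species == s) < 2L) next
    env <- random_labeling_envelope(map, s, r = r_uni,
                                    ring_width = ring_width,
                                    nsim = nsim, rank = rank,
                                    seed = seed + 200L + i)
    paths[[paste0("markvario_", s)]] <- export_result(
      env, file.path(out_dir, sprintf("markvario_%s.csv", s)))
  }
  invisible(paths)
}
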