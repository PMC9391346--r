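# Two-axis classification of bivariate species association in the style of
# Wiegand: the bivariate Ripley K (a neighbourhood-density view) and the
# nearest-neighbour distribution D12 (a per-individual view) are each
# standardised against a simulated independence null, giving the axes M(r)
# and P(r); the sign pattern outside a central acceptance box sorts each
# distance into one of five association types.

#' Standardised scheme axes P(r) and M(r)
#'
#' `P(r) = (D12(r) - E[D12(r)]) / SD[D12(r)]` and
#' `M(r) = (K12(r) - E[K12(r)]) / SD[K12(r)]`, with the expectation and
#' standard deviation estimated from null-model simulations. Where a null
#' SD is zero the axis is undefined (`NA`).
#'
#' @param observed_k12,observed_d12 `second_order` objects on a common r
#'   grid.
#' @param null A null-distribution summary: list with `r`, `mean_k`,
#'   `sd_k`, `mean_d`, `sd_d`, `nsim` (as built by [run_scheme()]'s
#'   simulation stage, or by hand).
#' @return A `data.frame` with columns `r`, `P`, `M`.
#' @export
scheme_axes <- function(observed_k12, observed_d12, null) {
  if (!isTRUE(all.equal(observed_k12$r, null$r)) ||
      !isTRUE(all.equal(observed_d12$r, null$r))) {
    stop("observed and null r grids differ")
  }
  z <- function(obs, m, s) ifelse(is.na(s) | s == 0, NA_real_,
                                  (obs - m) / s)
  data.frame(r = null$r,
             P = z(observed_d12$value, null$mean_d, null$sd_d),
             M = z(observed_k12$value, null$mean_k, null$sd_k))
}

#' Classify bivariate association from the scheme axes
#'
#' Type 0 ("no departure") when both axes lie inside the acceptance box
#' `[-threshold, threshold]`; otherwise the quadrant of `(M, P)` decides:
#' Type I segregation (M < 0, P < 0), Type II partial overlap
#' (M > 0, P < 0), Type III mixing (M > 0, P > 0), Type IV (M < 0, P > 0;
#' rare, one aggregated species barely overlapped by the other). A
#' coordinate exactly 0 outside the box counts as positive.
#'
#' @param P,M Numeric vectors of axis values (same length).
#' @param threshold Box half-width (default 2.33, the conventional printed
#'   value for this scheme).
#' @return Factor with levels `"0"`, `"I"`, `"II"`, `"III"`, `"IV"`; `NA`
#'   where an axis is undefined.
#' @export
classify_association <- function(P, M, threshold = 2.33) {
  stopifnot(length(P) == length(M))
  out <- rep(NA_character_, length(P))
  def <- !(is.na(P) | is.na(M))
  inbox <- def & abs(P) <= threshold & abs(M) <= threshold
  out[inbox] <- "0"
  quad <- def & !inbox
  mp <- M >= 0; pp <- P >= 0
  out[quad & !mp & !pp] <- "I"
  out[quad & mp & !pp] <- "II"
  out[quad & mp & pp] <- "III"
  out[quad & !mp & pp] <- "IV"
  factor(out, levels = c("0", "I", "II", "III", "IV"))
}

#' Run the full association scheme for one species pair
#'
#' Computes the observed bivariate K12 and D12, simulates the independence
#' null (`sp1` fixed at its observed locations, `sp2` redrawn — from a
#' fitted Thomas cluster process by default, retaining the species' own
#' aggregation, or from conditioned CSR), estimates `E[.]` and `SD[.]` per
#' distance from the simulations, standardises the axes and classifies
#' every distance.
#'
#' @param map A `stem_map`.
#' @param sp1,sp2 Species labels (both with at least 2 trees).
#' @param r Distance grid (default `1:30`).
#' @param null `"thomas"` (default) or `"csr"` for the redraw of `sp2`.
#' @param nsim Number of null simulations (default 499).
#' @param threshold Acceptance box half-width (default 2.33).
#' @param fit_r_range Distance range for the Thomas fit when
#'   `null = "thomas"`.
#' @param seed Optional integer seed.
#' @return A `scheme_trajectory`: list with `r`, `P`, `M`, `type`,
#'   `threshold`, `null_summary` and `meta`.
#' @export
run_scheme <- function(map, sp1, sp2, r = seq_len(30),
                       null = c("thomas", "csr"), nsim = 499,
                       threshold = 2.33, fit_r_range = c(1, 25),
                       seed = NULL) {
  null <- match.arg(null)
  if (sum(map$species == sp1) < 2L || sum(map$species == sp2) < 2L) {
    stop("both species need at least 2 trees")
  }
  if (!is.null(seed)) set.seed(seed)
  obs_k <- ripley_k12(map, sp1, sp2, r = r)
  obs_d <- nn_distribution_d12(map, sp1, sp2, r = r)
  fixed <- subset_species(map, sp1)
  rnd <- subset_species(map, sp2)
  n2 <- n_trees(rnd)
  win <- map$window
  fit <- NULL
  if (null == "thomas") {
    k_uni <- ripley_k12(rnd, sp2, sp2,
                        r = seq(fit_r_range[1L], fit_r_range[2L], by = 1))
    fit <- fit_thomas(k_uni, intensity(rnd), r_range = fit_r_range)
  }
  sims_k <- matrix(NA_real_, nsim, length(r))
  sims_d <- matrix(NA_real_, nsim, length(r))
  for (s in seq_len(nsim)) {
    p <- if (null == "thomas") simulate_thomas_n(n2, fit, win) else
      simulate_csr(n2, win)
    m <- stem_map(c(fixed$x, p[, 1L]), c(fixed$y, p[, 2L]),
                  c(fixed$species, rep(sp2, n2)),
                  c(fixed$dbh, rnd$dbh), window = win)
    # the scale warning, if due, was already issued for the observed curve
    sims_k[s, ] <- suppressWarnings(ripley_k12(m, sp1, sp2, r = r)$value)
    sims_d[s, ] <- nn_distribution_d12(m, sp1, sp2, r = r)$value
  }
  null_summary <- list(r = r,
                       mean_k = colMeans(sims_k),
                       sd_k = apply(sims_k, 2L, stats::sd),
                       mean_d = colMeans(sims_d, na.rm = TRUE),
                       sd_d = apply(sims_d, 2L, stats::sd),
                       nsim = nsim)
  ax <- scheme_axes(obs_k, obs_d, null_summary)
  structure(list(r = r, P = ax$P, M = ax$M,
                 type = classify_association(ax$P, ax$M, threshold),
                 threshold = threshold, null_summary = null_summary,
                 meta = list(sp1 = sp1, sp2 = sp2, null = null,
                             nsim = nsim, seed = seed,
                             thomas_fit = fit)),
            class = "scheme_trajectory")
}

#' @export
print.scheme_trajectory <- function(x, ...) {
  cat(sprintf("Association scheme %s vs %s (%s null, nsim = %d):\n",
              x$meta$sp1, x$meta$sp2, x$meta$null, x$meta$nsim))
  print(table(type = x$type, useNA = "ifany"))
  invisible(x)
}

#' @export
as.data.frame.scheme_trajectory <- function(x, ...) {
  data.frame(r = x$r, P = x$P, M = x$M, type = as.character(x$type))
}

#' @export
plot.scheme_trajectory <- function(x, ...) {
  lim <- max(abs(c(x$P, x$M, x$threshold)), na.rm = TRUE) * 1.1
  graphics::plot(x$M, x$P, xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = "M(r)", ylab = "P(r)", ...)
  graphics::rect(-x$threshold, -x$threshold, x$threshold, x$threshold,
                 border = "grey40", lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey70")
  invisible(x)
}
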