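#' Construct a stem map
#'
#' A stem map is a marked point pattern: tree stem coordinates inside a
#' rectangular plot window, with a species label and a diameter at breast
#' height (DBH, cm) attached to every tree, and optionally a total height
#' (m). All coordinates are continuous metres with the origin at the plot's
#' lower-left corner.
#'
#' @param x,y Numeric vectors of stem coordinates in metres.
#' @param species Character vector (or factor) of species labels, one per
#'   tree. Labels are free-form strings.
#' @param dbh Numeric vector of diameters at breast height in centimetres;
#'   must be strictly positive.
#' @param height Optional numeric vector of tree heights in metres.
#' @param window Numeric vector `c(xmin, ymin, xmax, ymax)` in metres. The
#'   window must have strictly positive width and height, and every tree
#'   must lie inside it (boundary included).
#'
#' @return An object of class `"stem_map"`: a list with elements `x`, `y`,
#'   `species`, `dbh`, `height` (or `NULL`) and `window`.
#' @examples
#' m <- stem_map(x = c(10, 20, 30), y = c(10, 20, 30),
#'               species = c("Bp", "Pk", "Bp"), dbh = c(12, 30, 8),
#'               window = c(0, 0, 100, 100))
#' n_trees(m)
#' @export
stem_map <- function(x, y, species, dbh, height = NULL,
                     window = c(0, 0, 100, 100)) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  species <- as.character(species)
  dbh <- as.numeric(dbh)
  window <- as.numeric(window)
  if (length(window) != 4L) {
    stop("'window' must be c(xmin, ymin, xmax, ymax)")
  }
  if (!(window[3L] > window[1L] && window[4L] > window[2L])) {
    stop("window must have strictly positive width and height")
  }
  n <- length(x)
  if (length(y) != n || length(species) != n || length(dbh) != n) {
    stop("x, y, species and dbh must have equal length")
  }
  if (!is.null(height)) {
    height <- as.numeric(height)
    if (length(height) != n) stop("height must have the same length as x")
  }
  if (anyNA(x) || anyNA(y) || anyNA(dbh)) {
    stop("coordinates and dbh must not contain missing values")
  }
  if (any(dbh <= 0)) {
    stop("dbh must be strictly positive for every tree")
  }
  out_w <- which(x < window[1L] | x > window[3L] |
                 y < window[2L] | y > window[4L])
  if (length(out_w) > 0L) {
    stop(sprintf("tree(s) outside the declared window (first offending row: %d, x = %g, y = %g)",
                 out_w[1L], x[out_w[1L]], y[out_w[1L]]))
  }
  structure(
    list(x = x, y = y, species = species, dbh = dbh, height = height,
         window = window),
    class = "stem_map"
  )
}

#' @export
print.stem_map <- function(x, ...) {
  w <- x$window
  cat(sprintf("Stem map: %d trees, %d species, window [%g, %g] x [%g, %g] m\n",
              n_trees(x), length(unique(x$species)),
              w[1L], w[3L], w[2L], w[4L]))
  tab <- sort(table(x$species), decreasing = TRUE)
  cat("Species counts:\n")
  print(tab)
  invisible(x)
}

#' Number of trees in a stem map
#' @param map A `stem_map`.
#' @return Integer count.
#' @export
n_trees <- function(map) length(map$x)

#' Window area of a stem map
#' @param map A `stem_map` (or a 4-vector window).
#' @return Area in square metres.
#' @export
window_area <- function(map) {
  w <- if (inherits(map, "stem_map")) map$window else as.numeric(map)
  (w[3L] - w[1L]) * (w[4L] - w[2L])
}

window_sides <- function(window) {
  c(window[3L] - window[1L], window[4L] - window[2L])
}

#' Subset a stem map by species
#'
#' @param map A `stem_map`.
#' @param species A species label, a character vector of labels, or `"all"`.
#' @return A `stem_map` containing only the selected trees.
#' @export
subset_species <- function(map, species = "all") {
  if (identical(species, "all")) return(map)
  keep <- map$species %in% species
  if (!any(keep)) stop(sprintf("no trees of species '%s' in map",
                               paste(species, collapse = ", ")))
  stem_map(map$x[keep], map$y[keep], map$species[keep], map$dbh[keep],
           height = if (is.null(map$height)) NULL else map$height[keep],
           window = map$window)
}

#' Read a stem map from a delimited text file
#'
#' Expects a CSV with header columns `x`, `y`, `species`, `dbh` and
#' optionally `height`. Trees below the census diameter threshold are
#' dropped at read time and the drop count reported with a message (and
#' stored in the `n_dropped` attribute), mirroring the usual field protocol
#' of mapping only stems above a minimum DBH.
#'
#' @param path Path to the CSV file.
#' @param min_dbh Minimum DBH in cm retained (default 5, the usual census
#'   threshold); rows with `dbh < min_dbh` are excluded.
#' @param window Either a numeric `c(xmin, ymin, xmax, ymax)` or `"infer"`
#'   to use the data extent.
#' @return A validated `stem_map` with attribute `n_dropped`.
#' @export
read_stem_map <- function(path, min_dbh = 5, window = "infer") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("x", "y", "species", "dbh")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  }
  for (col in c("x", "y", "dbh")) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      stop(sprintf("non-numeric or missing values in column '%s' (first at row %d)",
                   col, which(is.na(v))[1L]))
    }
    df[[col]] <- v
  }
  drop <- df$dbh < min_dbh
  n_dropped <- sum(drop)
  if (n_dropped > 0L) {
    message(sprintf("read_stem_map: dropped %d tree(s) with dbh < %g cm",
                    n_dropped, min_dbh))
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no trees remain after the min_dbh filter")
  if (identical(window, "infer")) {
    window <- c(min(df$x), min(df$y), max(df$x), max(df$y))
  }
  m <- stem_map(df$x, df$y, df$species, df$dbh,
                height = if ("height" %in% names(df)) df$height else NULL,
                window = window)
  attr(m, "n_dropped") <- n_dropped
  m
}

#' Write a stem map to CSV with a JSON metadata sidecar
#'
#' Writes one tree per row (`x,y,species,dbh[,height]`) and a `<path>.json`
#' sidecar holding the window and provenance metadata, so that a re-read
#' with [read_stem_map()] reproduces the object exactly.
#'
#' @param map A `stem_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stem_map <- function(map, path) {
  df <- as.data.frame(map)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(window = map$window, n_trees = n_trees(map),
               package = "stemspat",
               version = as.character(utils::packageVersion("stemspat")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
as.data.frame.stem_map <- function(x, ...) {
  df <- data.frame(x = x$x, y = x$y, species = x$species, dbh = x$dbh,
                   stringsAsFactors = FALSE)
  if (!is.null(x$height)) df$height <- x$height
  df
}

#' Intensity (trees per square metre) of a stem map
#'
#' @param map A `stem_map`.
#' @param species A species label or `"all"`.
#' @return Trees per square metre.
#' @examples
#' m <- simulate_csr(500, c(0, 0, 100, 100), seed = 1)
#' intensity(stem_map(m[, 1], m[, 2], rep("A", 500), rep(10, 500),
#'                    window = c(0, 0, 100, 100)))
#' @export
intensity <- function(map, species = "all") {
  n <- if (identical(species, "all")) n_trees(map) else
    sum(map$species == species)
  if (n == 0L) stop(sprintf("no trees of species '%s'", species))
  n / window_area(map)
}

#' Assign trees to a regular grid of square subplots
#'
#' Cells are half-open `[a, a + cell)` in both axes, except the last cell
#' along each axis, which is closed so that trees on the upper window
#' boundary still map to exactly one cell. Cell indices are 0-based from the
#' lower-left corner. If `cell_size` does not divide a window dimension the
#' ragged edge cells are allowed with a warning.
#'
#' @param map A `stem_map`.
#' @param cell_size Side length of the square cells in metres.
#' @return A list with 0-based `ix`, `iy` per tree, a 1-based linear `cell`
#'   id, and `nx`, `ny`, `n_cells`.
#' @export
subplot_assignment <- function(map, cell_size) {
  if (cell_size <= 0) stop("cell_size must be positive")
  w <- map$window
  sides <- window_sides(w)
  nx <- ceiling(sides[1L] / cell_size - 1e-9)
  ny <- ceiling(sides[2L] / cell_size - 1e-9)
  if (abs(nx * cell_size - sides[1L]) > 1e-9 ||
      abs(ny * cell_size - sides[2L]) > 1e-9) {
    warning("cell_size does not divide the window; edge cells are ragged")
  }
  ix <- pmin(floor((map$x - w[1L]) / cell_size), nx - 1L)
  iy <- pmin(floor((map$y - w[2L]) / cell_size), ny - 1L)
  list(ix = as.integer(ix), iy = as.integer(iy),
       cell = as.integer(ix + nx * iy + 1L),
       nx = as.integer(nx), ny = as.integer(ny),
       n_cells = as.integer(nx * ny))
}
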