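#' Generate a synthetic landuse raster and neighborhood table
#'
#' Builds a patchy (spatially autocorrelated) landuse raster over a regular
#' grid, together with a set of rectangular statistical neighborhoods tiling
#' the same extent and carrying four demographic attributes. Patches are
#' produced by a seeded Voronoi growth: class-labelled seed points are placed
#' in the grid and every cell adopts the class of its nearest seed, yielding
#' contiguous regions rather than i.i.d. noise, so downstream distance and
#' coverage features vary smoothly in space.
#'
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param width_cells,height_cells raster size in cells (>= 10).
#' @param class_mix named numeric vector over (a subset of) the nine landuse
#'   classes, summing to 1; expected area share per class. Classes with a
#'   positive share are guaranteed at least one seed, hence at least one cell.
#' @param cell_size cell edge length in meters (default 100).
#' @param n_neighborhoods approximate number of neighborhoods (default 25).
#' @return A list with elements \code{landuse} (a \code{landuse_raster}) and
#'   \code{neighborhoods} (a \code{neighborhood_table}).
#' @examples
#' w <- make_landscape(1, 30, 30)
#' table(w$landuse$classes)
#' @export
make_landscape <- function(seed, width_cells = 60, height_cells = 60,
                           class_mix = NULL, cell_size = 100,
                           n_neighborhoods = 25) {
  cls <- landuse_classes()
  if (is.null(class_mix)) {
    class_mix <- c(parks = 0.05, sports = 0.03, recreation = 0.03,
                   forest = 0.10, water = 0.07, agriculture = 0.30,
                   traffic = 0.07, residential = 0.30, cbd = 0.05)
  }
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% cls))
    stop("class_mix names must be landuse classes: ",
         paste(setdiff(names(class_mix), cls), collapse = ", "))
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (width_cells < 10 || height_cells < 10)
    stop("raster must be at least 10x10 cells")
  stopifnot_scalar_pos(cell_size, "cell_size")
  class_mix <- class_mix[class_mix > 0]

  with_seed(seed, {
    nc <- as.integer(width_cells); nr <- as.integer(height_cells)
    # seeds: at least one per positive-mix class, rest multinomial by mix
    n_seed <- max(length(class_mix), round(nc * nr / 40))
    lab <- names(class_mix)
    seed_cls <- c(lab, sample(lab, n_seed - length(lab), replace = TRUE,
                              prob = class_mix))
    sx <- runif(n_seed, 0, nc); sy <- runif(n_seed, 0, nr)
    # nearest-seed assignment (Voronoi patches)
    ctr_x <- rep(seq_len(nc) - 0.5, each = nr)
    ctr_y <- rep(seq_len(nr) - 0.5, times = nc)
    nearest <- nearest_seed_cpp(ctr_x, ctr_y, sx, sy)
    classes <- matrix(seed_cls[nearest], nrow = nr, ncol = nc)
    landuse <- landuse_raster(classes, origin = c(0, 0), cell_size = cell_size)

    nb <- make_neighborhoods(nc, nr, cell_size, n_neighborhoods, landuse)
    list(landuse = landuse, neighborhoods = nb)
  })
}

#' Construct a landuse raster
#'
#' @param classes character matrix of class labels (rows = grid rows from the
#'   south, columns = grid columns from the west).
#' @param origin (x, y) of the lower-left corner in meters.
#' @param cell_size cell edge length in meters.
#' @return An object of class \code{landuse_raster}: a list with fields
#'   \code{classes}, \code{origin}, \code{cell_size}, \code{width},
#'   \code{height}.
#' @export
landuse_raster <- function(classes, origin = c(0, 0), cell_size = 100) {
  stopifnot(is.matrix(classes))
  bad <- setdiff(unique(as.vector(classes)), landuse_classes())
  if (length(bad)) stop("unknown landuse classes: ", paste(bad, collapse = ", "))
  stopifnot_scalar_pos(cell_size, "cell_size")
  structure(list(classes = classes, origin = as.numeric(origin),
                 cell_size = cell_size,
                 width = ncol(classes), height = nrow(classes)),
            class = "landuse_raster")
}

#' @export
print.landuse_raster <- function(x, ...) {
  cat("<landuse_raster> ", x$height, "x", x$width, " cells, ",
      x$cell_size, " m each, origin (", x$origin[1], ", ", x$origin[2],
      ")\n", sep = "")
  print(round(100 * table(x$classes) / length(x$classes), 1))
  invisible(x)
}

# rectangular neighborhoods tiling the raster extent, with demographics
# loosely tied to residential coverage so demographic bins are non-degenerate
make_neighborhoods <- function(nc, nr, cell_size, n_nb, landuse) {
  kx <- max(1L, round(sqrt(n_nb * nc / nr)))
  ky <- max(1L, round(n_nb / kx))
  xb <- round(seq(0, nc, length.out = kx + 1) +
                c(0, runif(max(kx - 1, 0), -nc / (4 * kx), nc / (4 * kx)), 0))
  yb <- round(seq(0, nr, length.out = ky + 1) +
                c(0, runif(max(ky - 1, 0), -nr / (4 * ky), nr / (4 * ky)), 0))
  xb <- unique(pmin(pmax(xb, 0), nc)); yb <- unique(pmin(pmax(yb, 0), nr))
  xb <- sort(xb); yb <- sort(yb)
  polys <- list(); res_frac <- numeric(0)
  res <- landuse$classes == "residential"
  for (j in seq_len(length(yb) - 1)) {
    for (i in seq_len(length(xb) - 1)) {
      x0 <- xb[i] * cell_size; x1 <- xb[i + 1] * cell_size
      y0 <- yb[j] * cell_size; y1 <- yb[j + 1] * cell_size
      polys[[length(polys) + 1L]] <-
        cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
      rows <- (yb[j] + 1):max(yb[j] + 1, yb[j + 1])
      cols <- (xb[i] + 1):max(xb[i] + 1, xb[i + 1])
      res_frac <- c(res_frac, mean(res[rows, cols, drop = FALSE]))
    }
  }
  n <- length(polys)
  dens <- round(50 + 8000 * res_frac * exp(rnorm(n, 0, 0.4)))
  dens[res_frac < 0.02 & runif(n) < 0.5] <- 0  # uninhabited polygons exist
  nb <- data.frame(
    neighborhood_id = paste0("NB", sprintf("%03d", seq_len(n))),
    population_density = dens,
    pct_over_65 = round(runif(n, 5, 35), 1),
    pct_one_person = round(runif(n, 10, 60), 1),
    pct_no_child = round(runif(n, 30, 80), 1),
    stringsAsFactors = FALSE)
  neighborhood_table(nb, polys)
}

#' Construct a neighborhood table
#'
#' @param attributes data.frame with columns \code{neighborhood_id},
#'   \code{population_density}, \code{pct_over_65}, \code{pct_one_person},
#'   \code{pct_no_child}.
#' @param polygons list of closed polygon rings (2-column matrices, meters),
#'   one per row of \code{attributes}, in table order (the order used to break
#'   boundary ties in point-in-polygon queries).
#' @return An object of class \code{neighborhood_table}.
#' @export
neighborhood_table <- function(attributes, polygons) {
  need <- c("neighborhood_id", "population_density", "pct_over_65",
            "pct_one_person", "pct_no_child")
  if (!all(need %in% names(attributes)))
    stop("attributes must have columns: ", paste(need, collapse = ", "))
  if (length(polygons) != nrow(attributes))
    stop("one polygon per attribute row required")
  pct <- as.matrix(attributes[, c("pct_over_65", "pct_one_person", "pct_no_child")])
  if (any(pct < 0 | pct > 100)) stop("percentages must lie in [0, 100]")
  if (any(attributes$population_density < 0)) stop("density must be >= 0")
  structure(list(attributes = attributes, polygons = polygons),
            class = "neighborhood_table")
}

#' @export
print.neighborhood_table <- function(x, ...) {
  cat("<neighborhood_table> ", nrow(x$attributes), " neighborhoods\n", sep = "")
  print(head(x$attributes, 4))
  invisible(x)
}

# integer codes 1..9 for serialization
landuse_codes <- function(classes) match(classes, landuse_classes())
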