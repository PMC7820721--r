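#' Build a regular analysis grid over an extent
#'
#' @param extent numeric vector \code{c(xmin, ymin, xmax, ymax)} in meters.
#' @param cell_size cell edge length in meters (default 100).
#' @return An object of class \code{grid_spec} with fields \code{origin},
#'   \code{cell_size}, \code{width}, \code{height}. Width and height are
#'   \code{ceiling(extent / cell_size)}, so the grid covers the extent.
#' @examples
#' build_grid(c(0, 0, 1000, 1000))      # 10 x 10
#' build_grid(c(0, 0, 250, 100))        # 3 x 1
#' @export
build_grid <- function(extent, cell_size = 100) {
  stopifnot_scalar_pos(cell_size, "cell_size")
  if (length(extent) != 4 || extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("extent must be c(xmin, ymin, xmax, ymax) with positive area")
  structure(list(origin = c(extent[1], extent[2]), cell_size = cell_size,
                 width = as.integer(ceiling((extent[3] - extent[1]) / cell_size)),
                 height = as.integer(ceiling((extent[4] - extent[2]) / cell_size))),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", x$height, "x", x$width, " cells of ", x$cell_size,
      " m, origin (", x$origin[1], ", ", x$origin[2], ")\n", sep = "")
  invisible(x)
}

#' Distance raster to the nearest cell of a landuse class
#'
#' For every grid cell, the center-to-center Euclidean distance (meters) to
#' the nearest cell carrying \code{class}; exactly 0 on cells of the class
#' itself (the class is usable as a support surface there).
#'
#' @param landuse a \code{landuse_raster}.
#' @param class one of the nine landuse class labels; must occur in the
#'   raster, otherwise the distance is undefined and an error is raised.
#' @return Numeric matrix of distances with the raster's dimensions.
#' @export
distance_to_class <- function(landuse, class) {
  stopifnot(inherits(landuse, "landuse_raster"))
  if (!class %in% landuse_classes()) stop("unknown landuse class: ", class)
  mask <- landuse$classes == class
  if (!any(mask)) stop("class absent from raster: distance undefined")
  nearest_cell_distance_cpp(mask, landuse$cell_size)
}

# window row/col span used for coverage: a w x w block "centered" on (r, c);
# for even w there is no exact center cell, the block spans [r - w/2, r + w/2 - 1]
coverage_span <- function(i, w) {
  lo <- i - floor(w / 2)
  hi <- i + ceiling(w / 2) - 1L
  c(lo, hi)
}

#' Coverage percentage of a landuse class around one cell
#'
#' Percentage of cells carrying \code{class} in a \code{window} x
#' \code{window} block of cells around \code{cell_index}. With the default
#' 10-cell window on a 100 m grid this is the share of a 1 km^2 rectangle.
#' An even window has no exact center cell; the block spans rows
#' \code{[r - 5, r + 4]} and columns \code{[c - 5, c + 4]}. At raster borders
#' the window is clipped and the denominator is the number of cells actually
#' inside the raster.
#'
#' @param landuse a \code{landuse_raster}.
#' @param class a landuse class label.
#' @param cell_index \code{c(row, col)} of the query cell (1-based).
#' @param window window edge length in cells (default 10).
#' @return A percentage in \[0, 100\].
#' @export
coverage_percent <- function(landuse, class, cell_index, window = 10) {
  stopifnot(inherits(landuse, "landuse_raster"))
  if (!class %in% landuse_classes()) stop("unknown landuse class: ", class)
  r <- cell_index[1]; c <- cell_index[2]
  if (r < 1 || c < 1 || r > landuse$height || c > landuse$width)
    stop("cell_index outside grid")
  rs <- coverage_span(r, window); cs <- coverage_span(c, window)
  rows <- max(rs[1], 1):min(rs[2], landuse$height)
  cols <- max(cs[1], 1):min(cs[2], landuse$width)
  block <- landuse$classes[rows, cols, drop = FALSE]
  100 * sum(block == class) / length(block)
}

#' Coverage raster of a landuse class
#'
#' \code{\link{coverage_percent}} evaluated at every cell, computed with a
#' summed-area table.
#'
#' @inheritParams coverage_percent
#' @return Numeric matrix of percentages with the raster's dimensions.
#' @export
coverage_raster <- function(landuse, class, window = 10) {
  stopifnot(inherits(landuse, "landuse_raster"))
  if (!class %in% landuse_classes()) stop("unknown landuse class: ", class)
  m <- landuse$classes == class
  nr <- nrow(m); nc <- ncol(m)
  # summed-area table with a zero border
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  block_sum <- function(r0, r1, c0, c1) {
    S[cbind(r1 + 1, c1 + 1)] - S[cbind(r0, c1 + 1)] -
      S[cbind(r1 + 1, c0)] + S[cbind(r0, c0)]
  }
  lo_off <- floor(window / 2); hi_off <- ceiling(window / 2) - 1L
  r0 <- pmax(seq_len(nr) - lo_off, 1L); r1 <- pmin(seq_len(nr) + hi_off, nr)
  c0 <- pmax(seq_len(nc) - lo_off, 1L); c1 <- pmin(seq_len(nc) + hi_off, nc)
  out <- matrix(0, nr, nc)
  for (cc in seq_len(nc)) {
    cnt <- block_sum(r0, r1, rep(c0[cc], nr), rep(c1[cc], nr))
    ncell <- (r1 - r0 + 1) * (c1[cc] - c0[cc] + 1)
    out[, cc] <- 100 * cnt / ncell
  }
  out
}

#' Demographic attributes at a point
#'
#' Point-in-polygon query against a neighborhood table. Boundary points are
#' assigned to the first polygon in table order that covers them; a point in
#' no polygon yields \code{NULL} (a missing-context signal — the caller is
#' expected to drop the run and log it).
#'
#' @param point numeric \code{c(x, y)} in meters.
#' @param neighborhoods a \code{neighborhood_table}.
#' @return One row of the attribute table, or \code{NULL}.
#' @export
demographics_at <- function(point, neighborhoods) {
  stopifnot(inherits(neighborhoods, "neighborhood_table"))
  idx <- polygon_index(matrix(point, ncol = 2), neighborhoods)
  if (is.na(idx)) return(NULL)
  neighborhoods$attributes[idx, , drop = FALSE]
}

# vectorized polygon lookup: first covering polygon in table order, NA if none
polygon_index <- function(pts, neighborhoods) {
  out <- rep(NA_integer_, nrow(pts))
  todo <- seq_len(nrow(pts))
  for (i in seq_along(neighborhoods$polygons)) {
    if (!length(todo)) break
    poly <- neighborhoods$polygons[[i]]
    inside <- mgcv::in.out(poly, pts[todo, , drop = FALSE])
    # in.out is agnostic on exact boundary points; check edges explicitly so
    # the "first polygon in table order" tie rule holds
    border <- !inside & on_polygon_edge(pts[todo, , drop = FALSE], poly)
    hit <- inside | border
    out[todo[hit]] <- i
    todo <- todo[!hit]
  }
  out
}

on_polygon_edge <- function(pts, poly, eps = 1e-9) {
  hit <- rep(FALSE, nrow(pts))
  for (k in seq_len(nrow(poly) - 1)) {
    a <- poly[k, ]; b <- poly[k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- a[1] + t * ab[1] - pts[, 1]
    dy <- a[2] + t * ab[2] - pts[, 2]
    hit <- hit | (dx * dx + dy * dy <= eps^2)
  }
  hit
}

#' Build the full geographic context stack
#'
#' Precomputes, for each of the nine landuse classes, the distance raster and
#' the coverage raster, plus the per-cell neighborhood assignment, over the
#' landuse raster's grid.
#'
#' @param landuse a \code{landuse_raster}.
#' @param neighborhoods a \code{neighborhood_table} covering the extent.
#' @param window coverage window in cells (default 10).
#' @return An object of class \code{geo_context} with fields \code{landuse},
#'   \code{neighborhoods}, \code{dist} (named list of matrices), \code{cov}
#'   (named list of matrices), \code{nb_index} (matrix of polygon row indices,
#'   NA where no polygon covers the cell center), \code{window}.
#' @export
build_geo_context <- function(landuse, neighborhoods, window = 10) {
  stopifnot(inherits(landuse, "landuse_raster"),
            inherits(neighborhoods, "neighborhood_table"))
  present <- unique(as.vector(landuse$classes))
  dist <- list(); cov <- list()
  for (cl in landuse_classes()) {
    dist[[cl]] <- if (cl %in% present) distance_to_class(landuse, cl) else
      matrix(NA_real_, landuse$height, landuse$width)
    cov[[cl]] <- coverage_raster(landuse, cl, window)
  }
  ctr <- cell_centers(landuse)
  nb_index <- matrix(polygon_index(ctr, neighborhoods),
                     nrow = landuse$height, ncol = landuse$width)
  structure(list(landuse = landuse, neighborhoods = neighborhoods,
                 dist = dist, cov = cov, nb_index = nb_index,
                 window = window),
            class = "geo_context")
}

#' @export
print.geo_context <- function(x, ...) {
  cat("<geo_context> ", x$landuse$height, "x", x$landuse$width,
      " grid; distance + coverage rasters for ", length(x$dist),
      " classes; ", nrow(x$neighborhoods$attributes), " neighborhoods\n",
      sep = "")
  invisible(x)
}

# matrix of cell-center coordinates, in column-major cell order
cell_centers <- function(landuse) {
  nr <- landuse$height; nc <- landuse$width; cs <- landuse$cell_size
  cbind(x = landuse$origin[1] + (rep(seq_len(nc), each = nr) - 0.5) * cs,
        y = landuse$origin[2] + (rep(seq_len(nr), times = nc) - 0.5) * cs)
}

# (row, col) of the cell containing each (x, y); NA outside the raster
cell_of_xy <- function(landuse, x, y) {
  col <- floor((x - landuse$origin[1]) / landuse$cell_size) + 1
  row <- floor((y - landuse$origin[2]) / landuse$cell_size) + 1
  bad <- col < 1 | col > landuse$width | row < 1 | row > landuse$height
  row[bad] <- NA; col[bad] <- NA
  cbind(row = as.integer(row), col = as.integer(col))
}
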