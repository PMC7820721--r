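# Plain-text serialization of every pipeline artifact:
#   run tables / transactions / weekly matrices / linkage  -> CSV
#   rasters -> Esri ASCII grid (.asc) + integer class codes 1-9
#   neighborhoods -> GeoJSON
#   binning scheme / reports -> JSON

#' Read and write run tables
#'
#' CSV with columns exactly \code{activity_id, user_id, total_distance_m,
#' start_timestamp, start_x, start_y, weather_type, temperature_c,
#' wind_type, humidity_type} (ISO-8601 timestamps).
#'
#' @param records a \code{run_records} data.frame.
#' @param path file path.
#' @return \code{read_runs} returns a \code{run_records} data.frame.
#' @export
write_runs <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_runs
#' @export
read_runs <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(start_timestamp = "character"))
  out$weather_type[out$weather_type == ""] <- NA
  class(out) <- c("run_records", "data.frame")
  out
}

#' Write / read a class raster as Esri ASCII grid
#'
#' Single-band integer raster (class codes 1-9 in the order of
#' \code{\link{landuse_classes}}); the .asc header carries origin and cell
#' size. The code-to-class table is the position in
#' \code{landuse_classes()}.
#'
#' @param landuse a \code{landuse_raster}.
#' @param path file path (conventionally .asc).
#' @export
write_landuse_asc <- function(landuse, path) {
  codes <- matrix(landuse_codes(landuse$classes),
                  nrow = landuse$height)
  write_asc(codes, landuse$origin, landuse$cell_size, path)
}

#' @rdname write_landuse_asc
#' @export
read_landuse_asc <- function(path) {
  g <- read_asc(path)
  landuse_raster(matrix(landuse_classes()[g$values], nrow = nrow(g$values)),
                 origin = g$origin, cell_size = g$cell_size)
}

# generic Esri ASCII grid writer; row 1 of the matrix is the southernmost
# row, while .asc stores north-to-south, so rows are flipped on write/read
write_asc <- function(values, origin, cell_size, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(values)),
               paste("nrows", nrow(values)),
               paste("xllcorner", origin[1]),
               paste("yllcorner", origin[2]),
               paste("cellsize", cell_size),
               "NODATA_value -9999"), con)
  vals <- values
  vals[is.na(vals)] <- -9999
  for (r in rev(seq_len(nrow(vals))))
    writeLines(paste(vals[r, ], collapse = " "), con)
  invisible(path)
}

read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  h <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                       tolower(vapply(kv, `[`, "", 1)))
  body <- utils::read.table(path, skip = 6)
  m <- as.matrix(body)
  dimnames(m) <- NULL
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[m == h["nodata_value"]] <- NA
  list(values = m, origin = unname(h[c("xllcorner", "yllcorner")]),
       cell_size = unname(h["cellsize"]))
}

#' Write / read a numeric raster (distance or coverage) as ASCII grid
#'
#' @param values numeric matrix (row 1 = southernmost row).
#' @param landuse the \code{landuse_raster} supplying origin/cell size.
#' @param path file path.
#' @export
write_raster_asc <- function(values, landuse, path) {
  write_asc(round(values, 3), landuse$origin, landuse$cell_size, path)
}

#' Write / read neighborhoods as GeoJSON
#'
#' A FeatureCollection of Polygon features with the four demographic
#' properties and the neighborhood id.
#'
#' @param neighborhoods a \code{neighborhood_table}.
#' @param path file path.
#' @export
write_neighborhoods_geojson <- function(neighborhoods, path) {
  att <- neighborhoods$attributes
  feats <- lapply(seq_len(nrow(att)), function(i) {
    ring <- neighborhoods$polygons[[i]]
    list(type = "Feature",
         properties = as.list(att[i, , drop = FALSE]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(k) as.numeric(ring[k, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_neighborhoods_geojson
#' @export
read_neighborhoods_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  att <- do.call(rbind, lapply(feats, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE)))
  for (col in c("population_density", "pct_over_65", "pct_one_person",
                "pct_no_child"))
    att[[col]] <- as.numeric(att[[col]])
  polys <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
  })
  neighborhood_table(att, polys)
}

#' Write / read transactions as CSV
#'
#' One row per transaction: \code{tid}, \code{user_id}, \code{weight} and
#' the 29 item columns.
#'
#' @param transactions a \code{wtransactions}.
#' @param path file path.
#' @export
write_transactions <- function(transactions, path) {
  write.csv(transactions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  structure(out, class = c("wtransactions", "data.frame"))
}

#' Write / read the weekly activity matrix as CSV
#'
#' Columns \code{user_id}, \code{w1} .. \code{w52}.
#'
#' @param matrix a \code{weekly_activity} matrix.
#' @param path file path.
#' @export
write_weekly_matrix <- function(matrix, path) {
  df <- data.frame(user_id = rownames(matrix), unclass(matrix))
  names(df) <- c("user_id", paste0("w", 1:52))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weekly_matrix
#' @export
read_weekly_matrix <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, paste0("w", 1:52)])
  dimnames(m) <- list(df$user_id, NULL)
  structure(m, class = c("weekly_activity", "matrix"))
}

#' Serialize a binning scheme as JSON
#'
#' @param bins a \code{binning_scheme}.
#' @param path file path.
#' @export
write_binning_scheme <- function(bins, path) {
  jsonlite::write_json(unclass(bins), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_binning_scheme
#' @export
read_binning_scheme <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(raw, class = "binning_scheme")
}

#' Write a linkage as CSV
#'
#' Rows (a, b, height, size) in merge order; negative ids are leaves.
#'
#' @param linkage a \code{ward_linkage}.
#' @param path file path.
#' @export
write_linkage <- function(linkage, path) {
  write.csv(data.frame(a = linkage$merge[, 1], b = linkage$merge[, 2],
                       height = linkage$height, size = linkage$size),
            path, row.names = FALSE)
  invisible(path)
}
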