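#' National-quantile binning of geographic features
#'
#' Builds the discretization scheme for the geographic (distance, coverage,
#' demographic) features from their distribution over all grid cells of the
#' reference landscape: a dedicated \code{"0"} category, plus 10
#' equal-probability bins over the strictly positive cell values. Edges use
#' the nearest-rank quantile (sorted positive values indexed at
#' \code{ceiling(n k / 10)}, k = 1..9); duplicate edges on discrete
#' distributions are merged, so degenerate features get fewer (possibly one)
#' positive bins. Edges are computed once over the reference raster and
#' frozen in the scheme. Temporal and measured-weather features use fixed
#' bins (8 three-hour bins, 7 weekdays, 12 months, 5 temperature bins over
#' \[-10, 30\] °C) and the fixed category vocabularies.
#'
#' @param geo a \code{geo_context} stack (the reference landscape).
#' @return An object of class \code{binning_scheme}: a named list with, per
#'   feature, \code{type} ("categorical" or "numeric_zero"), \code{labels}
#'   (ordered categories) and, for numeric features, \code{edges}.
#' @export
national_quantile_bins <- function(geo) {
  stopifnot(inherits(geo, "geo_context"))
  scheme <- fixed_bins()
  for (cl in landuse_classes()) {
    scheme[[paste0("dist_", cl)]] <- numeric_zero_bins(as.vector(geo$dist[[cl]]))
    scheme[[paste0("cov_", cl)]]  <- numeric_zero_bins(as.vector(geo$cov[[cl]]))
  }
  nbv <- geo$neighborhoods$attributes[as.vector(geo$nb_index), , drop = FALSE]
  for (f in c("population_density", "pct_over_65", "pct_one_person",
              "pct_no_child")) {
    scheme[[f]] <- numeric_zero_bins(nbv[[f]])
  }
  structure(scheme[situation_features()], class = "binning_scheme")
}

# fixed (non-geographic) part of the scheme
fixed_bins <- function() {
  hour_lab <- sprintf("[%d,%d)", seq(0, 21, 3), seq(3, 24, 3))
  temp_edges <- c(-2, 6, 14, 22)
  temp_lab <- c("[-10,-2]", "(-2,6]", "(6,14]", "(14,22]", "(22,30]")
  list(
    hour = list(type = "categorical", labels = hour_lab),
    weekday = list(type = "categorical", labels = weekday_names()),
    month = list(type = "categorical", labels = month.name),
    temperature = list(type = "numeric_fixed", labels = temp_lab,
                       edges = temp_edges, range = c(-10, 30)),
    weather = list(type = "categorical", labels = weather_types()),
    wind = list(type = "categorical", labels = wind_types()),
    humidity = list(type = "categorical", labels = humidity_types())
  )
}

# zero category + nearest-rank decile bins over positive values
numeric_zero_bins <- function(values) {
  v <- values[is.finite(values)]
  pos <- sort(v[v > 0])
  n <- length(pos)
  if (n == 0) {
    warning("all reference values are zero; scheme collapses to the '0' category")
    return(list(type = "numeric_zero", labels = "0", edges = numeric(0)))
  }
  edges <- unique(pos[ceiling(n * (1:9) / 10)])
  edges <- edges[edges < max(pos)]          # an edge at the max would make an empty top bin
  vmax <- max(pos)
  lo <- c(0, edges); hi <- c(edges, vmax)
  labels <- c("0", sprintf("(%s,%s]", format_num(lo), format_num(hi)))
  list(type = "numeric_zero", labels = labels, edges = edges, vmax = vmax)
}

format_num <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 7)

#' Categorize values under a binning scheme
#'
#' Maps raw feature values to their category labels. Numeric geographic
#' features: 0 maps to the \code{"0"} category; positive values fall in
#' left-open right-closed decile bins, values above the reference maximum
#' clamp into the top bin. Temperature clamps into \[-10, 30\] with a warning
#' when out of range. Categorical features must use a known category.
#'
#' @param bins a \code{binning_scheme}.
#' @param feature feature name (one of \code{situation_features()}).
#' @param values numeric or character vector.
#' @return Character vector of category labels.
#' @export
bin_value <- function(bins, feature, values) {
  sch <- bins[[feature]]
  if (is.null(sch)) stop("unknown feature: ", feature)
  switch(sch$type,
    categorical = {
      if (feature == "hour") return(bin_hour(values))
      if (feature == "weekday" && is.numeric(values))
        return(weekday_names()[values])
      if (feature == "month" && is.numeric(values))
        return(month.name[values])
      bad <- !is.na(values) & !values %in% sch$labels
      if (any(bad)) stop("unknown ", feature, " value(s): ",
                         paste(unique(values[bad]), collapse = ", "))
      as.character(values)
    },
    numeric_fixed = bin_temperature(values, sch),
    numeric_zero = {
      out <- rep(NA_character_, length(values))
      zero <- !is.na(values) & values <= 0
      out[zero] <- "0"
      pos <- !is.na(values) & values > 0
      if (any(pos)) {
        idx <- findInterval(values[pos], sch$edges, left.open = TRUE) + 1L
        idx <- pmin(idx, length(sch$labels) - 1L)  # clamp above reference max
        out[pos] <- sch$labels[-1][idx]
      }
      out
    })
}

# hour-of-day (decimal) -> eight three-hour half-open bins [0,3) .. [21,24)
bin_hour <- function(hour) {
  idx <- pmin(floor(hour / 3), 7)
  sprintf("[%d,%d)", idx * 3, idx * 3 + 3)
}

bin_temperature <- function(temp, sch) {
  out_of_range <- !is.na(temp) & (temp < sch$range[1] | temp > sch$range[2])
  if (any(out_of_range))
    warning(sum(out_of_range),
            " temperature value(s) outside [-10, 30] clamped into boundary bins")
  t <- pmin(pmax(temp, sch$range[1]), sch$range[2])
  idx <- findInterval(t, sch$edges, left.open = TRUE) + 1L
  sch$labels[idx]
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat("<binning_scheme> ", length(x), " features\n", sep = "")
  for (f in names(x))
    cat(sprintf("  %-20s %2d categories\n", f, length(x[[f]]$labels)))
  invisible(x)
}
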