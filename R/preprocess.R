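#' Clean run records
#'
#' Removes runs that cannot enter the analysis: total distance below
#' \code{min_distance} (100 m; exactly 100 m is retained), missing or
#' unparseable fields, categorical values outside the fixed vocabularies,
#' and — when a geographic context is supplied — start points outside the
#' raster or covered by no neighborhood polygon (missing context). Cleaning
#' is total and idempotent; per-reason drop counts are attached as the
#' \code{"drop_log"} attribute.
#'
#' @param records a \code{run_records} data.frame.
#' @param geo optional \code{geo_context}; enables the missing-context rule.
#' @param min_distance minimum retained distance in meters (default 100).
#' @return The retained records, with attribute \code{drop_log}.
#' @export
clean_runs <- function(records, geo = NULL, min_distance = 100) {
  n0 <- nrow(records)
  drop <- c(missing_field = 0L, bad_category = 0L, bad_timestamp = 0L,
            short_distance = 0L, missing_context = 0L)
  if (!n0) return(structure(records, drop_log = drop))

  need <- c("user_id", "total_distance_m", "start_timestamp", "start_x",
            "start_y", "weather_type", "temperature_c", "wind_type",
            "humidity_type")
  miss <- Reduce(`|`, lapply(records[need], is.na))
  drop["missing_field"] <- sum(miss)
  keep <- !miss

  badcat <- keep & (!records$weather_type %in% weather_types() |
                    !records$wind_type %in% wind_types() |
                    !records$humidity_type %in% humidity_types())
  drop["bad_category"] <- sum(badcat)
  keep <- keep & !badcat

  ts <- parse_ts(records$start_timestamp)
  badts <- keep & is.na(ts)
  drop["bad_timestamp"] <- sum(badts)
  keep <- keep & !badts

  short <- keep & records$total_distance_m < min_distance
  drop["short_distance"] <- sum(short)
  keep <- keep & !short

  if (!is.null(geo)) {
    cell <- cell_of_xy(geo$landuse, records$start_x, records$start_y)
    no_ctx <- is.na(cell[, "row"])
    inside <- !no_ctx
    nb <- rep(NA_integer_, n0)
    nb[inside] <- geo$nb_index[cbind(cell[inside, "row"], cell[inside, "col"])]
    no_ctx <- no_ctx | is.na(nb)
    no_ctx <- keep & no_ctx
    drop["missing_context"] <- sum(no_ctx)
    keep <- keep & !no_ctx
  }
  if (sum(drop))
    message("clean_runs: dropped ", sum(drop), "/", n0, " runs (",
            paste(names(drop)[drop > 0], drop[drop > 0], sep = "=",
                  collapse = ", "), ")")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, drop_log = drop)
}

#' Remove users with too few runs
#'
#' Drops all runs of users contributing fewer than \code{min_runs} runs over
#' the whole (cleaned) history.
#'
#' @param records cleaned \code{run_records}.
#' @param min_runs minimum run count per retained user (default 10).
#' @return The retained records, with attribute \code{n_users_dropped}.
#' @export
filter_sparse_users <- function(records, min_runs = 10) {
  if (!nrow(records)) return(structure(records, n_users_dropped = 0L))
  cnt <- table(records$user_id)
  keep_users <- names(cnt)[cnt >= min_runs]
  out <- records[records$user_id %in% keep_users, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, drop_log = attr(records, "drop_log"),
            n_users_dropped = length(cnt) - length(keep_users))
}

#' Per-user normalized running distance
#'
#' Normalizes each run's distance against the user's personal statistics:
#' \deqn{y' = (y - \mathrm{average}(y^j)) / (\max(y^j) - \min(y^j))}
#' over all of the user's retained runs, yielding a score in \[-1, 1\]: a run
#' at the user's mean distance maps to exactly 0. When a user's max equals
#' their min (all runs identical) the weight is 0 by convention.
#'
#' @param records cleaned, filtered \code{run_records}.
#' @return Numeric vector of weights, one per row of \code{records}.
#' @export
normalize_distance <- function(records) {
  if (!nrow(records)) return(numeric(0))
  y <- records$total_distance_m
  u <- records$user_id
  mu <- tapply(y, u, mean); rng <- tapply(y, u, function(v) max(v) - min(v))
  num <- y - mu[u]
  den <- rng[u]
  w <- ifelse(den > 0, num / den, 0)
  as.numeric(w)
}

#' Extract the 29-feature situation vector of one run
#'
#' @param record a single-row \code{run_records} data.frame (cleaned; start
#'   point inside the raster and a neighborhood).
#' @param geo a \code{geo_context}.
#' @param bins a \code{binning_scheme}.
#' @return Named character vector of exactly 29 (feature, category) items.
#' @export
extract_features <- function(record, geo, bins) {
  stopifnot(nrow(record) == 1)
  f <- situation_matrix(record, geo, bins)
  out <- unlist(f[1, , drop = TRUE])
  if (anyNA(out)) stop("record lacks geographic context")
  out
}

# lenient ISO-8601 parser: NA (not an error) on malformed strings
parse_ts <- function(x) {
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"), tz = "UTC")
  out
}

# vectorized feature extraction: one row per record, 29 character columns
situation_matrix <- function(records, geo, bins) {
  ts <- parse_ts(records$start_timestamp)
  hour <- as.integer(format(ts, "%H")) + as.integer(format(ts, "%M")) / 60
  out <- data.frame(
    hour = bin_hour(hour),
    weekday = weekday_names()[as.integer(format(ts, "%u"))],
    month = month.name[as.integer(format(ts, "%m"))],
    temperature = bin_value(bins, "temperature", records$temperature_c),
    weather = bin_value(bins, "weather", records$weather_type),
    wind = bin_value(bins, "wind", records$wind_type),
    humidity = bin_value(bins, "humidity", records$humidity_type),
    stringsAsFactors = FALSE)
  cell <- cell_of_xy(geo$landuse, records$start_x, records$start_y)
  ok <- !is.na(cell[, "row"])
  idx <- cbind(cell[ok, "row"], cell[ok, "col"])
  for (cl in landuse_classes()) {
    dv <- cv <- rep(NA_real_, nrow(records))
    dv[ok] <- geo$dist[[cl]][idx]
    cv[ok] <- geo$cov[[cl]][idx]
    out[[paste0("dist_", cl)]] <- bin_value(bins, paste0("dist_", cl), dv)
    out[[paste0("cov_", cl)]] <- bin_value(bins, paste0("cov_", cl), cv)
  }
  nb <- rep(NA_integer_, nrow(records))
  nb[ok] <- geo$nb_index[idx]
  att <- geo$neighborhoods$attributes
  for (f in c("population_density", "pct_over_65", "pct_one_person",
              "pct_no_child")) {
    out[[f]] <- bin_value(bins, f, att[[f]][nb])
  }
  out[situation_features()]
}

#' Build weighted situation transactions
#'
#' Turns cleaned, filtered run records into the transaction table used by the
#' miner: one row per run with its id, user, normalized-distance weight
#' (\code{\link{normalize_distance}}) and the 29 situation items.
#'
#' @param records cleaned, filtered \code{run_records}.
#' @param geo a \code{geo_context}.
#' @param bins a \code{binning_scheme}.
#' @return A data.frame of class \code{wtransactions} with columns
#'   \code{tid}, \code{user_id}, \code{weight} and the 29 feature columns;
#'   the full category vocabulary per feature is kept in the \code{"levels"}
#'   attribute.
#' @export
build_transactions <- function(records, geo, bins) {
  w <- normalize_distance(records)
  f <- situation_matrix(records, geo, bins)
  if (anyNA(f)) stop("records lack geographic context; run clean_runs(records, geo) first")
  out <- cbind(data.frame(tid = records$activity_id,
                          user_id = records$user_id,
                          weight = w, stringsAsFactors = FALSE), f)
  lev <- lapply(bins, `[[`, "labels")
  structure(out, class = c("wtransactions", "data.frame"), levels = lev)
}

#' Weekly activity matrix with most-active 52-week window
#'
#' Counts each user's runs per ISO week over the full history, then selects
#' per user the 52-consecutive-week window with the most runs (ties broken
#' by the earliest window start). Histories spanning fewer than 52 weeks are
#' zero-padded on the right.
#'
#' @param records cleaned, filtered \code{run_records}.
#' @return An integer matrix (users x 52) of class \code{weekly_activity};
#'   rownames are user ids, attribute \code{window_start} gives each user's
#'   selected window start (global week index, 1-based).
#' @export
weekly_matrix <- function(records) {
  stopifnot(nrow(records) > 0)
  ts <- parse_ts(records$start_timestamp)
  d <- as.Date(ts)
  monday <- d - (as.integer(format(d, "%u")) - 1)   # ISO week start
  origin <- min(monday)
  gweek <- as.integer(monday - origin) %/% 7L + 1L
  W <- max(52L, max(gweek))
  users <- sort(unique(records$user_id))
  mat <- matrix(0L, length(users), 52L, dimnames = list(users, NULL))
  wstart <- integer(length(users))
  cnt_all <- table(factor(records$user_id, users), factor(gweek, seq_len(W)))
  for (i in seq_along(users)) {
    cnt <- as.integer(cnt_all[i, ])
    sums <- filter_window52(cnt)
    s <- which.max(sums)                 # earliest max (which.max tie rule)
    wstart[i] <- s
    mat[i, ] <- cnt[s:(s + 51)]
  }
  structure(mat, class = c("weekly_activity", "matrix"),
            window_start = wstart, origin_monday = origin)
}

# sliding sums of width 52 over a (right-padded) count vector
filter_window52 <- function(cnt) {
  W <- length(cnt)
  if (W < 52) cnt <- c(cnt, rep(0L, 52 - W))
  cs <- c(0L, cumsum(cnt))
  n <- length(cnt) - 51
  cs[(1:n) + 52] - cs[1:n]
}

#' @export
print.weekly_activity <- function(x, ...) {
  cat("<weekly_activity> ", nrow(x), " users x 52 weeks; mean annual runs ",
      round(mean(rowSums(x)), 1), "\n", sep = "")
  invisible(x)
}
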