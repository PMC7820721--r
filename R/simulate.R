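#' Planted situation effects
#'
#' An effect specification lists situations (sets of (feature, category)
#' items over the temporal and weather features) together with an additive
#' shift in meters applied to the distance of any run whose situation vector
#' contains the set. Effect sizes are multiplied by the user's archetype
#' \code{situation_sensitivity}. These planted effects are what the mining
#' stage is expected to recover.
#'
#' @param delta additive distance shift in meters (finite).
#' @param ... named (feature = category) items, e.g.
#'   \code{weekday = "Sunday", hour = "[9,12)"}. Features must be temporal or
#'   weather features (the ones computable at simulation time); categories
#'   must be valid bins.
#' @return \code{situation_effect}: one effect; \code{effect_spec}: a classed
#'   list of effects.
#' @examples
#' eff <- effect_spec(situation_effect(800, weekday = "Sunday", hour = "[9,12)"))
#' @export
situation_effect <- function(delta, ...) {
  items <- c(...)
  if (!is.finite(delta)) stop("delta must be finite")
  if (!length(items) || is.null(names(items)) || any(names(items) == ""))
    stop("a situation needs at least one named (feature = category) item")
  fb <- fixed_bins()
  for (f in names(items)) {
    if (!f %in% names(fb))
      stop("effects can only be planted on temporal/weather features, not: ", f)
    if (!items[[f]] %in% fb[[f]]$labels)
      stop("'", items[[f]], "' is not a valid category of feature ", f)
  }
  structure(list(situation = items, delta = delta), class = "situation_effect")
}

#' @rdname situation_effect
#' @param ... for \code{effect_spec}: \code{situation_effect} objects.
#' @export
effect_spec <- function(...) {
  effs <- list(...)
  if (length(effs) == 1 && is.list(effs[[1]]) &&
      !inherits(effs[[1]], "situation_effect")) effs <- effs[[1]]
  stopifnot(all(vapply(effs, inherits, TRUE, "situation_effect")))
  structure(effs, class = "effect_spec")
}

# archetype-shared preference vectors, aligned with the discretization bins:
# 8 three-hour slots and 7 weekdays (Sunday and the 9:00-12:00 slot favoured)
diurnal_prefs <- function() c(0.01, 0.01, 0.06, 0.24, 0.14, 0.12, 0.26, 0.16)
weekday_prefs <- function() c(1, 1, 1.1, 1, 1.1, 1.6, 2.2)

# monthly mean temperature (deg C) of the synthetic climate
month_temp_mean <- function() 10.5 + 7.5 * cos(2 * pi * ((1:12) - 7) / 12)

#' Simulate run records
#'
#' Generates one run table over the given horizon: per user, the yearly run
#' total equals \code{round(annual_rate)} (remainders spread over years), run
#' weeks follow the archetype weekly pattern (bursty users concentrate in
#' their seasonal block, at the same phase every year), weekdays and
#' three-hour slots follow the preference vectors, weather is drawn from a
#' month-conditioned model, and start locations are sampled with elevated
#' probability in and near residential cells. Each run's distance is
#'
#' \code{baseline + sum(matched effect deltas) * sensitivity + N(0, noise_sd)}
#'
#' clipped below at 50 m. A small fraction of runs are "aborted" recordings
#' (uniform 50-400 m) and a small fraction lose their weather record; both
#' exist so the cleaning rules have realistic work to do and can be switched
#' off.
#'
#' @param seed integer seed.
#' @param users a \code{runner_profiles} data.frame from
#'   \code{\link{make_runners}}.
#' @param world list with \code{landuse} (and optionally
#'   \code{neighborhoods}) from \code{\link{make_landscape}}.
#' @param effects an \code{\link{effect_spec}} (or NULL for no effects).
#' @param horizon_years number of simulated years (>= 1).
#' @param noise_sd per-run Gaussian distance noise, meters.
#' @param abort_prob probability a run is an aborted recording.
#' @param missing_prob probability the weather record is missing.
#' @param start_monday first Monday of the simulated calendar.
#' @return A \code{run_records} data.frame with columns \code{activity_id},
#'   \code{user_id}, \code{total_distance_m}, \code{start_timestamp},
#'   \code{start_x}, \code{start_y}, \code{weather_type},
#'   \code{temperature_c}, \code{wind_type}, \code{humidity_type}.
#' @export
simulate_runs <- function(seed, users, world, effects = NULL,
                          horizon_years = 4, noise_sd = 500,
                          abort_prob = 0.02, missing_prob = 0.005,
                          start_monday = "2012-12-31") {
  if (!nrow(users)) return(empty_run_records())
  if (horizon_years < 1) stop("horizon must be >= 1 year")
  if (!is.null(effects) && !inherits(effects, "effect_spec"))
    stop("effects must be an effect_spec")
  landuse <- world$landuse
  stopifnot(inherits(landuse, "landuse_raster"))
  with_seed(seed, {
    H <- as.integer(horizon_years)
    # per-user run counts and calendar placement
    per_user <- lapply(seq_len(nrow(users)), function(i) {
      u <- users[i, ]
      n_total <- round(H * u$annual_rate)
      if (n_total <= 0) return(NULL)
      base <- n_total %/% H
      n_year <- rep(base, H) + c(rep(1, n_total %% H), rep(0, H - n_total %% H))
      year <- rep(seq_len(H), n_year)
      # quasi-even weekly placement inside the user's active period: an even
      # base load plus randomly placed remainder weeks; the most-active
      # 52-week window then reads the annual rate without selection bias
      wks <- seq(u$block_start_week, length.out = u$block_len)
      woy <- unlist(lapply(n_year, function(ny) {
        base <- ny %/% length(wks)
        rem <- ny - base * length(wks)
        c(rep(wks, base), sample(wks, rem))
      }), use.names = FALSE)
      data.frame(user_idx = i, gweek = (year - 1) * 52 + woy)
    })
    runs <- do.call(rbind, per_user)
    n <- nrow(runs)
    if (is.null(n) || n == 0) return(empty_run_records())

    wday <- sample.int(7, n, replace = TRUE, prob = weekday_prefs())
    slot <- sample.int(8, n, replace = TRUE, prob = diurnal_prefs()) - 1L
    hour <- slot * 3 + runif(n, 0, 3)
    t0 <- as.POSIXct(paste(start_monday, "00:00:00"), tz = "UTC")
    ts <- t0 + ((runs$gweek - 1) * 7 + (wday - 1)) * 86400 + round(hour * 3600)
    month <- as.integer(format(ts, "%m"))

    temp <- round(rnorm(n, month_temp_mean()[month], 3.5), 1)
    summer <- month %in% 4:9
    wt <- character(n)
    p_summer <- c(0.30, 0.22, 0.18, 0.12, 0.07, 0.04, 0.00, 0.01, 0.06)
    p_winter <- c(0.12, 0.15, 0.26, 0.20, 0.10, 0.01, 0.06, 0.02, 0.08)
    wt[summer] <- sample(weather_types(), sum(summer), TRUE, p_summer)
    wt[!summer] <- sample(weather_types(), sum(!summer), TRUE, p_winter)
    wind <- sample(wind_types(), n, TRUE, c(0.2, 0.35, 0.3, 0.12, 0.03))
    hum <- sample(humidity_types(), n, TRUE, c(0.25, 0.5, 0.25))

    # start cells: elevated weight in and near residential cells
    res <- landuse$classes == "residential"
    near <- dilate_mask(res, 3)
    w_cell <- 1 + 4 * as.vector(res) + 2 * as.vector(near & !res)
    cell <- sample.int(length(w_cell), n, replace = TRUE, prob = w_cell)
    nr <- landuse$height
    row <- (cell - 1) %% nr + 1; col <- (cell - 1) %/% nr + 1
    cs <- landuse$cell_size
    x <- landuse$origin[1] + (col - 1 + runif(n)) * cs
    y <- landuse$origin[2] + (row - 1 + runif(n)) * cs

    # planted effects, matched on the run's own temporal/weather items
    delta <- rep(0, n)
    if (!is.null(effects) && length(effects)) {
      items <- data.frame(hour = bin_hour(hour),
                          weekday = weekday_names()[wday],
                          month = month.name[month],
                          temperature = bin_temperature(temp, fixed_bins()$temperature),
                          weather = wt, wind = wind, humidity = hum,
                          stringsAsFactors = FALSE)
      for (eff in effects) {
        m <- rep(TRUE, n)
        for (f in names(eff$situation))
          m <- m & !is.na(items[[f]]) & items[[f]] == eff$situation[[f]]
        delta[m] <- delta[m] + eff$delta
      }
    }
    dist <- users$baseline_m[runs$user_idx] +
      delta * users$sensitivity[runs$user_idx] +
      (if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
    dist <- pmax(dist, 50)
    ab <- runif(n) < abort_prob
    dist[ab] <- runif(sum(ab), 50, 400)
    wt[runif(n) < missing_prob] <- NA

    out <- data.frame(
      activity_id = sprintf("A%07d", seq_len(n)),
      user_id = users$user_id[runs$user_idx],
      total_distance_m = round(dist),
      start_timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
      start_x = round(x, 1), start_y = round(y, 1),
      weather_type = wt, temperature_c = temp,
      wind_type = wind, humidity_type = hum,
      stringsAsFactors = FALSE)
    class(out) <- c("run_records", "data.frame")
    out
  })
}

empty_run_records <- function() {
  out <- data.frame(activity_id = character(), user_id = character(),
                    total_distance_m = numeric(), start_timestamp = character(),
                    start_x = numeric(), start_y = numeric(),
                    weather_type = character(), temperature_c = numeric(),
                    wind_type = character(), humidity_type = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("run_records", "data.frame")
  out
}

# binary dilation of a logical matrix by k cells (Chebyshev)
dilate_mask <- function(m, k) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(k)) {
    out <- out |
      rbind(FALSE, out[-nr, , drop = FALSE]) |
      rbind(out[-1, , drop = FALSE], FALSE) |
      cbind(FALSE, out[, -nc, drop = FALSE]) |
      cbind(out[, -1, drop = FALSE], FALSE)
  }
  out
}
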