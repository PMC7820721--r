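#' Runner archetype specification
#'
#' Describes one runner archetype: its annual run count, how runs spread over
#' the year, its per-user baseline distance distribution, and how strongly
#' planted situation effects act on it.
#'
#' @param label archetype name ("sporadic" or "regular").
#' @param annual_run_count_mean mean number of runs per year (> 0).
#' @param weekly_pattern "bursty" (runs concentrated in one seasonal block of
#'   the year, repeated at the same phase each year) or "consistent" (runs
#'   spread uniformly over all weeks).
#' @param active_weeks length of the seasonal block for bursty archetypes.
#' @param baseline_distance_mean,baseline_distance_sd per-user baseline run
#'   distance distribution (meters).
#' @param situation_sensitivity multiplier applied to planted effect sizes
#'   for users of this archetype (>= 0).
#' @return An object of class \code{archetype_spec}.
#' @export
archetype_spec <- function(label, annual_run_count_mean, weekly_pattern,
                           active_weeks = 18,
                           baseline_distance_mean = 6000,
                           baseline_distance_sd = 1500,
                           situation_sensitivity = 1) {
  stopifnot_scalar_pos(annual_run_count_mean, "annual_run_count_mean")
  if (situation_sensitivity < 0) stop("situation_sensitivity must be >= 0")
  weekly_pattern <- match.arg(weekly_pattern, c("bursty", "consistent"))
  structure(list(label = label,
                 annual_run_count_mean = annual_run_count_mean,
                 weekly_pattern = weekly_pattern,
                 active_weeks = active_weeks,
                 baseline_distance_mean = baseline_distance_mean,
                 baseline_distance_sd = baseline_distance_sd,
                 situation_sensitivity = situation_sensitivity),
            class = "archetype_spec")
}

#' Default runner archetypes
#'
#' Two archetypes emulating the empirical runner clusters: a sporadic one
#' (about 34 runs per year, concentrated in a seasonal sub-period) and a
#' regular one (about 94 runs per year, spread consistently over the year).
#'
#' @param sporadic_sensitivity,regular_sensitivity effect-size multipliers
#'   (sporadic runners are modelled as more situation-sensitive).
#' @return Named list of two \code{archetype_spec} objects.
#' @export
default_archetypes <- function(sporadic_sensitivity = 2,
                               regular_sensitivity = 0.5) {
  list(
    sporadic = archetype_spec("sporadic", 34, "bursty", active_weeks = 18,
                              baseline_distance_mean = 5000,
                              baseline_distance_sd = 1200,
                              situation_sensitivity = sporadic_sensitivity),
    regular = archetype_spec("regular", 94, "consistent",
                             baseline_distance_mean = 8000,
                             baseline_distance_sd = 1500,
                             situation_sensitivity = regular_sensitivity))
}

#' Generate a synthetic runner population
#'
#' Draws \code{n_users} user profiles from the given archetypes. Each user
#' gets a personal annual run rate (Gamma-distributed around the archetype
#' mean, coefficient of variation 0.25), a baseline distance, a seasonal
#' activity block (bursty archetypes), and weekday/hour-of-day preference
#' vectors aligned with the discretization bins (Sunday and the three-hour
#' morning slots are favoured).
#'
#' @param seed integer seed.
#' @param n_users number of users (>= 2).
#' @param archetype_fractions named numeric vector over the archetype labels,
#'   summing to 1.
#' @param specs named list of \code{archetype_spec}s (default
#'   \code{\link{default_archetypes}()}).
#' @return A data.frame of user profiles (class \code{runner_profiles}) with
#'   columns \code{user_id}, \code{archetype}, \code{annual_rate},
#'   \code{baseline_m}, \code{sensitivity}, \code{block_start_week},
#'   \code{block_len}.
#' @export
make_runners <- function(seed, n_users, archetype_fractions = NULL,
                         specs = default_archetypes()) {
  if (n_users < 2) stop("need at least 2 users")
  if (is.null(archetype_fractions))
    archetype_fractions <- c(sporadic = 0.8, regular = 0.2)
  if (abs(sum(archetype_fractions) - 1) > 1e-8)
    stop("archetype_fractions must sum to 1")
  if (!all(names(archetype_fractions) %in% names(specs)))
    stop("fractions name unknown archetypes")
  with_seed(seed, {
    arch <- sample(names(archetype_fractions), n_users, replace = TRUE,
                   prob = archetype_fractions)
    rate <- baseline <- sens <- numeric(n_users)
    bstart <- blen <- integer(n_users)
    for (a in unique(arch)) {
      i <- which(arch == a); sp <- specs[[a]]
      cv <- 0.25
      rate[i] <- rgamma(length(i), shape = 1 / cv^2,
                        scale = sp$annual_run_count_mean * cv^2)
      baseline[i] <- pmax(rnorm(length(i), sp$baseline_distance_mean,
                                sp$baseline_distance_sd), 1000)
      sens[i] <- sp$situation_sensitivity
      if (sp$weekly_pattern == "bursty") {
        blen[i] <- sp$active_weeks
        bstart[i] <- sample.int(52 - sp$active_weeks + 1, length(i),
                                replace = TRUE)
      } else {
        blen[i] <- 52L; bstart[i] <- 1L
      }
    }
    structure(data.frame(user_id = sprintf("U%05d", seq_len(n_users)),
                         archetype = arch, annual_rate = rate,
                         baseline_m = baseline, sensitivity = sens,
                         block_start_week = bstart, block_len = blen,
                         stringsAsFactors = FALSE),
              class = c("runner_profiles", "data.frame"),
              specs = specs)
  })
}
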