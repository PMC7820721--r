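#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults reproduce the
#' packaged study conditions: 500 users split 80/20 into the sporadic and
#' regular archetypes, a 60x60-cell (6 km x 6 km) landscape of 100 m cells,
#' 4 simulated years, and two planted situation effects (+800 m on Sunday
#' 9:00-12:00 runs, -600 m on Wednesday 18:00-21:00 runs).
#'
#' @param seed master seed; per-stage child seeds are derived from it.
#' @param n_users number of simulated users.
#' @param archetype_fractions named fractions over the archetypes.
#' @param archetypes named list of \code{\link{archetype_spec}}s.
#' @param effects an \code{\link{effect_spec}} of planted effects.
#' @param world list of landscape parameters (\code{width_cells},
#'   \code{height_cells}, \code{cell_size}, \code{class_mix},
#'   \code{n_neighborhoods}).
#' @param horizon_years simulated years.
#' @param noise_sd per-run distance noise (m).
#' @param min_distance,min_runs cleaning thresholds (100 m, 10 runs).
#' @param sigma mining threshold; the default \code{"auto"} sets it to 5x
#'   the Monte-Carlo null standard deviation of single-item supports.
#' @param mode,max_len mining mode and itemset size cap.
#' @param n_clusters dendrogram cut (number of clusters); alternatively set
#'   \code{cut_threshold} to cut at a fixed height.
#' @param cut_threshold optional height threshold overriding
#'   \code{n_clusters}.
#' @param top_k situations per top-situation list.
#' @return A classed list (\code{runsit_config}).
#' @export
runsit_config <- function(seed = 1, n_users = 500,
                          archetype_fractions = c(sporadic = 0.8, regular = 0.2),
                          archetypes = default_archetypes(),
                          effects = default_effects(),
                          world = list(width_cells = 60, height_cells = 60,
                                       cell_size = 100, class_mix = NULL,
                                       n_neighborhoods = 25),
                          horizon_years = 4, noise_sd = 500,
                          min_distance = 100, min_runs = 10,
                          sigma = "auto", mode = "exhaustive", max_len = 4,
                          n_clusters = 2, cut_threshold = NULL, top_k = 5) {
  cfg <- list(seed = seed, n_users = n_users,
              archetype_fractions = archetype_fractions,
              archetypes = archetypes, effects = effects, world = world,
              horizon_years = horizon_years, noise_sd = noise_sd,
              min_distance = min_distance, min_runs = min_runs,
              sigma = sigma, mode = mode, max_len = max_len,
              n_clusters = n_clusters, cut_threshold = cut_threshold,
              top_k = top_k)
  structure(cfg, class = "runsit_config")
}

#' Default planted effects
#'
#' Sunday-morning runs (+800 m) and Wednesday-evening runs (-600 m),
#' mirroring the direction of the empirical finding that late-morning Sunday
#' runs tend to be long and weekday-evening runs short.
#' @return An \code{\link{effect_spec}}.
#' @export
default_effects <- function() {
  effect_spec(situation_effect(800, weekday = "Sunday", hour = "[9,12)"),
              situation_effect(-600, weekday = "Wednesday", hour = "[18,21)"))
}

#' Run the full analysis pipeline
#'
#' simulate world and runners -> simulate runs -> enrich with geographic
#' context and bins -> clean, filter, build transactions and the weekly
#' matrix -> DTW + Ward clustering -> per-cluster variability, histograms
#' and weighted frequent itemset mining. Every stage draws its randomness
#' from a child seed of \code{config$seed}, so the report is reproducible
#' bit-for-bit.
#'
#' @param config a \code{\link{runsit_config}}.
#' @param out_dir optional directory; when given, every intermediate
#'   artifact (run table CSV, rasters, GeoJSON, transactions, weekly matrix,
#'   linkage, report tables) is persisted there.
#' @return An object of class \code{runsit_report}; see
#'   \code{\link{print.runsit_report}}.
#' @export
run_pipeline <- function(config = runsit_config(), out_dir = NULL) {
  stopifnot(inherits(config, "runsit_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  wd <- config$world
  world <- stage("simulate_world",
    make_landscape(child_seed(config$seed, 1), wd$width_cells,
                   wd$height_cells, wd$class_mix, wd$cell_size,
                   wd$n_neighborhoods))
  users <- stage("simulate_users",
    make_runners(child_seed(config$seed, 2), config$n_users,
                 config$archetype_fractions, config$archetypes))
  runs <- stage("simulate_runs",
    simulate_runs(child_seed(config$seed, 3), users, world, config$effects,
                  config$horizon_years, config$noise_sd))
  geo <- stage("enrich", build_geo_context(world$landuse, world$neighborhoods))
  bins <- stage("enrich", national_quantile_bins(geo))

  cleaned <- stage("prepare", clean_runs(runs, geo, config$min_distance))
  filtered <- stage("prepare", filter_sparse_users(cleaned, config$min_runs))
  tx <- stage("prepare", build_transactions(filtered, geo, bins))
  wm <- stage("prepare", weekly_matrix(filtered))

  dm <- stage("cluster", pairwise_dtw(wm))
  linkage <- stage("cluster", ward_linkage(dm))
  labels <- stage("cluster",
    if (!is.null(config$cut_threshold))
      cut_dendrogram(linkage, config$cut_threshold)
    else cut_k(linkage, config$n_clusters))
  profiles <- stage("cluster", cluster_profile(labels, wm))

  # mining is done per cluster; report tables follow the less active cluster
  user_cluster <- labels[tx$user_id]
  sigma_used <- config$sigma
  if (identical(sigma_used, "auto")) {
    sigma_used <- 5 * null_item_support_sd(tx, n_perm = 20,
                                           seed = child_seed(config$seed, 4))$max
  }
  variability <- list(); histograms <- list(); situations <- list()
  headline <- c("hour", "weekday", "temperature", "dist_residential",
                "dist_parks", "population_density")
  fc <- feature_categories()
  for (k in profiles$cluster) {
    txk <- tx[user_cluster == k, , drop = FALSE]
    attr(txk, "levels") <- attr(tx, "levels")
    ck <- as.character(k)
    variability[[ck]] <- feature_variability(txk)
    histograms[[ck]] <- lapply(stats::setNames(headline, headline),
                               function(f) value_histogram(txk, f))
    situations[[ck]] <- lapply(
      stats::setNames(unique(fc), unique(fc)),
      function(cat) {
        mined <- mine_situations(txk, sigma_used, config$mode, config$max_len,
                                 features = names(fc)[fc == cat])
        top_situations(mined, "all", config$top_k)
      })
  }

  report <- structure(list(
    config = config, profiles = profiles, labels = labels,
    linkage = linkage, variability = variability, histograms = histograms,
    situations = situations, sigma = sigma_used,
    n_transactions = nrow(tx),
    drop_log = attr(cleaned, "drop_log"),
    n_input_runs = nrow(runs),
    users = users), class = "runsit_report")

  if (!is.null(out_dir)) persist_report(report, world, geo, bins, runs,
                                        tx, wm, linkage, out_dir)
  report
}

persist_report <- function(report, world, geo, bins, runs, tx, wm, linkage,
                           out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_runs(runs, p("runs.csv"))
  write_landuse_asc(world$landuse, p("landuse.asc"))
  write_neighborhoods_geojson(world$neighborhoods, p("neighborhoods.geojson"))
  for (cl in landuse_classes()) {
    write_raster_asc(geo$dist[[cl]], world$landuse, p(paste0("dist_", cl, ".asc")))
    write_raster_asc(geo$cov[[cl]], world$landuse, p(paste0("cov_", cl, ".asc")))
  }
  write_binning_scheme(bins, p("binning_scheme.json"))
  write_transactions(tx, p("transactions.csv"))
  write_weekly_matrix(wm, p("weekly_matrix.csv"))
  write_linkage(linkage, p("linkage.csv"))
  write.csv(data.frame(user_id = names(report$labels),
                       cluster = as.integer(report$labels)),
            p("labels.csv"), row.names = FALSE)
  write.csv(report$profiles, p("cluster_profiles.csv"), row.names = FALSE)
  for (ck in names(report$variability))
    write.csv(report$variability[[ck]],
              p(paste0("variability_cluster", ck, ".csv")), row.names = FALSE)
  jsonlite::write_json(report_summary_list(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

report_summary_list <- function(report) {
  list(seed = report$config$seed,
       sigma = report$sigma,
       n_input_runs = report$n_input_runs,
       n_transactions = report$n_transactions,
       drop_log = as.list(report$drop_log),
       profiles = report$profiles,
       situations = lapply(report$situations, function(cl)
         lapply(cl, function(s) list(positive = s$positive,
                                     negative = s$negative))))
}

#' @export
print.runsit_report <- function(x, ...) {
  cat("== runsit pipeline report (seed ", x$config$seed, ") ==\n", sep = "")
  cat(x$n_input_runs, " simulated runs -> ", x$n_transactions,
      " transactions (drops: ",
      paste(names(x$drop_log), x$drop_log, sep = "=", collapse = ", "),
      ")\n\n", sep = "")
  cat("Runner clusters:\n")
  print(x$profiles, row.names = FALSE)
  cat("\nMining threshold sigma = ", signif(x$sigma, 4), "\n", sep = "")
  less <- as.character(x$profiles$cluster[which.min(x$profiles$mean_annual_runs)])
  cat("\nTop temporal situations, less active cluster (", less, "):\n", sep = "")
  tops <- x$situations[[less]]$temporal
  if (nrow(tops$positive)) {
    cat("  above average:\n")
    print(head(tops$positive[, c("itemset", "support", "count")], 3),
          row.names = FALSE)
  }
  if (nrow(tops$negative)) {
    cat("  below average:\n")
    print(head(tops$negative[, c("itemset", "support", "count")], 3),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.runsit_report <- function(object, ...) {
  less <- as.character(object$profiles$cluster[
    which.min(object$profiles$mean_annual_runs)])
  more <- setdiff(names(object$variability), less)
  v_less <- object$variability[[less]]
  structure(list(profiles = object$profiles,
                 sigma = object$sigma,
                 top_variable_features =
                   head(v_less[order(-v_less$sd), ], 6),
                 less_active_cluster = less,
                 regular_cluster = more), class = "summary.runsit_report")
}

#' @export
print.summary.runsit_report <- function(x, ...) {
  print(x$profiles, row.names = FALSE)
  cat("\nMost distance-variable features (less active cluster):\n")
  print(x$top_variable_features, row.names = FALSE)
  invisible(x)
}
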