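# Synthetic world, runner population and run generator.

test_that("landscapes are deterministic, patchy and respect the class mix", {
  w1 <- make_landscape(1, 50, 50, class_mix = NULL)
  w2 <- make_landscape(1, 50, 50, class_mix = NULL)
  expect_identical(w1$landuse$classes, w2$landuse$classes)
  expect_identical(w1$neighborhoods$attributes, w2$neighborhoods$attributes)

  # uniform mix: all 9 classes present
  mix <- stats::setNames(rep(1 / 9, 9), landuse_classes())
  wu <- make_landscape(2, 50, 50, class_mix = mix)
  expect_setequal(unique(as.vector(wu$landuse$classes)), landuse_classes())

  # patches, not i.i.d. noise: neighbours agree far more often than chance
  m <- w1$landuse$classes
  agree <- mean(m[-1, ] == m[-nrow(m), ])
  expect_gt(agree, 0.5)

  # degenerate single-class mix
  wr <- make_landscape(3, 20, 20, class_mix = c(residential = 1))
  expect_true(all(wr$landuse$classes == "residential"))
  expect_true(all(distance_to_class(wr$landuse, "residential") == 0))

  expect_error(make_landscape(1, 20, 20, class_mix = c(moon = 1)), "class")
  expect_error(make_landscape(1, 5, 5), "10x10")
})

test_that("neighborhoods tile the extent and carry valid demographics", {
  w <- small_world()
  att <- w$neighborhoods$attributes
  expect_true(all(att$population_density >= 0))
  expect_true(all(att$pct_over_65 >= 0 & att$pct_over_65 <= 100))
  # every cell center is covered by exactly one (first-match) polygon
  geo <- small_context()$geo
  expect_false(anyNA(geo$nb_index))
})

test_that("runner populations match archetype fractions and annual rates", {
  u <- make_runners(7, 1000, c(sporadic = 0.8, regular = 0.2))
  expect_identical(u, make_runners(7, 1000, c(sporadic = 0.8, regular = 0.2)))
  tab <- table(u$archetype)
  expect_equal(as.integer(tab["sporadic"]), 800, tolerance = 0.08)
  expect_equal(as.integer(tab["regular"]), 200, tolerance = 0.15)

  # Monte-Carlo: sporadic mean annual count within [29, 39] at n = 500
  u2 <- make_runners(8, 500, c(sporadic = 1))
  expect_true(mean(u2$annual_rate) > 29 && mean(u2$annual_rate) < 39)
  # regular archetype within 15% of 94 at n >= 200
  u3 <- make_runners(9, 300, c(regular = 1))
  expect_lt(abs(mean(u3$annual_rate) - 94) / 94, 0.15)

  expect_true(all(make_runners(10, 50, c(regular = 1))$archetype == "regular"))
  expect_error(make_runners(1, 1), "2 users")
  expect_error(make_runners(1, 10, c(sporadic = 0.5)), "sum to 1")
})

test_that("sporadic weekly activity is concentrated, regular activity spread", {
  w <- small_world()
  u <- make_runners(11, 60)
  r <- suppressWarnings(
    simulate_runs(12, u, w, NULL, horizon_years = 2, abort_prob = 0,
                  missing_prob = 0))
  wm <- weekly_matrix(r)
  act_weeks <- rowSums(wm > 0)
  by_arch <- tapply(act_weeks[u$user_id], u$archetype, mean)
  expect_lt(by_arch["sporadic"], 25)   # runs inside an 18-week block
  expect_gt(by_arch["regular"], 40)    # spread over the year
})

test_that("run records are deterministic, in-horizon and well-formed", {
  w <- small_world()
  u <- make_runners(13, 20)
  r1 <- suppressWarnings(simulate_runs(14, u, w, default_effects()))
  r2 <- suppressWarnings(simulate_runs(14, u, w, default_effects()))
  expect_identical(r1, r2)

  ts <- as.POSIXct(r1$start_timestamp, tz = "UTC")
  span <- as.numeric(difftime(max(ts), min(ts), units = "days"))
  expect_lte(span, 4 * 365.25)
  expect_true(all(r1$total_distance_m >= 50))
  expect_true(all(r1$start_x >= 0 & r1$start_x <= 4000))
  expect_true(all(stats::na.omit(r1$weather_type) %in% weather_types()))

  expect_identical(nrow(simulate_runs(1, u[0, ], w)), 0L)
})

test_that("zero noise and no effects collapse distances onto user baselines", {
  w <- small_world()
  u <- make_runners(15, 10)
  r <- simulate_runs(16, u, w, NULL, horizon_years = 1, noise_sd = 0,
                     abort_prob = 0, missing_prob = 0)
  per_user <- tapply(r$total_distance_m, r$user_id, function(v) diff(range(v)))
  expect_true(all(per_user == 0))
  expect_true(all(normalize_distance(r) == 0))
})

test_that("a planted Sunday effect shifts Sunday distances by its delta", {
  w <- small_world()
  specs <- default_archetypes(sporadic_sensitivity = 1, regular_sensitivity = 1)
  u <- make_runners(17, 60, specs = specs)
  eff <- effect_spec(situation_effect(800, weekday = "Sunday"))
  r <- simulate_runs(18, u, w, eff, horizon_years = 2, noise_sd = 300,
                     abort_prob = 0, missing_prob = 0)
  expect_gt(nrow(r), 2000)
  wd <- weekday_names()[as.integer(format(as.POSIXct(r$start_timestamp,
                                                     tz = "UTC"), "%u"))]
  # within-user contrast, averaged across users (baselines cancel)
  contrast <- tapply(seq_len(nrow(r)), r$user_id, function(i) {
    s <- wd[i] == "Sunday"
    if (!any(s) || all(s)) return(NA_real_)
    mean(r$total_distance_m[i][s]) - mean(r$total_distance_m[i][!s])
  })
  expect_equal(mean(contrast, na.rm = TRUE), 800, tolerance = 0.1)
})

test_that("effects on unknown features or categories are rejected", {
  expect_error(situation_effect(500, dist_parks = "0"), "temporal/weather")
  expect_error(situation_effect(500, weekday = "Funday"), "not a valid category")
  expect_error(situation_effect(Inf, weekday = "Sunday"), "finite")
})

test_that("start locations favour residential surroundings", {
  w <- small_world()
  u <- make_runners(19, 60)
  r <- suppressWarnings(simulate_runs(20, u, w, NULL, horizon_years = 1))
  cell <- runsit:::cell_of_xy(w$landuse, r$start_x, r$start_y)
  frac_res_starts <- mean(w$landuse$classes[cell] == "residential")
  frac_res_cells <- mean(w$landuse$classes == "residential")
  expect_gt(frac_res_starts, 1.5 * frac_res_cells)
})
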