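# Cleaning, per-user normalization, feature extraction, weekly matrix.

test_that("cleaning drops short, malformed and context-less runs, idempotently", {
  ctx <- small_context()
  recs <- rbind(make_record(distance = 50, id = "short"),
                make_record(distance = 100, id = "boundary"),
                make_record(distance = 5000, weather = NA, id = "noweather"),
                make_record(distance = 5000, ts = "not a date", id = "badts"),
                make_record(distance = 5000, x = -999, id = "offmap"),
                make_record(distance = 5000, id = "good"))
  out <- suppressMessages(clean_runs(recs, ctx$geo))
  expect_setequal(out$activity_id, c("boundary", "good"))
  log <- attr(out, "drop_log")
  expect_equal(sum(log), 4L)
  expect_equal(nrow(recs), nrow(out) + sum(log))   # drop accounting
  expect_equal(unname(log[c("short_distance", "missing_field",
                            "bad_timestamp", "missing_context")]),
               rep(1L, 4))
  # idempotence
  again <- clean_runs(out, ctx$geo)
  expect_equal(as.data.frame(again), as.data.frame(out), ignore_attr = TRUE)
  expect_equal(sum(attr(again, "drop_log")), 0L)
})

test_that("sparse users are removed with their runs at the 10-run boundary", {
  nine <- do.call(rbind, lapply(1:9, function(i)
    make_record(user = "U9", id = paste0("a", i))))
  ten <- do.call(rbind, lapply(1:10, function(i)
    make_record(user = "U10", id = paste0("b", i))))
  out <- filter_sparse_users(rbind(nine, ten))
  expect_setequal(unique(out$user_id), "U10")
  expect_equal(nrow(out), 10L)
  expect_equal(nrow(filter_sparse_users(nine[0, ])), 0L)
})

test_that("distance normalization follows the per-user min/mean/max scaling", {
  recs <- do.call(rbind, lapply(seq_along(c(2000, 5000, 8000)), function(i)
    make_record(distance = c(2000, 5000, 8000)[i], id = paste0("r", i))))
  w <- normalize_distance(recs)
  expect_equal(w, c(-0.5, 0, 0.5))           # (8000-5000)/(8000-2000) = 0.5
  # run at the user mean is exactly 0; all identical runs give 0
  same <- rbind(make_record(distance = 4000, id = "s1"),
                make_record(distance = 4000, id = "s2"))
  expect_equal(normalize_distance(same), c(0, 0))
  # property: bounds and zero-sum per user on random inputs
  set.seed(42)
  recs2 <- do.call(rbind, lapply(1:60, function(i)
    make_record(distance = round(runif(1, 100, 20000)),
                user = paste0("U", i %% 5), id = paste0("x", i))))
  w2 <- normalize_distance(recs2)
  expect_true(all(abs(w2) <= 1))
  sums <- tapply(w2, recs2$user_id, sum)
  expect_equal(max(abs(sums)), 0, tolerance = 1e-9)
})

test_that("feature extraction reproduces the reference record and emits 29 items", {
  ctx <- small_context()
  rec <- make_record()   # 2016-05-05 10:31:18, 11 C, cloudy, light wind
  v <- extract_features(rec, ctx$geo, ctx$bins)
  expect_length(v, 29)
  expect_equal(names(v), situation_features())
  expect_equal(unname(v["hour"]), "[9,12)")
  expect_equal(unname(v["weekday"]), "Thursday")
  expect_equal(unname(v["month"]), "May")
  expect_equal(unname(v["temperature"]), "(6,14]")
  expect_equal(unname(v["weather"]), "cloudy")
  expect_equal(unname(v["wind"]), "light wind")
  expect_equal(unname(v["humidity"]), "middle humidity")
  # hour discretization has 8 bins; temperature 5
  expect_length(ctx$bins$hour$labels, 8)
  expect_length(ctx$bins$temperature$labels, 5)
  # extreme cold clamps into the lowest bin with a warning
  cold <- make_record(temp = -25)
  expect_warning(vc <- extract_features(cold, ctx$geo, ctx$bins), "clamped")
  expect_equal(unname(vc["temperature"]), "[-10,-2]")
  # unknown categorical value rejects the record
  expect_error(extract_features(make_record(weather = "plasma storm"),
                                ctx$geo, ctx$bins), "unknown weather")
})

test_that("transactions have one item per feature and conserve counts", {
  ctx <- small_context()
  u <- make_runners(21, 30)
  r <- simulate_runs(22, u, ctx$world, NULL, horizon_years = 2,
                     abort_prob = 0, missing_prob = 0)
  fl <- filter_sparse_users(clean_runs(r, ctx$geo))
  tx <- build_transactions(fl, ctx$geo, ctx$bins)
  expect_equal(ncol(tx), 3 + 29)
  expect_true(all(abs(tx$weight) <= 1))
  # conservation: per feature, category counts sum to the transaction count
  for (f in c("hour", "weekday", "dist_parks", "population_density")) {
    expect_false(anyNA(tx[[f]]))
    expect_equal(sum(table(tx[[f]])), nrow(tx))
  }
})

test_that("weekly matrices select the most active 52-week window", {
  # all runs in one ISO week
  one <- do.call(rbind, lapply(1:5, function(i)
    make_record(ts = sprintf("2016-03-0%d 10:00:00", i), id = paste0("w", i))))
  m1 <- weekly_matrix(one)
  expect_equal(ncol(m1), 52L)
  expect_equal(sum(m1), 5)
  expect_equal(sum(m1 > 0), 1)

  # two equal-total windows: the earlier one is selected
  two <- rbind(make_record(ts = "2014-01-06 10:00:00", id = "t1"),
               make_record(ts = "2016-06-06 10:00:00", id = "t2"))
  m2 <- weekly_matrix(two)
  expect_equal(attr(m2, "window_start"), 1L)
  expect_equal(as.integer(m2[1, 1]), 1L)   # earliest run opens the chosen window

  # row sums never exceed the user's total retained runs
  ctx <- small_context()
  u <- make_runners(23, 25)
  r <- simulate_runs(24, u, ctx$world, NULL, abort_prob = 0, missing_prob = 0)
  fl <- filter_sparse_users(clean_runs(r))
  wm <- weekly_matrix(fl)
  totals <- table(fl$user_id)
  expect_true(all(rowSums(wm) <= as.integer(totals[rownames(wm)])))
})

test_that("run tables, transactions and weekly matrices round-trip through CSV", {
  ctx <- small_context()
  u <- make_runners(25, 12)
  r <- suppressWarnings(simulate_runs(26, u, ctx$world, NULL, horizon_years = 1))
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "runs.csv")
  write_runs(r, f)
  r2 <- read_runs(f)
  expect_equal(as.data.frame(r2), as.data.frame(r))

  fl <- filter_sparse_users(clean_runs(r, ctx$geo))
  tx <- build_transactions(fl, ctx$geo, ctx$bins)
  ft <- file.path(tmp, "tx.csv")
  write_transactions(tx, ft)
  expect_equal(as.data.frame(read_transactions(ft)), as.data.frame(tx),
               ignore_attr = TRUE)

  wm <- weekly_matrix(fl)
  fw <- file.path(tmp, "wm.csv")
  write_weekly_matrix(wm, fw)
  wm2 <- read_weekly_matrix(fw)
  expect_equal(unclass(wm2), unclass(wm)[, , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(rownames(wm2), rownames(wm))

  fa <- file.path(tmp, "landuse.asc")
  write_landuse_asc(ctx$world$landuse, fa)
  lu2 <- read_landuse_asc(fa)
  expect_equal(lu2$classes, ctx$world$landuse$classes)

  fg <- file.path(tmp, "nb.geojson")
  write_neighborhoods_geojson(ctx$world$neighborhoods, fg)
  nb2 <- read_neighborhoods_geojson(fg)
  expect_equal(nb2$attributes, ctx$world$neighborhoods$attributes)
  expect_equal(nb2$polygons[[3]][, 1],
               ctx$world$neighborhoods$polygons[[3]][, 1], ignore_attr = TRUE)

  fb <- file.path(tmp, "bins.json")
  write_binning_scheme(ctx$bins, fb)
  b2 <- read_binning_scheme(fb)
  expect_equal(b2$dist_parks$edges, ctx$bins$dist_parks$edges)
  expect_equal(b2$hour$labels, ctx$bins$hour$labels)
})
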