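# Independent reference implementations and fixture builders used as oracles.
# These deliberately share no code with the package internals.

# -- DTW ---------------------------------------------------------------------

# full-matrix DTW dynamic program (pure R)
ref_dtw <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n))
    for (j in seq_len(m))
      D[i + 1, j + 1] <- abs(a[i] - b[j]) +
        min(D[i, j + 1], D[i + 1, j], D[i, j])
  D[n + 1, m + 1]
}

# exhaustive enumeration of all warping paths (tiny sequences only)
enum_dtw <- function(a, b) {
  n <- length(a); m <- length(b)
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == n && j == m) return(c0)
    best <- Inf
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    c0 + best
  }
  rec(1, 1)
}

# -- rasters -----------------------------------------------------------------

# O(cells^2) nearest-class-cell scan
brute_distance <- function(classes, class, cell_size) {
  nr <- nrow(classes); nc <- ncol(classes)
  tgt <- which(classes == class, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr))
    for (c in seq_len(nc))
      out[r, c] <- cell_size *
        sqrt(min((r - tgt[, 1])^2 + (c - tgt[, 2])^2))
  out
}

# direct window counting with the [i-5, i+4] convention
brute_coverage <- function(classes, class, r, c, window = 10) {
  nr <- nrow(classes); nc <- ncol(classes)
  rows <- max(r - floor(window / 2), 1):min(r + ceiling(window / 2) - 1, nr)
  cols <- max(c - floor(window / 2), 1):min(c + ceiling(window / 2) - 1, nc)
  100 * sum(classes[rows, cols] == class) / (length(rows) * length(cols))
}

# -- miner -------------------------------------------------------------------

# wrap a plain data.frame of item columns + weight into a transaction table
as_tx <- function(df, levels = NULL) {
  structure(df, class = c("wtransactions", "data.frame"), levels = levels)
}

# random small weighted transaction instance over abstract features f1..fk
random_tx <- function(seed, n_trans = 120, n_feat = 4, n_val = 4) {
  set.seed(seed)
  df <- data.frame(tid = seq_len(n_trans),
                   weight = round(runif(n_trans, -1, 1), 3))
  for (f in paste0("f", seq_len(n_feat)))
    df[[f]] <- sample(paste0("v", seq_len(n_val)), n_trans, replace = TRUE)
  as_tx(df)
}

# brute-force weighted frequent itemset enumeration over the surviving items
brute_mine <- function(tx, sigma, max_len = Inf, features = NULL) {
  hdr <- build_header(tx, sigma, features)
  items <- hdr$item
  res <- list()
  if (length(items)) {
    for (k in seq_len(min(length(items), max_len))) {
      for (comb in utils::combn(items, k, simplify = FALSE)) {
        feats <- sub("=.*$", "", comb)
        if (anyDuplicated(feats)) next      # one item per feature possible only
        s <- weighted_support(comb, tx)
        if (abs(s$weight) >= sigma)
          res[[length(res) + 1]] <- data.frame(
            itemset = paste(sort(comb), collapse = " + "),
            support = s$weight, count = s$count)
      }
    }
  }
  if (!length(res)) return(data.frame(itemset = character(),
                                      support = numeric(), count = integer()))
  out <- do.call(rbind, res)
  out[order(out$itemset), , drop = FALSE]
}

# compare mined itemsets with the brute-force reference
expect_same_itemsets <- function(mined, ref) {
  m <- mined[order(mined$itemset), c("itemset", "support", "count")]
  rownames(m) <- rownames(ref) <- NULL
  expect_equal(m$itemset, ref$itemset)
  expect_equal(m$support, ref$support, tolerance = 1e-12)
  expect_equal(m$count, ref$count)
}

# -- shared small fixtures ---------------------------------------------------

small_world <- function(seed = 1, n = 40) make_landscape(seed, n, n)

# a tiny enriched pipeline context, memoised per test run
small_context <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      world <- small_world()
      geo <- build_geo_context(world$landuse, world$neighborhoods)
      bins <- national_quantile_bins(geo)
      cache <<- list(world = world, geo = geo, bins = bins)
    }
    cache
  }
})

# manual run-record rows for unit tests
make_record <- function(distance = 5000, ts = "2016-05-05 10:31:18",
                        x = 150, y = 150, weather = "cloudy", temp = 11,
                        wind = "light wind", humidity = "middle humidity",
                        user = "U1", id = "A1") {
  structure(data.frame(activity_id = id, user_id = user,
                       total_distance_m = distance, start_timestamp = ts,
                       start_x = x, start_y = y, weather_type = weather,
                       temperature_c = temp, wind_type = wind,
                       humidity_type = humidity, stringsAsFactors = FALSE),
            class = c("run_records", "data.frame"))
}
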