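# Weighted supports, FP-tree, mining modes, variability, histograms.

test_that("weighted support sums signed weights over containing transactions", {
  tx <- as_tx(data.frame(tid = 1:2, weight = c(0.5, -0.2),
                         f1 = c("A", "A"), f2 = c("B", "x"),
                         stringsAsFactors = FALSE))
  expect_equal(weighted_support(c(f1 = "A"), tx),
               list(weight = 0.3, count = 2L))
  expect_equal(weighted_support(c(f1 = "A", f2 = "B"), tx),
               list(weight = 0.5, count = 1L))
  expect_equal(weighted_support(c(f1 = "Z"), tx)$count, 0L)
  expect_equal(weighted_support(character(0), tx),
               list(weight = 0.3, count = 2L))   # empty set: totals
  # "feature=value" string form is equivalent
  expect_equal(weighted_support("f2=B", tx)$weight, 0.5)
})

test_that("the header keeps |w| >= sigma items sorted by descending |w|", {
  tx <- as_tx(data.frame(
    tid = 1:4, weight = c(0.9, -0.5, 0.1, 0),
    f1 = c("a", "b", "c", "d"), stringsAsFactors = FALSE))
  h <- build_header(tx, 0.3, features = "f1")
  expect_equal(h$item, c("f1=a", "f1=b"))
  expect_equal(h$weight, c(0.9, -0.5))
  expect_equal(attr(h, "pruned")$item, c("f1=c", "f1=d"))
  # item occurring only in weight-0 transactions is pruned at any sigma > 0
  expect_true("f1=d" %in% attr(h, "pruned")$item)
  expect_equal(nrow(build_header(tx, 10, features = "f1")), 0L)
  expect_error(build_header(tx, 0), "sigma")
})

test_that("FP-tree node weights reconstruct every item's weighted support", {
  for (s in 1:5) {
    tx <- random_tx(s, n_trans = 80)
    tree <- build_wfptree(tx, 0.4, features = paste0("f", 1:4))
    hdr <- tree$header
    for (r in seq_len(nrow(hdr))) {
      nodes <- tree$header_nodes[[r]]
      expect_equal(sum(tree$weight[nodes]), hdr$weight[r], tolerance = 1e-12)
      expect_equal(sum(tree$count[nodes]), hdr$count[r])
    }
    expect_equal(tree$item[1], 0L)       # root carries no item
  }
})

test_that("exhaustive mining equals brute-force subset enumeration", {
  for (s in 1:25) {
    tx <- random_tx(s, n_trans = sample(40:200, 1),
                    n_feat = sample(3:5, 1), n_val = 3)
    sigma <- runif(1, 0.5, 3)
    got <- mine_situations(tx, sigma, "exhaustive", max_len = Inf,
                           features = grep("^f", names(tx), value = TRUE))
    ref <- brute_mine(tx, sigma, features = grep("^f", names(tx), value = TRUE))
    expect_same_itemsets(got, ref)
  }
  # max_len cap restricts sizes but not values
  tx <- random_tx(99, n_trans = 150, n_feat = 5)
  got2 <- mine_situations(tx, 0.8, max_len = 2,
                          features = paste0("f", 1:5))
  ref2 <- brute_mine(tx, 0.8, max_len = 2, features = paste0("f", 1:5))
  expect_same_itemsets(got2, ref2)
  expect_true(all(got2$n_items <= 2))
})

test_that("signed weights surface positive and negative situations", {
  # morning-Sunday-like planted contrast: positive weights co-occur with
  # (p1, p2); negative with (n1)
  set.seed(31)
  n <- 200
  pos <- seq_len(n) <= 60
  neg <- seq_len(n) > 160
  tx <- as_tx(data.frame(
    tid = seq_len(n),
    weight = ifelse(pos, 0.6, ifelse(neg, -0.5, 0)),
    f1 = ifelse(pos, "p1", ifelse(neg, "n1", sample(c("x", "y"), n, TRUE))),
    f2 = ifelse(pos, "p2", sample(c("p2", "z"), n, TRUE)),
    stringsAsFactors = FALSE))
  out <- mine_situations(tx, 5, features = c("f1", "f2"))
  expect_gt(out$support[1], 0)
  expect_true(grepl("f1=p1", out$itemset[1]))      # the planted set or a superset
  pair <- out[out$itemset == "f1=p1 + f2=p2", ]
  expect_equal(pair$support, 60 * 0.6, tolerance = 1e-12)
  expect_equal(pair$count, 60L)
  negset <- out[out$sign < 0, ]
  expect_true(any(grepl("f1=n1", negset$itemset)))
  expect_equal(min(negset$support), -0.5 * 40, tolerance = 1e-12)
  expect_equal(mine_situations(tx, 1e6, features = c("f1", "f2")) |> nrow(), 0L)
})

test_that("pruned-mode output is a subset of exhaustive output", {
  for (s in 1:10) {
    tx <- random_tx(100 + s, n_trans = 150, n_feat = 4)
    sigma <- runif(1, 0.5, 2)
    ex <- mine_situations(tx, sigma, "exhaustive", max_len = Inf,
                          features = paste0("f", 1:4))
    pr <- mine_situations(tx, sigma, "pruned", max_len = Inf,
                          features = paste0("f", 1:4))
    expect_true(all(pr$itemset %in% ex$itemset))
    # values of reported sets agree with direct recomputation
    for (i in seq_len(min(nrow(pr), 5))) {
      s2 <- weighted_support(strsplit(pr$itemset[i], " + ", fixed = TRUE)[[1]],
                             tx)
      expect_equal(pr$support[i], s2$weight, tolerance = 1e-12)
      expect_equal(pr$count[i], s2$count)
    }
  }
})

test_that("per-feature variability is the population sd of value supports", {
  tx <- as_tx(data.frame(
    tid = 1:6, weight = c(0.3, 0.3, 0.0, 0.0, -0.3, -0.3),
    f1 = c("a", "a", "b", "b", "c", "c"),
    f2 = rep("k", 6), stringsAsFactors = FALSE))
  fv <- feature_variability(tx, features = c("f1", "f2"))
  expect_equal(fv$sd[fv$feature == "f1"], sqrt(0.24), tolerance = 1e-12)
  expect_equal(fv$sd[fv$feature == "f2"], 0)
  expect_equal(fv$n_categories, c(3L, 1L))
  # all-zero weights: every feature's variability is 0
  tx0 <- as_tx(data.frame(tid = 1:4, weight = 0,
                          f1 = c("a", "b", "a", "b"),
                          stringsAsFactors = FALSE))
  expect_equal(feature_variability(tx0, "f1")$sd, 0)
})

test_that("value histograms conserve counts and total weight", {
  lev <- list(weekday = weekday_names())
  tx <- as_tx(data.frame(tid = 1, weight = 0.4, weekday = "Sunday",
                         stringsAsFactors = FALSE), levels = lev)
  h <- value_histogram(tx, "weekday")
  expect_equal(nrow(h), 7)
  expect_equal(h$count[h$value == "Sunday"], 1L)
  expect_equal(h$support[h$value == "Sunday"], 0.4)
  expect_true(all(h$count[h$value != "Sunday"] == 0))
  expect_true(all(h$support[h$value != "Sunday"] == 0))

  tx2 <- random_tx(55, n_trans = 150)
  h2 <- value_histogram(tx2, "f1")
  expect_equal(sum(h2$count), 150)
  expect_equal(sum(h2$support), sum(tx2$weight), tolerance = 1e-12)
  expect_error(value_histogram(tx2, "nope"), "unknown feature")

  # conservation at single-item level: supports per feature sum to total weight
  fv <- feature_variability(tx2, paste0("f", 1:4))
  sup <- attr(fv, "supports")
  for (f in names(sup))
    expect_equal(sum(sup[[f]]), sum(tx2$weight), tolerance = 1e-9)
})

test_that("top situations filter by feature category and rank by |support|", {
  sets <- structure(data.frame(
    itemset = c("weekday=Sunday + hour=[9,12)", "weekday=Sunday",
                "hour=[18,21) + temperature=(6,14]", "month=May",
                "dist_parks=0 + cov_forest=0"),
    n_items = c(2L, 1L, 2L, 1L, 2L),
    support = c(40, 25, -30, -10, 15),
    count = c(100L, 200L, 80L, 50L, 60L),
    sign = c(1, 1, -1, -1, 1), stringsAsFactors = FALSE),
    class = c("wfim_itemsets", "data.frame"))
  t1 <- top_situations(sets, "temporal", k = 5)
  expect_equal(t1$positive$itemset,
               c("weekday=Sunday + hour=[9,12)", "weekday=Sunday"))
  expect_equal(t1$negative$itemset, "month=May")   # mixed-category set excluded
  expect_equal(nrow(top_situations(sets, "temporal", k = 0)$positive), 0L)
  expect_equal(top_situations(sets, "topographical", 5)$positive$itemset,
               "dist_parks=0 + cov_forest=0")
  expect_equal(nrow(top_situations(sets, "all", 1)$positive), 1L)
})
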