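#' Weighted support of an itemset
#'
#' The weighted support of an itemset X is the sum of the weights (normalized
#' distances) of all transactions containing every item of X; its sign says
#' whether the situation is associated with above- (positive) or below-
#' average (negative) running distance. The empty itemset has the total
#' weight and total count.
#'
#' @param itemset either a named character vector
#'   (\code{c(weekday = "Sunday")}) or a character vector of
#'   \code{"feature=value"} strings; empty for the totals.
#' @param transactions a \code{wtransactions} data.frame.
#' @return List with \code{weight} and \code{count}.
#' @export
weighted_support <- function(itemset, transactions) {
  it <- parse_itemset(itemset)
  m <- rep(TRUE, nrow(transactions))
  for (f in names(it)) {
    col <- transactions[[f]]
    if (is.null(col)) return(list(weight = 0, count = 0L))
    m <- m & !is.na(col) & col == it[[f]]
  }
  list(weight = sum(transactions$weight[m]), count = sum(m))
}

parse_itemset <- function(itemset) {
  if (!length(itemset)) return(character(0))
  if (is.null(names(itemset)) || any(names(itemset) == "")) {
    sp <- regmatches(itemset, regexpr("=", itemset), invert = TRUE)
    out <- vapply(sp, `[`, "", 2)
    names(out) <- vapply(sp, `[`, "", 1)
    out
  } else itemset
}

item_key <- function(feature, value) paste0(feature, "=", value)

#' Header table of surviving items
#'
#' Single-item weighted supports over the transaction set, restricted to
#' items with \code{|w(i)| >= sigma} and ordered by descending \code{|w|}
#' (ties by item name) — the insertion order of the weighted FP-tree.
#'
#' @param transactions a \code{wtransactions}.
#' @param sigma absolute weighted-support threshold (> 0).
#' @param features optional subset of features to restrict mining to (the
#'   per-category mining mode); default all feature columns present.
#' @return Data.frame (class \code{wfim_header}) with columns \code{item},
#'   \code{feature}, \code{value}, \code{weight}, \code{count}; pruned items
#'   are kept in the \code{"pruned"} attribute.
#' @export
build_header <- function(transactions, sigma, features = NULL) {
  if (sigma <= 0) stop("sigma must be > 0")
  features <- features %||% intersect(situation_features(), names(transactions))
  w <- transactions$weight
  rows <- list()
  for (f in features) {
    col <- transactions[[f]]
    ws <- tapply(w, col, sum)
    cs <- tapply(rep(1L, length(col)), col, sum)
    rows[[f]] <- data.frame(item = item_key(f, names(ws)), feature = f,
                            value = names(ws), weight = as.numeric(ws),
                            count = as.integer(cs), stringsAsFactors = FALSE)
  }
  all_items <- do.call(rbind, rows)
  rownames(all_items) <- NULL
  keep <- abs(all_items$weight) >= sigma
  hdr <- all_items[keep, , drop = FALSE]
  hdr <- hdr[order(-abs(hdr$weight), hdr$item), , drop = FALSE]
  rownames(hdr) <- NULL
  structure(hdr, class = c("wfim_header", "data.frame"),
            pruned = all_items[!keep, , drop = FALSE], sigma = sigma,
            features = features)
}

# encode transactions against a header: unique rank sequences with
# aggregated weight and count (transactions sharing an item sequence follow
# the same FP-tree path, so aggregation before insertion is exact)
encode_transactions <- function(transactions, header) {
  features <- attr(header, "features")
  n <- nrow(transactions)
  if (!nrow(header) || !n)
    return(list(paths = list(), w = numeric(0), c = integer(0)))
  rk <- matrix(NA_integer_, n, length(features))
  for (j in seq_along(features)) {
    f <- features[j]
    rk[, j] <- match(item_key(f, transactions[[f]]), header$item)
  }
  paths <- apply(rk, 1, function(r) sort(r[!is.na(r)]), simplify = FALSE)
  keys <- vapply(paths, paste, "", collapse = ",")
  grp <- match(keys, unique(keys))
  w <- as.numeric(rowsum(transactions$weight, grp))
  cnt <- as.integer(rowsum(rep(1L, n), grp))
  first <- which(!duplicated(grp))
  list(paths = paths[first], w = w, c = cnt)
}

#' Build the weighted FP-tree
#'
#' Compresses the transactions into a prefix tree whose nodes accumulate the
#' summed signed weight and the count of all transactions routed through
#' them; items are inserted in header order (descending \code{|w|}). For any
#' item, the weights of its nodes sum to the item's weighted support over
#' the transactions that contain it.
#'
#' @inheritParams build_header
#' @return An object of class \code{wfp_tree}: parallel node vectors
#'   \code{item} (header rank; 0 for the root), \code{parent}, \code{weight},
#'   \code{count}, plus \code{header_nodes} (node ids per item rank) and the
#'   \code{header} table.
#' @export
build_wfptree <- function(transactions, sigma, features = NULL) {
  header <- build_header(transactions, sigma, features)
  enc <- encode_transactions(transactions, header)
  nit <- nrow(header)
  item <- 0L; parent <- 0L; weight <- 0; count <- 0L
  kids <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seq_along(enc$paths)) {
    cur <- 1L
    for (r in enc$paths[[s]]) {
      key <- paste0(cur, ".", r)
      nxt <- kids[[key]]
      if (is.null(nxt)) {
        item <- c(item, r); parent <- c(parent, cur)
        weight <- c(weight, 0); count <- c(count, 0L)
        nxt <- length(item)
        kids[[key]] <- nxt
      }
      weight[nxt] <- weight[nxt] + enc$w[s]
      count[nxt] <- count[nxt] + enc$c[s]
      cur <- nxt
    }
  }
  header_nodes <- lapply(seq_len(nit), function(r) which(item == r))
  structure(list(item = item, parent = parent, weight = weight,
                 count = count, header_nodes = header_nodes,
                 header = header, sigma = attr(header, "sigma")),
            class = "wfp_tree")
}

#' @export
print.wfp_tree <- function(x, ...) {
  cat("<wfp_tree> ", length(x$item) - 1, " nodes, ", nrow(x$header),
      " header items, sigma ", x$sigma, "\n", sep = "")
  invisible(x)
}

#' Mine weighted frequent itemsets
#'
#' Enumerates item combinations ("situations") whose absolute weighted
#' support reaches \code{sigma}, via the weighted FP-tree: for each header
#' item, its conditional pattern base (prefix paths with accumulated weight
#' and count) is extracted and mined recursively.
#'
#' Because weights are signed, \code{|w|} is not anti-monotone: an itemset
#' can clear the threshold while a subset does not. Two modes are provided:
#' \describe{
#'   \item{exhaustive (default)}{conditional bases are recursed without
#'     intermediate \code{|w|} pruning (only the zero-count and
#'     \code{max_len} bounds apply), so the output is exactly every
#'     \code{X} within the surviving items with \code{|w(X)| >= sigma} and
#'     \code{|X| <= max_len}.}
#'   \item{pruned}{items below \code{sigma} are also pruned inside
#'     conditional bases — the classic FP-growth heuristic; faster but
#'     possibly incomplete, always a subset of the exhaustive output.}
#' }
#'
#' @inheritParams build_header
#' @param mode "exhaustive" or "pruned".
#' @param max_len maximum itemset size (default 4; \code{Inf} for unlimited).
#' @return Data.frame of class \code{wfim_itemsets}, ordered by descending
#'   \code{|support|}: columns \code{itemset} (items joined by \code{" + "},
#'   alphabetical), \code{n_items}, \code{support}, \code{count},
#'   \code{sign}.
#' @export
mine_situations <- function(transactions, sigma, mode = c("exhaustive", "pruned"),
                            max_len = 4, features = NULL) {
  mode <- match.arg(mode)
  if (max_len < 1) stop("max_len must be >= 1")
  tree <- build_wfptree(transactions, sigma, features)
  header <- tree$header
  acc <- new.env(parent = emptyenv()); acc$res <- vector("list", 256); acc$k <- 0L

  emit <- function(ranks, w, cnt) {
    acc$k <- acc$k + 1L
    if (acc$k > length(acc$res)) acc$res <- c(acc$res, vector("list", length(acc$res)))
    acc$res[[acc$k]] <- list(ranks = ranks, w = w, c = cnt)
  }

  mine_base <- function(paths, ws, cs, suffix, depth) {
    if (!length(paths)) return()
    lens <- lengths(paths)
    pos <- lens > 0
    if (!any(pos)) return()
    it <- unlist(paths[pos], use.names = FALSE)
    idx <- rep(which(pos), lens[pos])
    w_it <- rowsum(ws[idx], it)
    c_it <- rowsum(cs[idx], it)
    ranks <- as.integer(rownames(w_it))
    if (mode == "pruned") {
      ok <- abs(w_it[, 1]) >= sigma
      if (!all(ok)) {
        drop <- ranks[!ok]
        paths <- lapply(paths, function(p) p[!p %in% drop])
        ranks <- ranks[ok]; w_it <- w_it[ok, , drop = FALSE]
        c_it <- c_it[ok, , drop = FALSE]
      }
    }
    for (k in seq_along(ranks)) {
      r <- ranks[k]
      if (abs(w_it[k, 1]) >= sigma) emit(c(r, suffix), w_it[k, 1], c_it[k, 1])
      if (depth < max_len) {
        sel <- vapply(paths, function(p) r %in% p, TRUE)
        if (any(sel)) {
          pre <- lapply(paths[sel], function(p) p[p < r])
          keys <- vapply(pre, paste, "", collapse = ",")
          grp <- match(keys, unique(keys))
          first <- which(!duplicated(grp))
          mine_base(pre[first],
                    as.numeric(rowsum(ws[sel], grp)),
                    as.integer(rowsum(cs[sel], grp)),
                    c(r, suffix), depth + 1L)
        }
      }
    }
  }

  # top-level pattern base straight from the tree: full root paths
  base <- tree_paths(tree)
  mine_base(base$paths, base$w, base$c, integer(0), 1L)

  res <- acc$res[seq_len(acc$k)]
  out <- data.frame(
    itemset = vapply(res, function(z)
      paste(sort(header$item[z$ranks]), collapse = " + "), ""),
    n_items = vapply(res, function(z) length(z$ranks), 1L),
    support = vapply(res, function(z) z$w, 1.0),
    count = vapply(res, function(z) as.integer(z$c), 1L),
    stringsAsFactors = FALSE)
  out$sign <- sign(out$support)
  out <- out[order(-abs(out$support), out$itemset), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("wfim_itemsets", "data.frame"),
            header = header, sigma = sigma, mode = mode, max_len = max_len)
}

# reconstruct the (deduplicated) root-to-leaf weighted paths of the tree:
# each node holds the weight/count of transactions *ending* there, which is
# node weight minus what flows on to its children
tree_paths <- function(tree) {
  nnode <- length(tree$item)
  if (nnode <= 1) return(list(paths = list(), w = numeric(0), c = integer(0)))
  child_w <- child_c <- rep(0, nnode)
  for (v in seq(2, nnode)) {
    p <- tree$parent[v]
    child_w[p] <- child_w[p] + tree$weight[v]
    child_c[p] <- child_c[p] + tree$count[v]
  }
  end_w <- tree$weight - child_w
  end_c <- tree$count - child_c
  keep <- which(seq_len(nnode) > 1 & end_c > 0)
  paths <- lapply(keep, function(v) {
    p <- integer(0)
    while (v > 1) { p <- c(tree$item[v], p); v <- tree$parent[v] }
    p
  })
  list(paths = paths, w = end_w[keep], c = as.integer(end_c[keep]))
}

#' @export
print.wfim_itemsets <- function(x, n = 10, ...) {
  cat("<wfim_itemsets> ", nrow(x), " itemsets (mode ", attr(x, "mode"),
      ", sigma ", signif(attr(x, "sigma"), 4), ", max_len ",
      attr(x, "max_len"), ")\n", sep = "")
  if (nrow(x)) print.data.frame(head(x, n))
  invisible(x)
}

#' Per-feature variability of weighted support
#'
#' For each feature, the single-item weighted supports over its observed
#' categories and their population standard deviation. A large value means
#' the feature's categories differ strongly in their association with
#' running distance.
#'
#' @param transactions a \code{wtransactions}.
#' @param features optional subset (default: all feature columns).
#' @return Data.frame with \code{feature}, \code{sd}, \code{n_categories};
#'   per-feature support vectors in the \code{"supports"} attribute.
#' @export
feature_variability <- function(transactions, features = NULL) {
  features <- features %||% intersect(situation_features(), names(transactions))
  w <- transactions$weight
  supports <- lapply(features, function(f) tapply(w, transactions[[f]], sum))
  names(supports) <- features
  sdp <- vapply(supports, function(s) sqrt(mean((s - mean(s))^2)), 1.0)
  structure(data.frame(feature = features, sd = as.numeric(sdp),
                       n_categories = lengths(supports),
                       stringsAsFactors = FALSE),
            supports = supports)
}

#' Value histogram of one feature
#'
#' Run frequency and weighted support per category of a feature, over the
#' feature's full category vocabulary (categories with no runs get 0, 0).
#' Counts sum to the number of transactions; supports sum to the total
#' weight.
#'
#' @param transactions a \code{wtransactions}.
#' @param feature one of the 29 feature names.
#' @return Data.frame with \code{value}, \code{count}, \code{support}.
#' @export
value_histogram <- function(transactions, feature) {
  if (!feature %in% names(transactions)) stop("unknown feature: ", feature)
  lev <- attr(transactions, "levels")[[feature]] %||%
    sort(unique(transactions[[feature]]))
  f <- factor(transactions[[feature]], levels = lev)
  cnt <- as.integer(table(f))
  sup <- tapply(transactions$weight, f, sum, default = 0)
  data.frame(value = lev, count = cnt, support = as.numeric(sup),
             stringsAsFactors = FALSE)
}

#' Top situations per feature category
#'
#' Filters mined itemsets to those whose features all belong to one feature
#' category (temporal, weather, topographical, demographical — or all), then
#' returns the top-k by \code{|support|}, split into positive- and
#' negative-support lists.
#'
#' @param itemsets a \code{wfim_itemsets} data.frame.
#' @param category_filter one of "temporal", "weather", "topographical",
#'   "demographical", "all".
#' @param k number of situations per list.
#' @return List with data.frames \code{positive} and \code{negative}.
#' @export
top_situations <- function(itemsets, category_filter = "all", k = 5) {
  category_filter <- match.arg(category_filter,
    c("temporal", "weather", "topographical", "demographical", "all"))
  fc <- feature_categories()
  in_cat <- function(set) {
    feats <- sub("=.*$", "", strsplit(set, " + ", fixed = TRUE)[[1]])
    all(fc[feats] == category_filter)
  }
  sel <- if (category_filter == "all") rep(TRUE, nrow(itemsets)) else
    vapply(itemsets$itemset, in_cat, TRUE, USE.NAMES = FALSE)
  sub <- itemsets
  class(sub) <- "data.frame"
  sub <- sub[sel, , drop = FALSE]
  pos <- sub[sub$support > 0, , drop = FALSE]
  neg <- sub[sub$support < 0, , drop = FALSE]
  pos <- head(pos[order(-pos$support), , drop = FALSE], k)
  neg <- head(neg[order(neg$support), , drop = FALSE], k)
  rownames(pos) <- rownames(neg) <- NULL
  list(positive = pos, negative = neg)
}

#' Monte-Carlo null calibration of the miner
#'
#' Estimates the magnitude of weighted supports and variability statistics
#' expected under "no situation effect", by permuting the transaction
#' weights (which breaks any situation-weight association while keeping both
#' margins). \code{null_item_support_sd} returns the per-item standard
#' deviation of single-item supports across permutations (and their
#' maximum); \code{null_variability} returns, per feature, the root mean
#' square of the variability statistic across permutations. A practical
#' mining threshold under the null is \code{sigma = 5 * max item sd}.
#'
#' @param transactions a \code{wtransactions}.
#' @param n_perm number of weight permutations.
#' @param seed RNG seed.
#' @param features optional feature subset.
#' @return See description.
#' @export
null_item_support_sd <- function(transactions, n_perm = 20, seed = 1,
                                 features = NULL) {
  features <- features %||% intersect(situation_features(), names(transactions))
  w <- transactions$weight
  with_seed(seed, {
    sims <- replicate(n_perm, {
      wp <- sample(w)
      unlist(lapply(features, function(f) tapply(wp, transactions[[f]], sum)))
    })
    per_item <- apply(sims, 1, sd)
    list(per_item = per_item, max = max(per_item))
  })
}

#' @rdname null_item_support_sd
#' @export
null_variability <- function(transactions, n_perm = 20, seed = 1,
                             features = NULL) {
  features <- features %||% intersect(situation_features(), names(transactions))
  w <- transactions$weight
  with_seed(seed, {
    sims <- replicate(n_perm, {
      tp <- transactions
      tp$weight <- sample(w)
      feature_variability(tp, features)$sd
    })
    data.frame(feature = features, null_rms = sqrt(rowMeans(sims^2)),
               stringsAsFactors = FALSE)
  })
}
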