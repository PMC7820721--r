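#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW between two numeric sequences with local
#' cost \eqn{|a_i - b_j|}, unit steps (match/insert/delete), anchored
#' endpoints and no warping window; returns the minimal cumulative cost.
#'
#' @param a,b non-empty numeric sequences.
#' @return The DTW distance (>= 0; 0 iff the aligned sequences coincide).
#' @examples
#' dtw_distance(c(1, 1, 2), c(1, 2))   # 0: indices warp onto each other
#' dtw_distance(c(0, 0), c(1, 1))      # 2
#' @export
dtw_distance <- function(a, b) {
  if (!length(a) || !length(b)) stop("sequences must be non-empty")
  dtw_cost_cpp(as.numeric(a), as.numeric(b))
}

#' Pairwise DTW distances between weekly activity sequences
#'
#' @param matrix a \code{weekly_activity} matrix (or any numeric matrix with
#'   one sequence per row; >= 2 rows).
#' @return Symmetric matrix of DTW distances with zero diagonal; rownames
#'   are carried over.
#' @export
pairwise_dtw <- function(matrix) {
  m <- unclass(matrix)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  d <- dtw_pairwise_cpp(m)
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Ward agglomerative linkage on a precomputed distance matrix
#'
#' Agglomerative clustering with the Ward variance-minimization criterion.
#' Initial inter-singleton distances are the input distances; after each
#' merge, distances are updated with the Lance-Williams Ward recurrence on
#' squared distances
#' \deqn{d(C_x,C_y)^2 = \frac{(n_i+n_y)\,d(C_i,C_y)^2 + (n_j+n_y)\,d(C_j,C_y)^2
#'   - n_y\, d(C_i,C_j)^2}{n_i+n_j+n_y}.}
#' At each step the globally closest active pair merges; exact ties are
#' broken by the smallest (a, b) pair of cluster indices (a cluster is
#' indexed by its smallest leaf). \code{update = "as_printed"} switches to a
#' variant without the subtracted term and with \eqn{n(C_x)+n(C_y)}
#' denominators throughout, kept for comparison; the default is the standard
#' recurrence (identical to \code{hclust(method = "ward.D2")}).
#'
#' Note the input distances here are DTW distances, which are not Euclidean;
#' Ward's variance interpretation is therefore heuristic on such input, but
#' the algorithm is well-defined and is applied regardless.
#'
#' @param dist symmetric non-negative distance matrix with zero diagonal (or
#'   a \code{dist} object).
#' @param update "standard" (default) or "as_printed".
#' @return An object of class \code{ward_linkage}: list with \code{merge}
#'   (hclust-style merge matrix), \code{height}, \code{size} (cluster size
#'   after each merge), \code{labels}, \code{update}.
#' @export
ward_linkage <- function(dist, update = c("standard", "as_printed")) {
  update <- match.arg(update)
  D <- if (inherits(dist, "dist")) as.matrix(dist) else as.matrix(dist)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 observations")
  if (any(D < 0) || max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0))
    stop("dist must be a symmetric non-negative matrix with zero diagonal")
  labels <- rownames(D) %||% as.character(seq_len(n))

  D2 <- D^2
  diag(D2) <- Inf
  size <- rep(1L, n)
  minleaf <- seq_len(n)              # tie-break identity of each cluster
  id <- -seq_len(n)                  # hclust convention: negatives = leaves
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  size_after <- integer(n - 1)

  for (step in seq_len(n - 1)) {
    act <- which(active)
    sub <- D2[act, act, drop = FALSE]
    best <- min(sub)
    # candidate pairs at the minimum; break ties on smallest (minleaf_a, minleaf_b)
    w <- which(sub - best <= best * 1e-14, arr.ind = TRUE)
    w <- w[w[, 1] < w[, 2], , drop = FALSE]
    pa <- act[w[, 1]]; pb <- act[w[, 2]]
    a_leaf <- pmin(minleaf[pa], minleaf[pb])
    b_leaf <- pmax(minleaf[pa], minleaf[pb])
    pick <- order(a_leaf, b_leaf)[1]
    i <- pa[pick]; j <- pb[pick]

    height[step] <- sqrt(D2[i, j])
    merge[step, ] <- sort_merge_pair(id[i], id[j])
    size_after[step] <- size[i] + size[j]

    oth <- act[!(act %in% c(i, j))]
    if (length(oth)) {
      ni <- size[i]; nj <- size[j]; ny <- size[oth]
      if (update == "standard") {
        newd <- ((ni + ny) * D2[i, oth] + (nj + ny) * D2[j, oth] -
                   ny * D2[i, j]) / (ni + nj + ny)
      } else {
        nx <- ni + nj
        newd <- ((ni + ny) * D2[i, oth] + (nj + ny) * D2[j, oth] +
                   ny * D2[i, j]) / (nx + ny)
      }
      D2[i, oth] <- newd; D2[oth, i] <- newd
    }
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- step
    active[j] <- FALSE
    D2[j, ] <- Inf; D2[, j] <- Inf
  }
  structure(list(merge = merge, height = height, size = size_after,
                 labels = labels, update = update),
            class = "ward_linkage")
}

# hclust orders a merge row: leaves (negative) before clusters, then ascending
sort_merge_pair <- function(a, b) {
  if ((a < 0 && b < 0 && a > b) || (a > 0 && b > 0 && a > b) || (a > 0 && b < 0))
    c(b, a) else c(a, b)
}

#' @export
print.ward_linkage <- function(x, ...) {
  n <- length(x$height) + 1
  cat("<ward_linkage> ", n, " leaves, ", length(x$height), " merges (",
      x$update, " update); root height ", signif(max(x$height), 6), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.hclust.ward_linkage <- function(x, ...) {
  h <- list(merge = x$merge, height = x$height,
            order = dendrogram_order(x$merge),
            labels = x$labels, method = "ward_linkage",
            call = match.call(), dist.method = "dtw")
  class(h) <- "hclust"
  h
}

#' @export
plot.ward_linkage <- function(x, ...) plot(as.hclust(x), ...)

dendrogram_order <- function(merge) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  walk(nrow(merge))
}

#' Cut a dendrogram at a height threshold
#'
#' Clusters are the connected components obtained after discarding all merges
#' with height strictly above \code{threshold}. Cutting above the root gives
#' one cluster; below the first merge, all singletons.
#'
#' @param linkage a \code{ward_linkage}.
#' @param threshold height threshold (>= 0).
#' @return Integer cluster labels (1-based, numbered by first appearance in
#'   leaf order), named by the leaf labels.
#' @export
cut_dendrogram <- function(linkage, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  n <- length(linkage$height) + 1
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  node_rep <- integer(n - 1)        # representative leaf of each merged node
  for (k in seq_len(n - 1)) {
    a <- linkage$merge[k, 1]; b <- linkage$merge[k, 2]
    ra <- if (a < 0) -a else node_rep[a]
    rb <- if (b < 0) -b else node_rep[b]
    if (linkage$height[k] <= threshold) {
      ra <- find(ra); rb <- find(rb)
      parent[rb] <- ra
    }
    node_rep[k] <- ra
  }
  roots <- vapply(seq_len(n), find, 1L)
  lab <- match(roots, unique(roots))
  names(lab) <- linkage$labels
  lab
}

#' Cut a dendrogram into k clusters
#'
#' Convenience wrapper deriving the threshold that yields exactly \code{k}
#' clusters: the midpoint between the (n-k)-th and (n-k+1)-th merge heights.
#'
#' @param linkage a \code{ward_linkage}.
#' @param k number of clusters.
#' @return As \code{\link{cut_dendrogram}}.
#' @export
cut_k <- function(linkage, k) {
  n <- length(linkage$height) + 1
  if (k < 1 || k > n) stop("k must be in [1, n]")
  h <- sort(linkage$height)
  thr <- if (k == 1) h[n - 1]
         else (c(0, h)[n - k + 1] + h[n - k + 1]) / 2
  cut_dendrogram(linkage, thr)
}

#' Profile runner clusters
#'
#' @param labels integer cluster labels aligned with the rows of
#'   \code{matrix}.
#' @param matrix a \code{weekly_activity} matrix.
#' @return Data.frame with one row per cluster: \code{cluster}, \code{n},
#'   \code{mean_annual_runs} (mean row sum); the per-cluster mean weekly
#'   sequences are attached as the \code{"mean_sequence"} attribute.
#' @export
cluster_profile <- function(labels, matrix) {
  stopifnot(length(labels) == nrow(matrix))
  rs <- rowSums(matrix)
  cl <- sort(unique(labels))
  prof <- data.frame(
    cluster = cl,
    n = as.integer(table(factor(labels, cl))),
    mean_annual_runs = as.numeric(tapply(rs, factor(labels, cl), mean)))
  seqs <- t(vapply(cl, function(k) colMeans(matrix[labels == k, , drop = FALSE]),
                   numeric(ncol(matrix))))
  structure(prof, mean_sequence = seqs)
}
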