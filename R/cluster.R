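# Deterministic PAM (BUILD + SWAP), silhouette widths, and 2-D embeddings
# (classical metric scaling and a diffusion map) -- all operating directly
# on a dissimilarity matrix such as 1 - forest proximity.

check_distance <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop_("distance matrix must be square")
  if (any(!is.finite(d))) stop_("distance matrix must be finite")
  if (any(d < 0)) stop_("distances must be non-negative")
  if (max(abs(d - t(d))) > 1e-8) stop_("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop_("distance diagonal must be zero")
  if (is.null(rownames(d))) dimnames(d) <- list(seq_len(nrow(d)),
                                                seq_len(nrow(d)))
  d
}

#' Partitioning around medoids
#'
#' Deterministic k-medoids clustering of a dissimilarity matrix, minimizing
#' the total dissimilarity of points to their nearest medoid. Small
#' problems (at most 10000 candidate medoid subsets, which covers the
#' case-clustering step of the pipeline) are solved exactly by enumeration;
#' larger ones use the classical BUILD + SWAP search: greedy seeding
#' (first the point with minimal total dissimilarity, then the point giving
#' the largest cost reduction, lowest index on ties) followed by repeated
#' best-improving medoid/non-medoid exchanges until no swap lowers the
#' total cost. Points are assigned to their nearest medoid (lowest index on
#' ties). BUILD + SWAP is a local search and can return a slightly
#' suboptimal medoid set on adversarial dissimilarities; the exact path
#' cannot.
#'
#' @param d Square symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param method `"auto"` (exact when small, default), `"exact"`, or
#'   `"build_swap"`.
#' @return An object of class `pam_fit` with `labels` (named cluster ids
#'   1..k), `medoids` (subject names), `medoid_index`, `total_cost`,
#'   `method` and `iterations`.
#' @examples
#' d <- as.matrix(dist(c(0, 1, 10, 11)))
#' pam_cluster(d, 2)$labels
#' @export
pam_cluster <- function(d, k, method = c("auto", "exact", "build_swap")) {
  d <- check_distance(d)
  method <- match.arg(method)
  n <- nrow(d)
  check_count(k, "k", min = 1L)
  if (k > n) stop_("k (%d) cannot exceed the number of points (%d)", k, n)
  if (method == "auto")
    method <- if (choose(n, k) <= 10000) "exact" else "build_swap"

  cost_of <- function(med) sum(apply(d[, med, drop = FALSE], 1, min))
  iter <- 0L

  if (method == "exact") {
    sets <- utils::combn(n, k)
    costs <- apply(sets, 2, cost_of)
    med <- sets[, which.min(costs)]
  } else {
    # BUILD
    med <- which.min(colSums(d))
    while (length(med) < k) {
      nearest <- apply(d[, med, drop = FALSE], 1, min)
      gains <- vapply(seq_len(n), function(c) {
        if (c %in% med) return(-Inf)
        sum(pmax(nearest - d[, c], 0))
      }, numeric(1))
      med <- c(med, which.max(gains))
    }
    cost <- cost_of(med)

    # SWAP: best-improvement
    repeat {
      iter <- iter + 1L
      best <- list(delta = 0)
      for (mi in seq_along(med)) {
        others <- med[-mi]
        for (h in seq_len(n)) {
          if (h %in% med) next
          new_cost <- cost_of(c(others, h))
          delta <- new_cost - cost
          if (delta < best$delta - 1e-12)
            best <- list(delta = delta, mi = mi, h = h, cost = new_cost)
        }
      }
      if (is.null(best$mi)) break
      med[best$mi] <- best$h
      stopifnot(best$cost <= cost + 1e-12)  # cost never increases
      cost <- best$cost
    }
  }
  med <- sort(med)
  labels <- apply(d[, med, drop = FALSE], 1, which.min)
  names(labels) <- rownames(d)
  out <- list(labels = labels, medoids = rownames(d)[med],
              medoid_index = med, total_cost = cost_of(med),
              method = method, iterations = iter, k = as.integer(k))
  class(out) <- "pam_fit"
  out
}

#' @export
print.pam_fit <- function(x, ...) {
  cat(sprintf("PAM fit: k = %d, total cost %.4f, cluster sizes %s\n",
              x$k, x$total_cost,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Silhouette widths
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, where `a(i)` is the mean
#' dissimilarity of i to its own cluster (excluding itself) and `b(i)` the
#' smallest mean dissimilarity to another cluster. Members of singleton
#' clusters get `s = 0` by convention.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param labels Cluster labels, one per row of `d`; at least 2 clusters.
#' @return A list with `scores` (per subject) and `cluster_means` (named by
#'   cluster).
#' @export
silhouette_scores <- function(d, labels) {
  d <- check_distance(d)
  if (length(labels) != nrow(d)) stop_("labels must match distance rows")
  labels <- as.character(labels)
  clusters <- unique(labels)
  if (length(clusters) < 2L) stop_("at least two clusters are required")
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1L)
    b <- min(vapply(clusters[clusters != labels[i]], function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  names(s) <- rownames(d)
  cluster_means <- vapply(clusters, function(cl) mean(s[labels == cl]),
                          numeric(1))
  list(scores = s, cluster_means = cluster_means)
}

#' Two-dimensional embedding of a dissimilarity matrix
#'
#' `classical_mds` double-centers the squared dissimilarities and returns
#' the top-2 principal coordinates. `diffusion_map` builds a Gaussian kernel
#' (bandwidth = median off-diagonal dissimilarity), normalizes it to a
#' Markov transition matrix, and returns the first two nontrivial
#' eigenvector coordinates scaled by their eigenvalues. In both methods each
#' coordinate's sign is fixed so the entry of largest magnitude is positive;
#' duplicated subjects map to identical coordinates.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param method `"classical_mds"` or `"diffusion_map"`.
#' @return Numeric matrix (subjects x 2).
#' @export
embed_2d <- function(d, method = c("classical_mds", "diffusion_map")) {
  d <- check_distance(d)
  method <- match.arg(method)
  if (all(d == 0)) stop_("degenerate all-zero distance matrix")
  n <- nrow(d)
  if (method == "classical_mds") {
    coords <- stats::cmdscale(d, k = min(2L, n - 1L))
    if (ncol(coords) < 2L)
      coords <- cbind(coords, matrix(0, n, 2L - ncol(coords)))
  } else {
    eps <- stats::median(d[upper.tri(d)][d[upper.tri(d)] > 0])
    K <- exp(-(d / eps)^2)
    rs <- rowSums(K)
    S <- K / sqrt(rs %o% rs)   # symmetric normalization of the Markov matrix
    eig <- eigen(S, symmetric = TRUE)
    psi <- eig$vectors / sqrt(rs)
    coords <- sweep(psi[, 2:3, drop = FALSE], 2, eig$values[2:3], "*")
  }
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(d), c("dim1", "dim2"))
  coords
}
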