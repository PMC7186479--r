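#' Construct a clustering result
#'
#' @param labels per-item cluster index in `0..k-1`.
#' @param k number of clusters.
#' @param medoid_ids item labels of the medoids (PAM only).
#' @param sse within-cluster sum of squares (when a profile matrix is known).
#' @param ch_index Calinski-Harabasz index (when a profile matrix is known).
#' @param silhouette per-item silhouette widths.
#' @param method `"pam"` or `"agglomerative"`.
#' @param seed seed used for tie-breaking.
#' @return object of class `clustering_result`.
#' @keywords internal
clustering_result <- function(labels, k, medoid_ids = NULL, sse = NA_real_,
                              ch_index = NA_real_, silhouette = NULL,
                              method, seed = NA_integer_) {
  if (length(unique(labels)) != k) stop("clustering produced an empty cluster")
  structure(list(labels = labels, k = k, medoid_ids = medoid_ids, sse = sse,
                 ch_index = ch_index, silhouette = silhouette,
                 method = method, seed = seed),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("clustering_result [", x$method, "]: k = ", x$k, ", n = ",
      length(x$labels), "\n", sep = "")
  cat("cluster sizes: ", paste(tabulate(x$labels + 1L, x$k), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

.dissim_values <- function(d) {
  if (inherits(d, "dissimilarity_matrix")) d$values else as.matrix(d)
}

#' Partitioning around medoids (PAM)
#'
#' Classic BUILD + SWAP k-medoids: BUILD greedily picks the k items whose
#' selection most decreases total dissimilarity to the nearest medoid; SWAP
#' exchanges a medoid with a non-medoid whenever that strictly lowers total
#' cost, until no improving swap remains. Medoids are actual items. Exact
#' cost ties are broken by lowest item index, so the result is deterministic;
#' the seed is recorded but only consulted for ties that survive the
#' index rule (none, with the lowest-index policy).
#'
#' @param d a [dissimilarity_matrix()] (or square symmetric matrix).
#' @param k number of clusters, `2 <= k <= n-1`.
#' @param seed integer recorded in the result.
#' @return a `clustering_result` with `medoid_ids` set.
#' @export
pam <- function(d, k, seed = 1L) {
  dm <- .dissim_values(d)
  n <- nrow(dm)
  if (k < 2L || k > n - 1L) stop("k must satisfy 2 <= k <= n-1")

  cost <- function(medoids) sum(apply(dm[, medoids, drop = FALSE], 1L, min))

  # BUILD
  medoids <- which.min(rowSums(dm))[1L]
  while (length(medoids) < k) {
    nearest <- apply(dm[, medoids, drop = FALSE], 1L, min)
    gain <- vapply(seq_len(n), function(cand) {
      if (cand %in% medoids) return(-Inf)
      sum(pmax(nearest - dm[, cand], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain)[1L])
  }

  # SWAP: steepest improving swap, lowest-index tie-break via which.min
  repeat {
    cur <- cost(medoids)
    best_delta <- 0
    best_swap <- NULL
    for (mi in seq_along(medoids)) {
      for (cand in setdiff(seq_len(n), medoids)) {
        trial <- medoids
        trial[mi] <- cand
        delta <- cost(trial) - cur
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_swap <- c(mi, cand)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1L]] <- best_swap[2L]
  }

  medoids <- sort(medoids)
  labels <- apply(dm[, medoids, drop = FALSE], 1L, which.min) - 1L
  ids <- rownames(dm) %||% as.character(seq_len(n))
  clustering_result(labels, k, medoid_ids = ids[medoids], method = "pam",
                    seed = as.integer(seed))
}

#' Hierarchical agglomerative clustering cut at k clusters
#'
#' Bottom-up merging under the chosen linkage, then the tree is cut at `k`
#' clusters. Cluster indices are relabeled 0..k-1 in order of first
#' appearance.
#'
#' @param d a [dissimilarity_matrix()] (or square symmetric matrix).
#' @param k number of clusters, `2 <= k <= n-1`.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return a `clustering_result`.
#' @export
agglomerative <- function(d, k, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  dm <- .dissim_values(d)
  n <- nrow(dm)
  if (k < 2L || k > n - 1L) stop("k must satisfy 2 <= k <= n-1")
  hc <- stats::hclust(stats::as.dist(dm), method = linkage)
  raw <- stats::cutree(hc, k = k)
  labels <- as.integer(factor(raw, levels = unique(raw))) - 1L
  clustering_result(labels, k, method = "agglomerative")
}

.split_labels <- function(labels) split(seq_along(labels), labels)

#' Within-cluster sum of squared differences (SSE)
#'
#' `sum_k sum_{i in k} ||x_i - c_k||^2` with `c_k` the cluster centroid
#' (mean profile). Items are the rows of `m`.
#'
#' @param m item x feature numeric matrix.
#' @param labels per-item cluster labels (any coding).
#' @return non-negative scalar.
#' @export
sse <- function(m, labels) {
  m <- as.matrix(m)
  if (length(labels) != nrow(m)) stop("labels length must match rows of m")
  total <- 0
  for (idx in .split_labels(labels)) {
    x <- m[idx, , drop = FALSE]
    cen <- colMeans(x)
    total <- total + sum(sweep(x, 2L, cen, "-")^2)
  }
  total
}

#' Calinski-Harabasz index
#'
#' `CH = [B/(k-1)] / [W/(n-k)]` with between-cluster sum of squares
#' `B = sum_k n_k ||c_k - c_bar||^2` and within-cluster sum of squares
#' `W = SSE`. Larger values indicate tighter, better-separated clusters.
#'
#' @param m item x feature numeric matrix.
#' @param labels per-item cluster labels.
#' @return scalar CH index.
#' @export
calinski_harabasz <- function(m, labels) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (length(labels) != n) stop("labels length must match rows of m")
  k <- length(unique(labels))
  if (k < 2L || k >= n) stop("CH requires 2 <= k <= n-1")
  grand <- colMeans(m)
  b <- 0
  for (idx in .split_labels(labels)) {
    cen <- colMeans(m[idx, , drop = FALSE])
    b <- b + length(idx) * sum((cen - grand)^2)
  }
  w <- sse(m, labels)
  (b / (k - 1)) / (w / (n - k))
}

#' Per-item silhouette widths
#'
#' Two variants are provided. `variant = "extrema"` scores each item by
#' `(min out-of-cluster dissimilarity - max in-cluster dissimilarity) /
#' max(of those two)`: positive iff the item is closer to every in-cluster
#' neighbor than to any out-of-cluster item. `variant = "standard"` is
#' Rousseeuw's silhouette `(b - a)/max(a, b)` with `a` the mean in-cluster
#' and `b` the smallest mean out-of-cluster dissimilarity. Both are bounded
#' in `[-1, 1]`; singleton clusters score 0 by convention.
#'
#' @param d a [dissimilarity_matrix()] (or square symmetric matrix).
#' @param labels per-item cluster labels.
#' @param variant `"extrema"` (default) or `"standard"`.
#' @return numeric vector of per-item widths in `[-1, 1]`.
#' @export
silhouette_widths <- function(d, labels, variant = c("extrema", "standard")) {
  variant <- match.arg(variant)
  dm <- .dissim_values(d)
  n <- nrow(dm)
  if (length(labels) != n) stop("labels length must match matrix dimension")
  if (length(unique(labels)) < 2L) stop("silhouette requires k >= 2")
  sw <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) { sw[i] <- 0; next }   # singleton
    if (variant == "extrema") {
      a <- max(dm[i, own])
      b <- min(dm[i, !own & seq_len(n) != i])
    } else {
      a <- mean(dm[i, own])
      others <- which(labels != labels[i])
      b <- min(tapply(dm[i, others], labels[others], mean))
    }
    denom <- max(a, b)
    sw[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  sw
}

#' Sweep the number of clusters and tabulate quality indices
#'
#' Runs one clustering per `k` in `k_range` and reports SSE,
#' Calinski-Harabasz and mean silhouette width (standard variant) for each,
#' with the argmax-CH row flagged. No automatic `k` is selected: inspect the
#' table (e.g. for an SSE elbow) to choose.
#'
#' @param m item x feature profile matrix (for SSE/CH).
#' @param d matching [dissimilarity_matrix()] (for clustering and silhouette).
#' @param k_range integer vector of cluster counts within `[2, n-1]`.
#' @param method `"pam"` or `"agglomerative"`.
#' @param seed seed forwarded to [pam()].
#' @param linkage linkage forwarded to [agglomerative()].
#' @return data.frame with columns `k`, `sse`, `ch`, `mean_silhouette`,
#'   `best_ch` (logical flag on the argmax-CH row).
#' @export
sweep_k <- function(m, d, k_range, method = c("pam", "agglomerative"),
                    seed = 1L, linkage = "average") {
  method <- match.arg(method)
  m <- as.matrix(m)
  n <- nrow(m)
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop("k_range must lie within [2, n-1]")
  rows <- lapply(k_range, function(k) {
    cl <- if (method == "pam") pam(d, k, seed = seed)
          else agglomerative(d, k, linkage = linkage)
    data.frame(k = k, sse = sse(m, cl$labels),
               ch = calinski_harabasz(m, cl$labels),
               mean_silhouette = mean(silhouette_widths(d, cl$labels,
                                                        "standard")))
  })
  out <- do.call(rbind, rows)
  out$best_ch <- seq_len(nrow(out)) == which.max(out$ch)
  out
}

#' Default taxon-profile preparation for temporal clustering
#'
#' The pipeline used before clustering taxa by temporal profile:
#' started-log variance stabilization, per-taxon z-scoring, and a
#' taxon-by-taxon Euclidean dissimilarity.
#'
#' @param table a [count_table()].
#' @param c started-log offset (default 1).
#' @return list with `profiles` (taxon x sample z-scored matrix) and `d`
#'   (taxon [dissimilarity_matrix()]).
#' @export
taxon_profiles <- function(table, c = 1) {
  z <- zscore(started_log(table, c), axis = "taxa")
  list(profiles = z$values, d = euclidean_dist(z, compare = "taxa"))
}
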