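#' Construct a dissimilarity matrix object
#'
#' Square symmetric non-negative matrix with zero diagonal, plus a flag
#' recording whether the measure is claimed to be a metric (Bray-Curtis is
#' not: it can violate the triangle inequality).
#'
#' @param values square symmetric numeric matrix.
#' @param ids item labels.
#' @param metric_name name of the measure.
#' @param is_metric_claimed whether the measure satisfies the metric axioms.
#' @return object of class `dissimilarity_matrix`.
#' @export
dissimilarity_matrix <- function(values, ids = rownames(values),
                                 metric_name = "unknown",
                                 is_metric_claimed = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("dissimilarity matrix must be square")
  if (any(!is.finite(values))) stop("dissimilarities must be finite")
  if (max(abs(values - t(values))) > 1e-12) stop("matrix is not symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  if (any(values < 0)) stop("dissimilarities must be non-negative")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (is.null(ids)) ids <- paste0("item", seq_len(nrow(values)))
  ids <- as.character(ids)
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, metric_name = metric_name,
                 is_metric_claimed = is_metric_claimed),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat("dissimilarity_matrix [", x$metric_name, "]: ", nrow(x$values),
      " items", if (!x$is_metric_claimed) " (non-metric)", "\n", sep = "")
  invisible(x)
}

# items-in-columns orientation: compare="samples" compares columns,
# compare="taxa" compares rows.
.items <- function(v, compare) {
  if (compare == "samples") list(m = t(v$values), ids = v$sample_ids)
  else list(m = v$values, ids = v$taxon_ids)
}

#' Euclidean distance between samples or taxa
#'
#' `d_ij = sqrt(sum_k (x_ik - x_jk)^2)` over the feature dimension.
#'
#' @param m numeric matrix or composition/count container.
#' @param compare `"samples"` (columns) or `"taxa"` (rows).
#' @return a [dissimilarity_matrix()], metric.
#' @export
euclidean_dist <- function(m, compare = c("samples", "taxa")) {
  compare <- match.arg(compare)
  v <- .as_values(m)
  if (any(!is.finite(v$values))) stop("input has non-finite entries")
  it <- .items(v, compare)
  d <- as.matrix(stats::dist(it$m, method = "euclidean"))
  dissimilarity_matrix(d, it$ids, "euclidean", is_metric_claimed = TRUE)
}

#' Jaccard distance between samples
#'
#' Counts are binarized (present iff count > 0); the distance is
#' `1 - |A intersect B| / |A union B|` over present-taxa sets. Two samples
#' with no taxa at all are identical sets, hence distance 0.
#'
#' @param table a [count_table()] (or non-negative matrix).
#' @return a [dissimilarity_matrix()].
#' @export
jaccard_dist <- function(table) {
  v <- .as_values(table)
  p <- v$values > 0
  inter <- t(p) %*% p                       # |A ∩ B|
  sizes <- colSums(p)
  uni <- outer(sizes, sizes, "+") - inter   # |A ∪ B|
  d <- ifelse(uni == 0, 0, 1 - inter / uni)
  diag(d) <- 0
  dissimilarity_matrix(d, v$sample_ids, "jaccard", is_metric_claimed = TRUE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC_ij = 1 - 2 sum_k min(s_ik, s_jk) / (sum_k s_ik + sum_k s_jk)`,
#' bounded in `[0, 1]`: 0 for identical communities, 1 for communities with
#' no taxa in common. Bray-Curtis does not obey the triangle inequality, so
#' the result is flagged non-metric; ordinations that assume metric input
#' (e.g. PCoA) can produce negative eigenvalues from it.
#'
#' @param table a [count_table()] (or non-negative matrix).
#' @return a [dissimilarity_matrix()] with `is_metric_claimed = FALSE`.
#' @export
bray_curtis <- function(table) {
  v <- .as_values(table)
  s <- v$values
  if (any(s < 0)) stop("Bray-Curtis requires non-negative abundances")
  tot <- colSums(s)
  n <- ncol(s)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    denom <- tot[i] + tot[j]
    if (denom == 0)
      stop("Bray-Curtis undefined for two all-zero samples ('",
           v$sample_ids[i], "', '", v$sample_ids[j], "')")
    d[i, j] <- d[j, i] <- 1 - 2 * sum(pmin(s[, i], s[, j])) / denom
  }
  dissimilarity_matrix(d, v$sample_ids, "bray_curtis",
                       is_metric_claimed = FALSE)
}

#' Aitchison distance between samples
#'
#' Euclidean distance computed on CLR-transformed abundances (after adding a
#' pseudocount): the natural metric for compositions, invariant to sample
#' wise rescaling.
#'
#' @param table a [count_table()] (or non-negative matrix).
#' @param c pseudocount (default 1).
#' @return a [dissimilarity_matrix()], metric.
#' @export
aitchison_dist <- function(table, c = 1) {
  d <- euclidean_dist(clr(add_pseudocount(table, c)), compare = "samples")
  d$metric_name <- "aitchison"
  d
}

#' A Bray-Curtis triangle-inequality counter-example
#'
#' Returns a 3-sample count table whose Bray-Curtis dissimilarities violate
#' the triangle inequality: samples A and B share no taxa (so `BC(A,B) = 1`)
#' yet each overlaps heavily with a doubly-abundant sample C, giving
#' `BC(A,B) > BC(A,C) + BC(C,B)`.
#'
#' @param total reads for the single taxon of samples A and B (default 1000);
#'   C carries `total` reads of each.
#' @return a [count_table()] with samples `A`, `B`, `C`.
#' @export
bray_curtis_counterexample <- function(total = 1000) {
  # A on taxon 1 only, B on taxon 2 only, C on both: BC(A,B) = 1 while
  # BC(A,C) = BC(C,B) = 1/3, so 1 > 1/3 + 1/3 violates the triangle
  # inequality strictly.
  counts <- cbind(A = c(total, 0),
                  B = c(0, total),
                  C = c(total, total))
  ct <- count_table(counts, taxon_ids = c("t1", "t2"))
  d <- bray_curtis(ct)$values
  stopifnot(d["A", "B"] > d["A", "C"] + d["C", "B"] + 1e-9)
  ct
}
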