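#' Construct a composition matrix
#'
#' Real-valued taxon-by-sample matrix produced by a normalization, carrying a
#' provenance tag so downstream steps can check what has been applied.
#'
#' @param values real taxon x sample matrix.
#' @param taxon_ids,sample_ids,times labels and per-sample times (hours).
#' @param transform_tag one of `"none"`, `"pseudocount"`, `"focal_lr"`,
#'   `"clr"`, `"ilr"`, `"zscore"`, `"started_log"`, `"detrended"`.
#' @return object of class `composition_matrix`.
#' @export
composition_matrix <- function(values, taxon_ids = rownames(values),
                               sample_ids = colnames(values), times = NULL,
                               transform_tag = "none") {
  values <- as.matrix(values)
  tags <- c("none", "pseudocount", "focal_lr", "clr", "ilr", "zscore",
            "started_log", "detrended")
  transform_tag <- match.arg(transform_tag, tags)
  if (any(!is.finite(values))) stop("composition values must be finite")
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  dimnames(values) <- list(taxon_ids, sample_ids)
  structure(list(values = values, taxon_ids = as.character(taxon_ids),
                 sample_ids = as.character(sample_ids), times = times,
                 transform_tag = transform_tag),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat("composition_matrix [", x$transform_tag, "]: ", nrow(x$values),
      " taxa x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

# Accept either container; return list(values, taxon_ids, sample_ids, times)
.as_values <- function(x) {
  if (inherits(x, "count_table"))
    list(values = x$counts + 0, taxon_ids = x$taxon_ids,
         sample_ids = x$sample_ids, times = x$times)
  else if (inherits(x, "composition_matrix"))
    x[c("values", "taxon_ids", "sample_ids", "times")]
  else {
    m <- as.matrix(x)
    list(values = m,
         taxon_ids = rownames(m) %||% paste0("taxon", seq_len(nrow(m))),
         sample_ids = colnames(m) %||% paste0("sample", seq_len(ncol(m))),
         times = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add a pseudocount to every cell
#'
#' Makes all entries strictly positive so that log-ratio transforms are
#' defined. Note that a pseudocount disproportionately affects rare taxa,
#' whose between-sample differences can be of the same magnitude as the
#' constant added.
#'
#' @param table a [count_table()] (or numeric matrix).
#' @param c positive constant added to every cell (default 1).
#' @return a [composition_matrix()] tagged `"pseudocount"`.
#' @export
add_pseudocount <- function(table, c = 1) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("pseudocount c must be a single positive number (log of zero is undefined downstream)")
  v <- .as_values(table)
  composition_matrix(v$values + c, v$taxon_ids, v$sample_ids, v$times,
                     "pseudocount")
}

.check_positive <- function(m, what = "input") {
  if (any(m <= 0))
    stop(what, " has non-positive entries; apply add_pseudocount() first")
}

#' Focal (additive) log-ratio transform
#'
#' Per sample, each taxon's log abundance is taken relative to one focal
#' taxon: `ln(x_i) - ln(x_focal)`. The focal row is identically zero.
#'
#' @param m strictly positive [composition_matrix()] (or matrix/count_table).
#' @param focal taxon id (or row index) of the reference taxon.
#' @return a [composition_matrix()] tagged `"focal_lr"`.
#' @export
focal_log_ratio <- function(m, focal) {
  v <- .as_values(m)
  .check_positive(v$values)
  if (is.character(focal)) {
    idx <- match(focal, v$taxon_ids)
    if (is.na(idx)) stop("unknown focal taxon '", focal, "'")
  } else idx <- as.integer(focal)
  if (idx < 1L || idx > nrow(v$values)) stop("focal index out of range")
  lg <- log(v$values)
  out <- sweep(lg, 2L, lg[idx, ], "-")
  composition_matrix(out, v$taxon_ids, v$sample_ids, v$times, "focal_lr")
}

#' Centered log-ratio (CLR) transform
#'
#' Per sample, log abundances are centered on their geometric mean:
#' `CLR_i = ln(x_i) - mean_k ln(x_k)`. Every transformed sample column sums
#' to zero, so the output is still sum-constrained.
#'
#' @param m strictly positive [composition_matrix()] (or matrix/count_table).
#' @return a [composition_matrix()] tagged `"clr"`.
#' @export
clr <- function(m) {
  v <- .as_values(m)
  .check_positive(v$values)
  lg <- log(v$values)
  out <- sweep(lg, 2L, colMeans(lg), "-")
  composition_matrix(out, v$taxon_ids, v$sample_ids, v$times, "clr")
}

#' Default orthonormal ILR contrast basis
#'
#' Helmert-type contrasts in taxon input order: an `(n-1) x n` matrix with
#' orthonormal rows, each orthogonal to the all-ones vector.
#'
#' @param n number of taxa (parts).
#' @return `(n-1) x n` numeric matrix.
#' @export
ilr_basis <- function(n) {
  if (n < 2L) stop("need at least 2 parts for an ILR basis")
  b <- matrix(0, n - 1L, n)
  for (k in seq_len(n - 1L)) {
    # contrast of the first k parts against part k+1, normalized
    b[k, seq_len(k)] <- 1 / k
    b[k, k + 1L] <- -1
    b[k, ] <- b[k, ] * sqrt(k / (k + 1))
  }
  b
}

#' Isometric log-ratio (ILR) transform
#'
#' Applies an orthonormal contrast basis to the CLR coordinates, mapping n
#' taxa to n-1 unconstrained coordinates. Euclidean distances between
#' ILR-transformed samples equal those between CLR-transformed samples
#' (isometry).
#'
#' @param m strictly positive [composition_matrix()] (or matrix/count_table).
#' @param basis `(n-1) x n` orthonormal contrast matrix with rows orthogonal
#'   to the all-ones vector, or `"default"` for Helmert-type contrasts in
#'   taxon input order (the partition is arbitrary; override if a meaningful
#'   sequential binary partition is available).
#' @return a [composition_matrix()] tagged `"ilr"` with `n-1` coordinate rows.
#' @export
ilr <- function(m, basis = "default") {
  v <- .as_values(m)
  .check_positive(v$values)
  n <- nrow(v$values)
  if (identical(basis, "default")) basis <- ilr_basis(n)
  basis <- as.matrix(basis)
  if (!all(dim(basis) == c(n - 1L, n)))
    stop("basis must be (n-1) x n = ", n - 1L, " x ", n)
  g <- basis %*% t(basis)
  if (max(abs(g - diag(n - 1L))) > 1e-8 || max(abs(basis %*% rep(1, n))) > 1e-8)
    stop("basis rows must be orthonormal and orthogonal to the ones vector")
  cl <- clr(v$values)
  composition_matrix(basis %*% cl$values,
                     paste0("ilr", seq_len(n - 1L)),
                     v$sample_ids, v$times, "ilr")
}

#' Z-score standardization
#'
#' Centers and scales each taxon (row) or sample (column) vector to mean 0
#' and sample standard deviation 1 (denominator n-1), putting variables of
#' different magnitudes on a common scale.
#'
#' @param m numeric matrix (or composition/count container).
#' @param axis `"taxa"` to standardize each row, `"samples"` for each column.
#' @return object of the same matrix shape; a [composition_matrix()] tagged
#'   `"zscore"` when the input carries labels.
#' @export
zscore <- function(m, axis = c("taxa", "samples")) {
  axis <- match.arg(axis)
  v <- .as_values(m)
  x <- v$values
  if (axis == "taxa") {
    mu <- rowMeans(x)
    sd_ <- apply(x, 1L, stats::sd)
    if (any(sd_ == 0))
      stop("constant vector (sd = 0) for taxon '",
           v$taxon_ids[which(sd_ == 0)[1L]], "'")
    out <- (x - mu) / sd_
  } else {
    mu <- colMeans(x)
    sd_ <- apply(x, 2L, stats::sd)
    if (any(sd_ == 0))
      stop("constant vector (sd = 0) for sample '",
           v$sample_ids[which(sd_ == 0)[1L]], "'")
    out <- sweep(sweep(x, 2L, mu, "-"), 2L, sd_, "/")
  }
  composition_matrix(out, v$taxon_ids, v$sample_ids, v$times, "zscore")
}

#' Started-log transform
#'
#' `ln(count + c)` entrywise: behaves like a plain log for large counts while
#' remaining defined at zero. Used here as the variance-stabilizing step of
#' the clustering pipeline; it approximates, but does not reproduce, model
#' based variance-stabilizing transforms fitted to a mean-variance trend.
#'
#' @param table a [count_table()] (or numeric matrix).
#' @param c positive offset (default 1).
#' @return a [composition_matrix()] tagged `"started_log"`.
#' @export
started_log <- function(table, c = 1) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("offset c must be a single positive number")
  v <- .as_values(table)
  if (any(v$values < 0)) stop("counts must be non-negative")
  composition_matrix(log(v$values + c), v$taxon_ids, v$sample_ids, v$times,
                     "started_log")
}

#' Remove a linear time trend from each taxon
#'
#' Fits an ordinary-least-squares line of each row on sampling time and
#' subtracts it, a first-order correction toward the stationarity assumed by
#' rank-based periodicity tests. Residuals have zero mean and zero OLS slope.
#'
#' @param m numeric matrix (taxa x samples) or composition container.
#' @param times per-sample times in hours; defaults to the container's times.
#' @return a [composition_matrix()] tagged `"detrended"`.
#' @export
detrend_linear <- function(m, times = NULL) {
  v <- .as_values(m)
  times <- times %||% v$times
  if (is.null(times)) stop("times required (none stored in input)")
  times <- as.numeric(times)
  if (length(times) != ncol(v$values))
    stop("times length does not match number of samples")
  if (length(times) < 3L) stop("detrending needs >= 3 time points")
  if (max(times) == min(times)) stop("times must not all be equal")
  tc <- times - mean(times)
  x <- v$values
  xc <- x - rowMeans(x)
  slope <- (xc %*% tc) / sum(tc^2)
  out <- xc - slope %*% rbind(tc)
  composition_matrix(out, v$taxon_ids, v$sample_ids, times, "detrended")
}
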