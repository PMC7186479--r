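#' Construct an ordination result
#'
#' @param coordinates item x axis matrix of embedded coordinates.
#' @param eigenvalues per-axis eigenvalues (PCA/PCoA; may be negative for
#'   non-metric PCoA input).
#' @param variance_fraction eigenvalue / sum of positive eigenvalues.
#' @param stress normalized residual of an MDS embedding, or `NA`.
#' @param method `"pca"`, `"pcoa"` or `"mds"`.
#' @param converged,n_restarts_used optimizer diagnostics (MDS only).
#' @return object of class `ordination_result`.
#' @keywords internal
ordination_result <- function(coordinates, eigenvalues = NULL,
                              variance_fraction = NULL, stress = NA_real_,
                              method, converged = TRUE, n_restarts_used = 0L) {
  structure(list(coordinates = coordinates, eigenvalues = eigenvalues,
                 variance_fraction = variance_fraction, stress = stress,
                 method = method, converged = converged,
                 n_restarts_used = n_restarts_used),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("ordination_result [", x$method, "]: ", nrow(x$coordinates),
      " items x ", ncol(x$coordinates), " axes\n", sep = "")
  if (!is.null(x$variance_fraction))
    cat("variance fraction (first axes): ",
        paste(sprintf("%.3f", utils::head(x$variance_fraction, 4)),
              collapse = ", "), "\n", sep = "")
  if (!is.na(x$stress)) cat(sprintf("stress: %.6g\n", x$stress))
  invisible(x)
}

#' Principal components analysis
#'
#' Eigen-decomposition of the covariance matrix of the observations
#' (rows of `m`); coordinates are the projections of the centered
#' observations on the eigenvectors, eigenvalues partition the total
#' variance.
#'
#' @param m observations x variables numeric matrix.
#' @param center subtract variable means (default TRUE).
#' @param scale divide variables by their standard deviation (default FALSE).
#' @return an `ordination_result` with `method = "pca"`.
#' @export
pca <- function(m, center = TRUE, scale = FALSE) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("input has non-finite entries")
  if (nrow(m) < 2L) stop("PCA needs >= 2 observations")
  x <- scale(m, center = center, scale = scale)
  q <- crossprod(x) / (nrow(m) - 1L)        # variable covariance matrix
  e <- eigen(q, symmetric = TRUE)
  ev <- pmax(e$values, 0)                   # clip numerically negative
  coords <- x %*% e$vectors
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  ordination_result(coords, eigenvalues = ev,
                    variance_fraction = if (sum(ev) > 0) ev / sum(ev) else ev,
                    method = "pca")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared dissimilarity matrix (Gower transform
#' `-1/2 J D^2 J`) and eigen-decomposes it; coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues. Negative
#' eigenvalues — which arise for non-metric inputs such as Bray-Curtis — are
#' reported as-is with zero coordinate contribution and a warning; no
#' Cailliez/Lingoes correction is applied. Variance fractions are computed
#' over the positive eigenvalues only.
#'
#' @param d a [dissimilarity_matrix()] (or square symmetric matrix).
#' @return an `ordination_result` with `method = "pcoa"`.
#' @export
pcoa <- function(d) {
  dm <- if (inherits(d, "dissimilarity_matrix")) d$values else as.matrix(d)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8)
    stop("PCoA requires a square symmetric dissimilarity matrix")
  n <- nrow(dm)
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% (dm^2) %*% j
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  ev <- e$values
  ev[abs(ev) < 1e-9 * max(abs(ev), 1)] <- 0
  if (any(ev < 0))
    warning("PCoA input is non-metric: ", sum(ev < 0),
            " negative eigenvalue(s) reported with zero coordinates")
  scal <- sqrt(pmax(ev, 0))
  coords <- e$vectors %*% diag(scal, n, n)
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("Axis", seq_len(n))
  pos <- sum(ev[ev > 0])
  ordination_result(coords, eigenvalues = ev,
                    variance_fraction = if (pos > 0) pmax(ev, 0) / pos else ev,
                    method = "pcoa")
}

#' Least-squares multidimensional scaling stress
#'
#' `sqrt( sum (d - d')^2 / sum d^2 )` over corresponding entries; 0 iff the
#' embedded distances reproduce the originals exactly.
#'
#' @param d_orig,d_embed dissimilarity matrices of matching dimension.
#' @return non-negative scalar.
#' @export
stress <- function(d_orig, d_embed) {
  a <- if (inherits(d_orig, "dissimilarity_matrix")) d_orig$values else as.matrix(d_orig)
  b <- if (inherits(d_embed, "dissimilarity_matrix")) d_embed$values else as.matrix(d_embed)
  if (!all(dim(a) == dim(b))) stop("dissimilarity matrices differ in dimension")
  if (sum(a^2) == 0) stop("stress undefined for an all-zero reference matrix")
  sqrt(sum((a - b)^2) / sum(a^2))
}

# raw (unnormalized) objective sum_{i<j} (delta_ij - d_ij(X))^2 and gradient
.mds_obj_grad <- function(x, delta, n, ndim) {
  xm <- matrix(x, n, ndim)
  dm <- as.matrix(stats::dist(xm))
  r <- dm - delta
  f <- sum(r[upper.tri(r)]^2)
  w <- matrix(0, n, n)
  nz <- dm > 0
  w[nz] <- r[nz] / dm[nz]          # 2 * factor folded below
  grad <- 2 * (xm * rowSums(w) - w %*% xm)
  list(f = f, grad = as.vector(grad))
}

#' Metric least-squares multidimensional scaling
#'
#' Finds coordinates in `ndim` dimensions minimizing the squared mismatch
#' between the input dissimilarities and the embedded Euclidean distances,
#' reporting the normalized [stress()]. Optimization starts from the PCoA
#' configuration plus seeded random restarts and returns the lowest-stress
#' solution. This is the metric least-squares objective; Kruskal's monotone
#' regression NMDS is deliberately not implemented.
#'
#' @param d a [dissimilarity_matrix()] (or square symmetric matrix).
#' @param ndim target dimension, `< n`.
#' @param seed integer seed for the random restarts.
#' @param n_restarts number of random restarts beyond the PCoA start
#'   (default 20).
#' @param tol relative objective-change tolerance (default 1e-8).
#' @param max_iter iteration cap per start (default 2000).
#' @return an `ordination_result` with `method = "mds"` and `stress` set.
#' @export
mds <- function(d, ndim = 2L, seed = 1L, n_restarts = 20L, tol = 1e-8,
                max_iter = 2000L) {
  dm <- if (inherits(d, "dissimilarity_matrix")) d$values else as.matrix(d)
  n <- nrow(dm)
  if (ndim >= n) stop("ndim must be smaller than the number of items")
  if (ndim < 1L) stop("ndim must be >= 1")
  scale0 <- max(dm)
  if (scale0 == 0) stop("all dissimilarities are zero")

  starts <- list(suppressWarnings(pcoa(dm))$coordinates[, seq_len(ndim),
                                                        drop = FALSE])
  set.seed(seed)
  for (r in seq_len(n_restarts))
    starts[[r + 1L]] <- matrix(stats::rnorm(n * ndim, sd = scale0 / 2), n, ndim)

  best <- NULL
  for (s in starts) {
    fit <- stats::optim(as.vector(s),
                        fn = function(x) .mds_obj_grad(x, dm, n, ndim)$f,
                        gr = function(x) .mds_obj_grad(x, dm, n, ndim)$grad,
                        method = "BFGS",
                        control = list(maxit = max_iter, reltol = tol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  xm <- matrix(best$par, n, ndim)
  rownames(xm) <- rownames(dm)
  colnames(xm) <- paste0("MDS", seq_len(ndim))
  st <- stress(dm, as.matrix(stats::dist(xm)))
  ordination_result(xm, stress = st, method = "mds",
                    converged = best$convergence == 0L,
                    n_restarts_used = n_restarts)
}

#' Scree table of variance explained per axis
#'
#' @param result an `ordination_result` from [pca()] or [pcoa()].
#' @return data.frame with columns `axis`, `variance_fraction`, `cumulative`,
#'   descending in variance fraction.
#' @export
scree <- function(result) {
  stopifnot(inherits(result, "ordination_result"))
  if (result$method == "mds" || is.null(result$variance_fraction))
    stop("scree requires a pca or pcoa result (MDS has no eigenvalues)")
  vf <- pmax(result$variance_fraction, 0)
  ord <- order(vf, decreasing = TRUE)
  data.frame(axis = ord, variance_fraction = vf[ord],
             cumulative = cumsum(vf[ord]))
}
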