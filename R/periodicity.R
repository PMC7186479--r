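#' Map sampling times to phase classes within a period
#'
#' `class(t) = round((t mod period)/delta_t) mod C` with `C = period/delta_t`
#' phase classes. Times must sit on the `delta_t` grid and the period must be
#' an integer multiple of `delta_t`.
#'
#' @param times sampling times in hours.
#' @param period cycle length in hours (default 24).
#' @param delta_t sampling interval in hours (default 4).
#' @return integer vector of phase classes in `0..C-1`.
#' @export
phase_classes <- function(times, period = 24, delta_t = 4) {
  c_ratio <- period / delta_t
  if (abs(c_ratio - round(c_ratio)) > 1e-9)
    stop("period must be divisible by delta_t")
  cc <- as.integer(round(c_ratio))
  off <- times / delta_t
  if (any(abs(off - round(off)) > 1e-9))
    stop("times are not on the delta_t grid: t = ",
         times[which(abs(off - round(off)) > 1e-9)[1L]])
  as.integer(round((times %% period) / delta_t)) %% cc
}

# Circular distance of each class from a peak class (0..floor(C/2)).
.circ_dist <- function(classes, peak, n_classes) {
  d <- abs(classes - peak)
  pmin(d, n_classes - d)
}

# Pair index sets for one peak: all observation pairs (u, v) whose classes
# are strictly ordered in the symmetric umbrella (u farther from the peak
# than v, so x_u is expected below x_v).
.umbrella_pairs <- function(classes, peak, n_classes) {
  lev <- -.circ_dist(classes, peak, n_classes)
  n <- length(classes)
  pr <- which(outer(lev, lev, "<"), arr.ind = TRUE)
  list(u = pr[, 1L], v = pr[, 2L], n_pairs = nrow(pr))
}

#' Umbrella concordance statistic
#'
#' Counts, Mann-Whitney style, the observation pairs consistent with a
#' single rise to `peak` and fall away from it: over all pairs whose phase
#' classes are strictly ordered in the symmetric umbrella about `peak`
#' (ordered by circular distance from the peak), a pair is concordant when
#' the value nearer the peak is larger; ties count 1/2. The maximum is the
#' total number of ordered pairs (a perfect tent profile), the minimum 0
#' (a perfect inverted tent).
#'
#' @param values observed series.
#' @param classes per-observation phase classes (see [phase_classes()]).
#' @param peak candidate peak class.
#' @param n_classes number of phase classes `C`; defaults to
#'   `max(classes) + 1`.
#' @return scalar statistic.
#' @export
umbrella_statistic <- function(values, classes, peak,
                               n_classes = max(classes) + 1L) {
  if (length(values) != length(classes))
    stop("values and classes differ in length")
  if (length(unique(classes)) < 2L) stop("need >= 2 distinct phase classes")
  pr <- .umbrella_pairs(classes, peak, n_classes)
  sum((values[pr$u] < values[pr$v]) + 0.5 * (values[pr$u] == values[pr$v]))
}

# Permutation null of the max-over-peaks p-value machinery: for each peak,
# the statistics of n_perm seeded permutations of `values`. Returns an
# n_perm x C matrix. For tie-free series the statistic depends on values
# only through ranks, so a null computed from ranks 1..n is shared by every
# tie-free taxon with the same class layout.
.umbrella_null <- function(values, classes, n_classes, n_perm, seed) {
  n <- length(values)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))      # n x n_perm
  vmat <- matrix(values[perms], n, n_perm)
  out <- matrix(0, n_perm, n_classes)
  for (p in seq_len(n_classes)) {
    pr <- .umbrella_pairs(classes, p - 1L, n_classes)
    lt <- vmat[pr$u, , drop = FALSE] < vmat[pr$v, , drop = FALSE]
    eq <- vmat[pr$u, , drop = FALSE] == vmat[pr$v, , drop = FALSE]
    out[, p] <- colSums(lt) + 0.5 * colSums(eq)
  }
  out
}

#' Umbrella rank test for single-peak periodicity
#'
#' Screens one detrended series for a consistent rise-and-fall at the given
#' period: for each candidate peak class the umbrella concordance statistic
#' is computed and referred to a seeded permutation null (shuffling the
#' observation order), `p = (1 + #\{perm >= obs\})/(1 + n_perm)`. The
#' reported p-value is the minimum over candidate peaks times the number of
#' classes (Bonferroni over candidate shapes), capped at 1; the reported
#' peak is the argmin class. At least two full periods must be sampled
#' (stationarity of the series across periods is assumed; detrend first).
#'
#' @param values observed (detrended) series.
#' @param times sampling times in hours.
#' @param period,delta_t cycle length and sampling interval in hours.
#' @param n_perm number of permutations (default 10000); p-values are floored
#'   at `1/(n_perm + 1)` before the shape correction.
#' @param seed integer seed for the permutation stream.
#' @param null_stats optional precomputed permutation-null matrix from a
#'   previous tie-free run with identical `(times, period, delta_t, n_perm,
#'   seed)`; reused only when `values` has no ties.
#' @return list with `p_value`, `peak_phase_class`, `statistic`,
#'   `n_permutations`, `seed`.
#' @export
rain_like_test <- function(values, times, period = 24, delta_t = 4,
                           n_perm = 10000L, seed = 1L, null_stats = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (diff(range(times)) < 2 * period - 1e-9)
    stop("need at least 2 full periods sampled for the stationarity assumption")
  classes <- phase_classes(times, period, delta_t)
  cc <- as.integer(round(period / delta_t))
  obs <- vapply(seq_len(cc) - 1L,
                function(p) umbrella_statistic(values, classes, p, cc),
                numeric(1))
  tie_free <- !anyDuplicated(values)
  if (is.null(null_stats) || !tie_free) {
    base <- if (tie_free) rank(values) else values
    null_stats <- .umbrella_null(base, classes, cc, n_perm, seed)
  }
  p_per_peak <- vapply(seq_len(cc), function(p)
    (1 + sum(null_stats[, p] >= obs[p] - 1e-9)) / (1 + n_perm), numeric(1))
  best <- which.min(p_per_peak)[1L]
  list(p_value = min(1, p_per_peak[best] * cc),
       peak_phase_class = best - 1L,
       statistic = obs[best],
       n_permutations = as.integer(n_perm),
       seed = as.integer(seed))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' P-values are ranked from smallest to largest and hypotheses `1..k*` are
#' rejected, where `k*` is the largest `k` with `p_(k) <= k * alpha / m`.
#'
#' @param p_values p-values in `[0, 1]`.
#' @param alpha target false discovery rate in `(0, 1)`.
#' @return logical rejection flags in input order.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values)))
    stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- which(ps <= seq_len(m) * alpha / m)
  flags <- logical(m)
  if (length(ok)) flags[ord[seq_len(max(ok))]] <- TRUE
  flags
}

#' Community-wide diel periodicity screen
#'
#' Runs the umbrella rank test on every taxon of a CLR-transformed,
#' detrended composition matrix and controls the false discovery rate across
#' taxa with the Benjamini-Hochberg step-up rule. The permutation null is
#' computed once and shared across tie-free taxa (it depends on the values
#' only through their ranks); taxa with ties get their own permutation run.
#'
#' @param m a [composition_matrix()]; the conventional pipeline is
#'   `detrend_linear(clr(add_pseudocount(table)))`. A warning is issued when
#'   the provenance tag is not `"detrended"`.
#' @param period,delta_t cycle length and sampling interval in hours.
#' @param alpha FDR level (default 0.05).
#' @param n_perm permutations per test (default 10000).
#' @param seed integer seed.
#' @return data.frame with one row per taxon: `taxon_id`, `statistic`,
#'   `p_value`, `peak_phase_class`, `q_rejected`, `n_permutations`, `seed`.
#' @export
periodicity_screen <- function(m, period = 24, delta_t = 4, alpha = 0.05,
                               n_perm = 10000L, seed = 1L) {
  v <- .as_values(m)
  if (inherits(m, "composition_matrix") && m$transform_tag != "detrended")
    warning("input is tagged '", m$transform_tag,
            "', not 'detrended'; the test assumes a detrended series")
  times <- v$times
  if (is.null(times)) stop("input carries no sampling times")
  classes <- phase_classes(times, period, delta_t)
  cc <- as.integer(round(period / delta_t))
  n <- length(times)
  shared_null <- .umbrella_null(seq_len(n), classes, cc, n_perm, seed)
  res <- lapply(seq_len(nrow(v$values)), function(i) {
    r <- rain_like_test(v$values[i, ], times, period, delta_t, n_perm, seed,
                        null_stats = shared_null)
    data.frame(taxon_id = v$taxon_ids[i], statistic = r$statistic,
               p_value = r$p_value, peak_phase_class = r$peak_phase_class)
  })
  out <- do.call(rbind, res)
  out$q_rejected <- bh_fdr(out$p_value, alpha)
  out$n_permutations <- as.integer(n_perm)
  out$seed <- as.integer(seed)
  out
}
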