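#' Design for a synthetic diel count table
#'
#' Describes the generative model behind [gen_diel_table()]: per-taxon latent
#' log-abundances with an optional 24-h cosine signal, a linear trend and
#' i.i.d. Gaussian noise, turned into counts by a per-sample multinomial
#' draw over the softmax of the latent values. Defaults emulate a 3-day
#' field campaign sampled every 4 h (19 time points).
#'
#' @param n_taxa number of taxa (default 100).
#' @param frac_periodic fraction of taxa given a cosine signal (floor rule;
#'   default 0.2).
#' @param amplitude cosine amplitude on the log scale (default 1, i.e. twice
#'   the default noise sd).
#' @param period cycle length in hours (default 24).
#' @param peak_phases per-taxon peak hours; default drawn uniformly on
#'   `[0, period)`.
#' @param trend_slopes per-taxon linear slopes (log-scale per hour); default
#'   drawn `N(0, 0.01)`.
#' @param noise_sd log-scale noise standard deviation (default 0.5).
#' @param baseline_sd sd of the per-taxon baseline log-abundances (default 2,
#'   giving a realistic spread of rare and dominant taxa).
#' @param depth reads per sample (default 50000).
#' @param times sampling times in hours (default `seq(0, 72, 4)`).
#' @param seed integer seed.
#' @return list of class `diel_design`.
#' @export
diel_design <- function(n_taxa = 100L, frac_periodic = 0.2, amplitude = 1,
                        period = 24, peak_phases = NULL, trend_slopes = NULL,
                        noise_sd = 0.5, baseline_sd = 2, depth = 50000L,
                        times = seq(0, 72, by = 4), seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  if (frac_periodic < 0 || frac_periodic > 1)
    stop("frac_periodic must lie in [0, 1]")
  if (n_taxa < 1L) stop("need at least one taxon")
  structure(list(n_taxa = as.integer(n_taxa), frac_periodic = frac_periodic,
                 amplitude = amplitude, period = period,
                 peak_phases = peak_phases, trend_slopes = trend_slopes,
                 noise_sd = noise_sd, baseline_sd = baseline_sd,
                 depth = as.integer(depth), times = times,
                 seed = as.integer(seed)),
            class = "diel_design")
}

#' Generate a synthetic diel count table
#'
#' Latent log-abundance of taxon i at time t:
#' `a_i(t) = baseline_i + amplitude * cos(2 pi (t - peak_i)/period) * [i periodic]
#' + slope_i * t + noise`, with the first `floor(frac_periodic * n_taxa)`
#' taxa periodic. Counts are multinomial per sample with total `depth` over
#' `softmax(a(t))`, so every column sums exactly to the depth and the data
#' carry the compositional negative-correlation structure of real sequence
#' counts. Deterministic given the design seed.
#'
#' @param design a [diel_design()].
#' @return a [count_table()] with attribute `periodic_taxa` (logical vector
#'   marking the planted taxa) and `design`.
#' @export
gen_diel_table <- function(design = diel_design()) {
  stopifnot(inherits(design, "diel_design"))
  set.seed(design$seed)
  n <- design$n_taxa
  tt <- design$times
  n_per <- floor(design$frac_periodic * n)
  periodic <- seq_len(n) <= n_per
  peaks <- design$peak_phases %||% stats::runif(n, 0, design$period)
  slopes <- design$trend_slopes %||% stats::rnorm(n, 0, 0.01)
  baseline <- stats::rnorm(n, 0, design$baseline_sd)
  a <- baseline +
    design$amplitude * periodic * cos(2 * pi * outer(-peaks, tt, "+") /
                                        design$period) +
    outer(slopes, tt) +
    matrix(stats::rnorm(n * length(tt), 0, design$noise_sd), n, length(tt))
  counts <- apply(a, 2L, function(col) {
    p <- exp(col - max(col))
    as.numeric(stats::rmultinom(1L, design$depth, p / sum(p)))
  })
  ct <- count_table(counts,
                    taxon_ids = sprintf("taxon%03d", seq_len(n)),
                    sample_ids = sprintf("t%05.1fh", tt),
                    times = tt)
  attr(ct, "periodic_taxa") <- periodic
  attr(ct, "design") <- design
  ct
}

#' Generate an ensemble of independent random walks
#'
#' `x(t + 1) = x(t) + eps`, `eps ~ N(0, 1)`, all walks starting at 0:
#' the canonical demonstration that autocorrelated series produce spurious
#' pairwise correlations despite having no underlying interactions.
#'
#' @param n_walks number of walks (>= 2).
#' @param n_steps number of unit steps (>= 10).
#' @param seed integer seed.
#' @return object of class `random_walk_ensemble`: list with `walks`
#'   (`n_walks x (n_steps + 1)`, first column zero) and `seed`.
#' @export
gen_random_walks <- function(n_walks, n_steps, seed = 1L) {
  if (n_walks < 2L) stop("need >= 2 walks")
  if (n_steps < 10L) stop("need >= 10 steps")
  set.seed(seed)
  inc <- matrix(stats::rnorm(n_walks * n_steps), n_walks, n_steps)
  walks <- cbind(0, t(apply(inc, 1L, cumsum)))
  structure(list(n_walks = as.integer(n_walks), n_steps = as.integer(n_steps),
                 walks = walks, seed = as.integer(seed)),
            class = "random_walk_ensemble")
}

# two-sided Pearson-correlation p-values for all row pairs (t approximation)
.pearson_pairs_p <- function(m) {
  keep <- apply(m, 1L, stats::sd) > 0
  dropped <- sum(!keep)
  if (dropped) warning(dropped, " constant series excluded")
  m <- m[keep, , drop = FALSE]
  n <- ncol(m)
  r <- stats::cor(t(m))
  rv <- r[upper.tri(r)]
  rv <- pmin(pmax(rv, -1 + 1e-15), 1 - 1e-15)
  tstat <- rv * sqrt((n - 2) / (1 - rv^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Spurious-correlation summary for a random-walk ensemble
#'
#' Tests every pair of walks for Pearson correlation (standard two-sided
#' t approximation), both on the raw walks and on their first-difference
#' residuals, and reports the fraction of pairs significant at `alpha` in
#' each case. Raw walks are autocorrelated and strongly inflate the
#' apparent significance rate; the i.i.d. residuals sit at the nominal
#' level.
#'
#' @param e a `random_walk_ensemble`.
#' @param alpha significance level in `(0, 1)`.
#' @return list with `frac_sig_walks` and `frac_sig_residuals`.
#' @export
spurious_correlation_summary <- function(e, alpha = 0.05) {
  stopifnot(inherits(e, "random_walk_ensemble"))
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  p_walk <- .pearson_pairs_p(e$walks)
  resid <- t(diff(t(e$walks)))
  p_res <- .pearson_pairs_p(resid)
  list(frac_sig_walks = mean(p_walk < alpha | alpha == 1),
       frac_sig_residuals = mean(p_res < alpha | alpha == 1))
}
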