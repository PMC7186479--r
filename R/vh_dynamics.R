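#' Construct a virus-host community
#'
#' Life-history traits and infection network of a Lotka-Volterra
#' virus-microbe community: host growth rates `r` (1/h), a community-wide
#' carrying capacity `K` (cells/ml), virus decay rates `m` (1/h), a binary
#' infection matrix `M` (hosts x viruses), adsorption rates `phi` (ml/h) and
#' burst sizes `beta` (virions per lysis).
#'
#' @param r host growth rates, length `N_H`.
#' @param K carrying capacity scalar.
#' @param m virus decay rates, length `N_V`.
#' @param M binary `N_H x N_V` infection matrix.
#' @param phi,beta `N_H x N_V` adsorption rates and burst sizes.
#' @param seed integer recorded for provenance.
#' @return object of class `vh_community`.
#' @export
vh_community <- function(r, K, m, M, phi, beta, seed = NA_integer_) {
  M <- as.matrix(M); phi <- as.matrix(phi); beta <- as.matrix(beta)
  n_h <- length(r); n_v <- length(m)
  if (!all(dim(M) == c(n_h, n_v))) stop("M must be N_H x N_V")
  if (!all(dim(phi) == c(n_h, n_v)) || !all(dim(beta) == c(n_h, n_v)))
    stop("phi and beta must be N_H x N_V")
  if (!all(M %in% c(0, 1))) stop("M must be binary")
  if (any(r <= 0) || K <= 0 || any(m <= 0) || any(phi <= 0) || any(beta <= 1))
    stop("traits must be positive (burst sizes > 1)")
  if (n_v > 0 && any(colSums(M) == 0))
    stop("every virus must infect at least one host")
  if (n_v > 0 && any(rowSums(M) == 0))
    stop("every host must be infected by at least one virus")
  structure(list(N_H = n_h, N_V = n_v, r = r, K = K, m = m, M = M,
                 phi = phi, beta = beta, seed = seed),
            class = "vh_community")
}

#' @export
print.vh_community <- function(x, ...) {
  cat("vh_community: ", x$N_H, " hosts, ", x$N_V, " viruses, K = ",
      format(x$K), " cells/ml\n", sep = "")
  cat("infections: ", sum(x$M), " of ", x$N_H * x$N_V, " possible\n", sep = "")
  invisible(x)
}

#' Coexistence equilibrium of a square virus-host community
#'
#' For `N_H = N_V` the steady state solves the virus equations for the host
#' densities, `(M * phi * beta)^T H* = m`, and the host equations for the
#' virus densities, `(M * phi) V* = r (1 - sum(H*)/K)`. Returns `NULL` when
#' the weighted network is singular or any component is non-positive (no
#' feasible coexistence point).
#'
#' @param c a [vh_community()].
#' @return list with `H_star`, `V_star`, or `NULL`.
#' @export
vh_equilibrium <- function(c) {
  stopifnot(inherits(c, "vh_community"))
  if (c$N_H != c$N_V) stop("equilibrium construction requires N_H = N_V")
  mw <- c$M * c$phi * c$beta
  h_star <- tryCatch(solve(t(mw), c$m), error = function(e) NULL)
  if (is.null(h_star) || any(!is.finite(h_star)) || any(h_star <= 0))
    return(NULL)
  growth <- c$r * (1 - sum(h_star) / c$K)
  v_star <- tryCatch(solve(c$M * c$phi, growth), error = function(e) NULL)
  if (is.null(v_star) || any(!is.finite(v_star)) || any(v_star <= 0))
    return(NULL)
  list(H_star = as.numeric(h_star), V_star = as.numeric(v_star))
}

#' Randomly sample a coexisting virus-host community
#'
#' Builds a nested infection network (virus `j` infects hosts `1..j`) with
#' adsorption rates and burst sizes drawn log-uniformly within biologically
#' plausible ranges (marine-virus orders of magnitude by default). A
#' strictly positive coexistence equilibrium is guaranteed by construction:
#' target equilibrium abundances `H*`, `V*` are drawn log-uniformly and the
#' remaining traits are set from the steady-state identities,
#' `m = (M phi beta)' H*` and `r = (M phi) V* / (1 - sum(H*)/K)`, which are
#' positive whenever the targets are. Candidates whose derived growth or
#' decay rates leave the plausibility bounds in `trait_ranges` are rejected
#' and redrawn. This enforces feasibility, not local stability (see
#' [vh_stability()] for the Jacobian check).
#'
#' @param N_H,N_V numbers of host and virus types; the equilibrium
#'   construction requires `N_H = N_V` (a pure-host community `N_V = 0` is
#'   also allowed).
#' @param seed integer seed.
#' @param trait_ranges named list with `c(min, max)` sampling ranges for
#'   `phi` (ml/h) and `beta`, acceptance bounds for the derived `r` (1/h)
#'   and `m` (1/h), scalar `K` (cells/ml), and target ranges `H_star`,
#'   `V_star` (per-type equilibrium densities).
#' @param max_tries rejection-sampling cap (default 1000).
#' @return a [vh_community()] with a guaranteed positive equilibrium.
#' @export
sample_community <- function(N_H, N_V = N_H, seed = 1L,
                             trait_ranges = list(r = c(0.01, 10),
                                                 m = c(0.001, 1),
                                                 phi = c(1e-9, 1e-7),
                                                 beta = c(10, 100),
                                                 K = 1e7,
                                                 H_star = c(1e4, 1e5),
                                                 V_star = c(1e6, 1e7)),
                             max_tries = 1000L) {
  runif_log <- function(n, range)
    exp(stats::runif(n, log(range[1]), log(range[2])))
  set.seed(seed)
  if (N_V == 0) {
    r <- runif_log(N_H, c(0.1, 1))
    com <- structure(list(N_H = N_H, N_V = 0L, r = r, K = trait_ranges$K,
                          m = numeric(0), M = matrix(0, N_H, 0),
                          phi = matrix(0, N_H, 0), beta = matrix(0, N_H, 0),
                          seed = as.integer(seed)),
                     class = "vh_community")
    return(com)
  }
  if (N_H != N_V) stop("square-equilibrium construction requires N_H = N_V")
  nested <- outer(seq_len(N_H), seq_len(N_V), "<=") * 1  # virus j: hosts 1..j
  k_cap <- trait_ranges$K
  for (try in seq_len(max_tries)) {
    phi <- matrix(runif_log(N_H * N_V, trait_ranges$phi), N_H, N_V)
    beta <- matrix(runif_log(N_H * N_V, trait_ranges$beta), N_H, N_V)
    h_star <- runif_log(N_H, trait_ranges$H_star)
    v_star <- runif_log(N_V, trait_ranges$V_star)
    if (sum(h_star) >= k_cap) next
    m <- as.numeric(t(nested * phi * beta) %*% h_star)
    r <- as.numeric((nested * phi) %*% v_star) / (1 - sum(h_star) / k_cap)
    if (any(m < trait_ranges$m[1]) || any(m > trait_ranges$m[2])) next
    if (any(r < trait_ranges$r[1]) || any(r > trait_ranges$r[2])) next
    com <- vh_community(r = r, K = k_cap, m = m, M = nested,
                        phi = phi, beta = beta, seed = as.integer(seed))
    if (!is.null(vh_equilibrium(com))) return(com)
  }
  stop(max_tries, " consecutive rejections; widen the trait ranges")
}

#' Jacobian spectral abscissa at the coexistence equilibrium
#'
#' Optional local-stability diagnostic: the largest real part of the
#' Jacobian eigenvalues at `(H*, V*)`. Negative means locally stable;
#' values near zero indicate the neutral oscillations typical of
#' Lotka-Volterra interiors.
#'
#' @param c a [vh_community()] with `N_H = N_V`.
#' @return scalar spectral abscissa, or `NA` if no equilibrium exists.
#' @export
vh_stability <- function(c) {
  eq <- vh_equilibrium(c)
  if (is.null(eq)) return(NA_real_)
  h <- eq$H_star; v <- eq$V_star
  n_h <- c$N_H; n_v <- c$N_V
  mp <- c$M * c$phi
  mpb <- c$M * c$phi * c$beta
  # d(Hdot_i)/dH_i' and cross blocks at equilibrium
  a11 <- -outer(h, rep(1, n_h)) * (c$r / c$K)   # -r_i H_i / K for every i'
  diag(a11) <- diag(a11) + c$r * (1 - sum(h) / c$K) - as.numeric(mp %*% v)
  a12 <- -h * mp                                 # -H_i (M phi)_ij
  a21 <- t(mpb) * v                              # V_j (M phi beta)_ij
  a22 <- diag(as.numeric(t(mpb) %*% h) - c$m, n_v, n_v)
  jac <- rbind(cbind(a11, a12), cbind(a21, a22))
  max(Re(eigen(jac, only.values = TRUE)$values))
}

#' Simulate virus-host Lotka-Volterra dynamics
#'
#' Integrates the coupled host/virus equations with an adaptive-step solver
#' (lsoda) at the requested relative tolerance and returns densities at the
#' requested sample times. Hosts grow logistically against the shared
#' carrying capacity and die by lysis; viruses grow by burst release and
#' decay at rate `m`.
#'
#' @param c a [vh_community()].
#' @param H0,V0 positive initial densities (cells/ml, virions/ml).
#' @param t_end final time in hours.
#' @param sample_times output times within `[0, t_end]`; default hourly.
#' @param rel_tol relative solver tolerance (default 1e-8).
#' @return object of class `vh_timeseries`: list with `times`, `H`
#'   (`N_H x T`), `V` (`N_V x T`), `community`.
#' @export
simulate_vh <- function(c, H0, V0, t_end = 200,
                        sample_times = seq(0, t_end, by = 1),
                        rel_tol = 1e-8) {
  stopifnot(inherits(c, "vh_community"))
  if (length(H0) != c$N_H || length(V0) != c$N_V)
    stop("initial conditions do not match community dimensions")
  if (any(H0 < 0) || any(V0 < 0)) stop("initial densities must be non-negative")
  if (min(sample_times) < 0 || max(sample_times) > t_end + 1e-9)
    stop("sample_times must lie within [0, t_end]")
  mp <- c$M * c$phi
  mpb <- c$M * c$phi * c$beta
  n_h <- c$N_H
  rhs <- function(t, y, parms) {
    h <- y[seq_len(n_h)]
    v <- y[-seq_len(n_h)]
    dh <- c$r * h * (1 - sum(h) / c$K) - h * as.numeric(mp %*% v)
    dv <- v * as.numeric(t(mpb) %*% h) - c$m * v
    list(c(dh, dv))
  }
  times <- sort(unique(c(0, sample_times)))
  sol <- deSolve::ode(y = c(H0, V0), times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rel_tol,
                      atol = rel_tol * c$K * 1e-6)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE solver failed; last state: ",
         paste(format(sol[nrow(sol), ]), collapse = ", "))
  keep <- match(round(sample_times, 9), round(sol[, 1L], 9))
  y <- t(sol[keep, -1L, drop = FALSE])
  y[y < 0 & y > -1e-9 * c$K] <- 0
  if (any(y < 0)) stop("negative densities beyond solver tolerance")
  structure(list(times = sample_times,
                 H = y[seq_len(n_h), , drop = FALSE],
                 V = y[-seq_len(n_h), , drop = FALSE],
                 community = c),
            class = "vh_timeseries")
}

#' @export
print.vh_timeseries <- function(x, ...) {
  cat("vh_timeseries: ", x$community$N_H, " hosts + ", x$community$N_V,
      " viruses at ", length(x$times), " times (",
      format(min(x$times)), "-", format(max(x$times)), " h)\n", sep = "")
  invisible(x)
}
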