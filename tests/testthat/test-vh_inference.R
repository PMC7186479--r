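test_that("central log-differences are exact for exponentials", {
  tt <- seq(0, 10, 0.5)
  ts <- structure(list(times = tt,
                       H = matrix(runif(2 * 21, 1, 2), 2, 21),
                       V = rbind(3 * exp(0.12 * tt), 7 * exp(-0.3 * tt))),
                  class = "vh_timeseries")
  inp <- percapita_derivatives(ts)
  expect_equal(inp$W[1, ], rep(0.12, 19), tolerance = 1e-12)
  expect_equal(inp$W[2, ], rep(-0.3, 19), tolerance = 1e-12)
  expect_equal(ncol(inp$H), 19L)

  const <- structure(list(times = 0:4, H = matrix(1, 1, 5),
                          V = matrix(2, 1, 5)), class = "vh_timeseries")
  expect_equal(percapita_derivatives(const)$W, matrix(0, 1, 3))

  three <- structure(list(times = 0:2, H = matrix(1, 1, 3),
                          V = matrix(exp(0:2), 1, 3)), class = "vh_timeseries")
  expect_equal(ncol(percapita_derivatives(three)$W), 1L)

  bad <- structure(list(times = 0:3, H = matrix(1, 1, 4),
                        V = matrix(c(1, 0, 1, 1), 1, 4)),
                   class = "vh_timeseries")
  expect_error(percapita_derivatives(bad), "non-positive")
})

test_that("noiseless generative data are recovered exactly at lambda = 0", {
  set.seed(81)
  h <- matrix(runif(2 * 30, 1e4, 1e5), 2, 30)
  m_true <- matrix(c(2e-6, 0, 3e-7, 1e-6), 2, 2)
  decay <- c(0.05, 0.02)
  w <- t(m_true) %*% h - decay
  inp <- structure(list(H = h, W = w, sample_times = 1:30),
                   class = "inference_input")
  fit <- infer_network(inp, lambda = 0)
  expect_equal(fit$M_tilde, m_true, tolerance = 1e-6)
  expect_equal(fit$m_hat, decay, tolerance = 1e-6)
  expect_lt(fit$kkt_residual, 1e-6)
  expect_equal(fit$solver_status, "optimal")
})

test_that("a large enough penalty empties the network", {
  set.seed(83)
  h <- matrix(runif(3 * 20, 10, 100), 3, 20)
  w <- matrix(rnorm(2 * 20, -0.5, 0.1), 2, 20)
  inp <- structure(list(H = h, W = w, sample_times = 1:20),
                   class = "inference_input")
  lam <- 2 * max(abs(h %*% t(w)))
  fit <- infer_network(inp, lambda = lam, decay_floor = 1e-6)
  expect_true(all(fit$M_tilde == 0))
  expect_equal(fit$m_hat, pmax(1e-6, -rowMeans(w)), tolerance = 1e-9)
})

test_that("the solution is invariant to sample ordering and matches an
           independent box-constrained optimizer", {
  set.seed(85)
  h <- matrix(runif(3 * 25, 1, 10), 3, 25)
  m_true <- matrix(runif(6, 0, 0.5) * rbinom(6, 1, 0.7), 3, 2)
  w <- t(m_true) %*% h - c(0.3, 0.1) + matrix(rnorm(50, 0, 0.05), 2, 25)
  inp <- structure(list(H = h, W = w, sample_times = 1:25),
                   class = "inference_input")
  lam <- 0.5
  fit <- infer_network(inp, lambda = lam)

  perm <- sample(25)
  inp_p <- structure(list(H = h[, perm], W = w[, perm],
                          sample_times = (1:25)[perm]),
                     class = "inference_input")
  fit_p <- infer_network(inp_p, lambda = lam)
  expect_equal(fit_p$M_tilde, fit$M_tilde, tolerance = 1e-9)
  expect_equal(fit_p$m_hat, fit$m_hat, tolerance = 1e-9)

  # oracle: L-BFGS-B on the same convex objective (smooth on the feasible set)
  for (j in 1:2) {
    obj <- function(z) {
      sum((w[j, ] - as.numeric(t(h) %*% z[1:3]) + z[4])^2) + lam * sum(z[1:3])
    }
    ora <- optim(c(rep(0.1, 3), 0.1), obj, method = "L-BFGS-B",
                 lower = c(0, 0, 0, 1e-6),
                 control = list(factr = 1e3, maxit = 2000))
    ours <- sum((w[j, ] - as.numeric(t(h) %*% fit$M_tilde[, j]) +
                   fit$m_hat[j])^2) + lam * sum(fit$M_tilde[, j])
    expect_lte(ours, ora$value + 1e-6)
  }
})

test_that("sparsity is non-increasing in lambda", {
  ex <- vh_experiment(seed = 21, dt = 2, t_end = 200, noise_sdlog = 0.02)
  nz <- sapply(10^seq(-6, 2, 1), function(lam)
    sum(infer_network(ex$input, lambda = lam)$M_tilde > 0))
  expect_true(all(diff(nz) <= 0 + 1e-9))
})

test_that("blocked cross-validation selects sensible penalties", {
  # noiseless generative data: the smallest lambda attains the minimum
  set.seed(87)
  h <- matrix(runif(2 * 24, 1e4, 1e5), 2, 24)
  m_true <- matrix(c(2e-6, 1e-7, 0, 1e-6), 2, 2)
  w <- t(m_true) %*% h - c(0.05, 0.02)
  inp <- structure(list(H = h, W = w, sample_times = 1:24),
                   class = "inference_input")
  grid <- 10^seq(-6, 0, 1)
  sel <- select_lambda(inp, grid, folds = 4, seed = 1)
  expect_equal(sel$lambda, min(grid))
  expect_identical(select_lambda(inp, grid, folds = 4, seed = 1), sel)

  # pure-noise response: heavy shrinkage wins
  w_noise <- matrix(rnorm(2 * 24, 0, 1), 2, 24)
  inp_n <- structure(list(H = h, W = w_noise, sample_times = 1:24),
                     class = "inference_input")
  sel_n <- select_lambda(inp_n, grid, folds = 4, seed = 1)
  expect_gte(sel_n$lambda, sort(grid, decreasing = TRUE)[2])
  expect_error(select_lambda(inp, grid, folds = 30), "folds")
})

test_that("recovery metrics report perfect and degenerate cases correctly", {
  com <- sample_community(3, 3, seed = 31)
  perfect <- structure(list(M_tilde = com$M * com$phi * com$beta,
                            m_hat = com$m, lambda = 0,
                            objective_value = 0, solver_status = "optimal"),
                       class = "inferred_network")
  met <- recovery_metrics(com, perfect)
  expect_equal(met$precision, 1)
  expect_equal(met$recall, 1)
  expect_equal(met$f1, 1)
  expect_equal(met$frobenius_rel_error, 0)
  expect_equal(met$decay_rel_error, 0)

  empty <- perfect
  empty$M_tilde <- matrix(0, 3, 3)
  expect_equal(recovery_metrics(com, empty)$recall, 0)
  wrong <- perfect
  wrong$M_tilde <- matrix(0, 2, 2)
  expect_error(recovery_metrics(com, wrong), "dimensions")
})
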