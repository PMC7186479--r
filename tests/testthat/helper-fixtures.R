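# Shared fixture builders; everything is generated in code, nothing on disk.

# small deterministic count table
toy_table <- function() {
  count_table(matrix(c(2, 0, 1,
                       1, 1, 0,
                       5, 3, 4), nrow = 3, byrow = TRUE),
              taxon_ids = c("t1", "t2", "t3"),
              sample_ids = c("s1", "s2", "s3"),
              times = c(0, 4, 8))
}

random_table <- function(n_taxa, n_samples, seed = 1, lambda = 20) {
  set.seed(seed)
  count_table(matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples),
              times = seq(0, by = 4, length.out = n_samples))
}

# two tight point pairs far apart; items in rows
separated_pairs <- function() {
  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  rownames(pts) <- paste0("p", 1:4)
  pts
}

# three 2-D blobs with separation ratio >> 5
three_blobs <- function(seed = 1, per = 15, gap = 10, sd = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(per * 2, 0, sd), per, 2),
        matrix(rnorm(per * 2, gap, sd), per, 2),
        matrix(rnorm(per * 2, 2 * gap, sd), per, 2))
}

# planted truth for the blob fixture
blob_labels <- function(per = 15) rep(0:2, each = per)

# brute-force Euclidean distance oracle (double loop)
dist_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  d
}

# Procrustes residual after optimal rotation/reflection/translation/identity
# scaling; used to compare configurations up to rigid motion
procrustes_residual <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  rot <- s$u %*% t(s$v)
  sqrt(sum((yc %*% rot - xc)^2))
}

# simulate a perturbed 10x10 community and return inference input + truth
vh_experiment <- function(seed, dt = 1, t_end = 600, pert = 0.5,
                          noise_sdlog = 0) {
  com <- sample_community(10, 10, seed = seed)
  eq <- vh_equilibrium(com)
  set.seed(seed + 1000)
  ts <- simulate_vh(com,
                    eq$H_star * runif(10, 1 - pert, 1 + pert),
                    eq$V_star * runif(10, 1 - pert, 1 + pert),
                    t_end, seq(0, t_end, by = dt))
  if (noise_sdlog > 0) {
    ts$H <- ts$H * exp(matrix(rnorm(length(ts$H), 0, noise_sdlog), nrow(ts$H)))
    ts$V <- ts$V * exp(matrix(rnorm(length(ts$V), 0, noise_sdlog), nrow(ts$V)))
  }
  list(community = com, ts = ts, input = percapita_derivatives(ts))
}
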