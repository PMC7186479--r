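# brute-force best 2-partition by total dissimilarity-to-best-medoid
best_two_partition <- function(dm) {
  n <- nrow(dm)
  best <- NULL
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    cost_of <- function(idx) min(sapply(idx, function(c) sum(dm[idx, c])))
    cost <- cost_of(which(grp)) + cost_of(which(!grp))
    if (is.null(best) || cost < best$cost) best <- list(cost = cost, grp = grp)
  }
  best
}

test_that("pam recovers separated pairs and matches brute-force enumeration", {
  pts <- separated_pairs()
  d <- euclidean_dist(t(pts))
  res <- pam(d, 2)
  expect_setequal(which(res$labels == res$labels[1]), 1:2)
  ora <- best_two_partition(d$values)
  same_side <- res$labels == res$labels[1]
  expect_true(all(same_side == ora$grp) || all(same_side == !ora$grp))

  # k = n-1: the only 2-item cluster is the closest pair; cost matches the
  # exhaustive medoid-subset oracle
  res3 <- pam(d, 3)
  twos <- which(tabulate(res3$labels + 1L) == 2)
  expect_length(twos, 1L)
  cost <- function(med) sum(apply(d$values[, med, drop = FALSE], 1, min))
  all_costs <- apply(combn(4, 3), 2, cost)
  got <- cost(match(res3$medoid_ids, rownames(pts)))
  expect_equal(got, min(all_costs), tolerance = 1e-12)
})

test_that("pam agrees with the cluster-package oracle on random blobs", {
  skip_if_not_installed("cluster")
  set.seed(19)
  pts <- rbind(matrix(rnorm(16), 8, 2), matrix(rnorm(16) + 8, 8, 2))
  d <- euclidean_dist(t(pts))
  ours <- pam(d, 2)
  ora <- cluster::pam(as.dist(d$values), 2)
  expect_true(all((ours$labels == ours$labels[1]) ==
                    (ora$clustering == ora$clustering[1])))
  expect_setequal(match(ours$medoid_ids, rownames(d$values)),
                  as.integer(ora$id.med))
})

test_that("a duplicated medoid joins its twin's cluster", {
  pts <- separated_pairs()
  res0 <- pam(euclidean_dist(t(pts)), 2)
  med1 <- res0$medoid_ids[1]
  aug <- rbind(pts, dup = pts[med1, ])
  res <- pam(euclidean_dist(t(aug)), 2)
  expect_equal(unname(res$labels[5]),
               unname(res$labels[match(med1, rownames(aug))]))
  expect_true(all(res$labels[1:4] == res0$labels) ||
                all(res$labels[1:4] == 1 - res0$labels))
})

test_that("agglomerative clustering recovers structure under every linkage", {
  pts <- separated_pairs()
  d <- euclidean_dist(t(pts))
  for (link in c("average", "complete", "single")) {
    res <- agglomerative(d, 2, linkage = link)
    expect_setequal(which(res$labels == res$labels[1]), 1:2)
  }
  # k = n-1 merges exactly one closest pair (both pairs tie at 0.1)
  res3 <- agglomerative(d, 3)
  expect_length(unique(res3$labels), 3L)
  expect_true(res3$labels[1] == res3$labels[2] ||
                res3$labels[3] == res3$labels[4])
})

test_that("single linkage chains where complete linkage does not", {
  # slowly widening chain: single linkage strings all but the far point into
  # one cluster; complete linkage breaks the chain in the middle
  x <- matrix(c(0, 1, 2.1, 3.3, 4.6), ncol = 1)
  d <- euclidean_dist(t(x))
  s <- agglomerative(d, 2, linkage = "single")$labels
  co <- agglomerative(d, 2, linkage = "complete")$labels
  expect_length(unique(s[1:4]), 1L)
  expect_false(identical(s, co))
})

test_that("sse matches hand arithmetic and refines monotonically", {
  expect_equal(sse(matrix(c(0, 2), 2, 1), c(0, 0)), 2)
  expect_equal(sse(matrix(c(0, 2), 2, 1), c(0, 1)), 0)  # singletons
  set.seed(29)
  m <- matrix(rnorm(20), 10, 2)
  coarse <- rep(0:1, each = 5)
  fine <- c(rep(0, 3), rep(2, 2), rep(1, 3), rep(3, 2))  # nested refinement
  expect_lte(sse(m, fine), sse(m, coarse) + 1e-12)
})

test_that("calinski-harabasz matches the hand-worked 4-point instance", {
  x <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  expect_equal(calinski_harabasz(x, c(0, 0, 1, 1)), 20000, tolerance = 1e-9)
  # splitting mid-pair is far worse than splitting at the gap
  expect_lt(calinski_harabasz(x, c(0, 1, 1, 1)),
            calinski_harabasz(x, c(0, 0, 1, 1)) / 100)
  expect_error(calinski_harabasz(x, rep(0, 4)), "requires")
})

test_that("silhouette widths match hand values, oracle, and stay in [-1,1]", {
  d <- euclidean_dist(rbind(c(0, 1, 10, 11)), compare = "samples")
  lab <- c(0, 0, 1, 1)
  expect_equal(silhouette_widths(d, lab, "extrema")[1], 0.9, tolerance = 1e-12)

  # point equidistant between its in-cluster extreme and the other cluster
  d2 <- matrix(0, 3, 3)
  d2[1, 2] <- d2[2, 1] <- 2
  d2[1, 3] <- d2[3, 1] <- 2
  d2[2, 3] <- d2[3, 2] <- 3
  expect_equal(silhouette_widths(d2, c(0, 0, 1), "extrema")[1], 0)

  skip_if_not_installed("cluster")
  set.seed(37)
  for (rep in 1:4) {
    dm <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
    lab8 <- sample(0:2, 8, replace = TRUE)
    if (length(unique(lab8)) < 2) next
    ours <- silhouette_widths(dm, lab8, "standard")
    ora <- cluster::silhouette(lab8 + 1L, dmatrix = dm)[, "sil_width"]
    expect_equal(ours, as.numeric(ora), tolerance = 1e-12)
    expect_true(all(ours >= -1 & ours <= 1))
    expect_true(all(silhouette_widths(dm, lab8, "extrema") >= -1))
  }
})

test_that("planted clusters with separation ratio >= 5 are recovered exactly", {
  m <- three_blobs(seed = 2)
  d <- euclidean_dist(t(m))
  truth <- blob_labels()
  for (res in list(pam(d, 3), agglomerative(d, 3))) {
    agree <- table(res$labels, truth)
    expect_equal(sum(apply(agree, 1, max)), length(truth))
  }
})

test_that("sweep_k finds the planted k by CH and SSE decreases in k", {
  m <- three_blobs(seed = 3)
  d <- euclidean_dist(t(m))
  tab <- sweep_k(m, d, 2:6, method = "pam")
  expect_equal(tab$k[tab$best_ch], 3)
  expect_true(all(diff(tab$sse) <= 1e-9))
  expect_error(sweep_k(m, d, 2:50, method = "pam"), "k_range")
})

test_that("pam swap phase never increases cost on random instances", {
  set.seed(53)
  for (rep in 1:3) {
    dm <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
    res <- pam(dm, 3)
    cost <- function(med) sum(apply(dm[, med, drop = FALSE], 1, min))
    meds <- match(res$medoid_ids, as.character(1:12))
    final <- cost(meds)
    # final cost is no worse than any single swap away
    for (mi in seq_along(meds)) for (cand in setdiff(1:12, meds)) {
      trial <- meds
      trial[mi] <- cand
      expect_gte(cost(trial), final - 1e-12)
    }
  }
}
)
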