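test_that("Manhattan dissimilarity matches hand computations", {
  a <- build_connectome(matrix(c(2.0, 2.5), ncol = 1,
                               dimnames = list(c("r1", "r2"), "f")))
  expect_equal(a["r1", "r2"], 0.5)
  expect_equal(diag(unclass(a)), c(r1 = 0, r2 = 0))

  x <- matrix(c(2.0, 0.1,
                2.5, 0.3,
                3.0, 0.2), nrow = 3, byrow = TRUE,
              dimnames = list(c("r1", "r2", "r3"), c("f1", "f2")))
  a <- build_connectome(x)
  expect_equal(a["r1", "r2"], 0.7)
  expect_equal(a["r1", "r3"], 1.1)
  expect_equal(a["r2", "r3"], 0.6)
  expect_true(isSymmetric(unclass(a)))

  same <- matrix(rep(c(2.2, 0.4), each = 5), nrow = 5)
  expect_true(all(build_connectome(same) == 0))
})

test_that("connectome equals a double-loop distance oracle on random tables", {
  for (seed in 1:20) {
    set.seed(seed)
    q <- sample(2:10, 1)
    f <- sample(1:3, 1)
    x <- matrix(runif(q * f, 1, 4), q, f)
    a <- build_connectome(x)
    oracle <- matrix(0, q, q)
    for (i in 1:q) for (j in 1:q) oracle[i, j] <- sum(abs(x[i, ] - x[j, ]))
    expect_equal(unclass(a), oracle, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("row permutation permutes the connectome consistently", {
  set.seed(4)
  x <- matrix(runif(8 * 2, 1, 4), 8, 2,
              dimnames = list(sprintf("r%d", 1:8), c("a", "b")))
  a <- build_connectome(x)
  perm <- sample(8)
  a_perm <- build_connectome(x[perm, ])
  expect_equal(unclass(a_perm), unclass(a)[perm, perm], tolerance = 1e-12)
})

test_that("non-finite features are rejected naming the ROI", {
  x <- matrix(c(2, NA, 3), ncol = 1, dimnames = list(c("ra", "rb", "rc"), "f"))
  expect_error(build_connectome(x), "rb")
})

test_that("pooled weights have the expected length and order", {
  set.seed(2)
  a1 <- build_connectome(matrix(runif(3, 1, 3), ncol = 1))
  expect_length(pool_weights(list(a1)), 3)
  # row-major upper triangle of a 3x3: (1,2), (1,3), (2,3)
  expect_equal(pool_weights(list(a1)),
               c(a1[1, 2], a1[1, 3], a1[2, 3]), ignore_attr = TRUE)
  expect_equal(pool_weights(list(a1, a1)),
               rep(pool_weights(list(a1)), 2), ignore_attr = TRUE)
  a2 <- build_connectome(matrix(runif(4, 1, 3), ncol = 1))
  expect_error(pool_weights(list(a1, a2)), "same node count")
})

test_that("pooled length follows the count formula on a cohort", {
  cohort <- built_cohort(tiny_cohort_config(seed = 2, q = 9))
  w <- pool_weights(cohort)
  expect_length(w, nrow(cohort) * 9 * 8 / 2)
  expect_true(all(w >= 0))
})

test_that("percentile cutoff interpolates order statistics", {
  expect_equal(percentile_cutoff(1:10, 0.7), 7.3)
  expect_equal(percentile_cutoff(rep(3.5, 20), 0.1), 3.5)
  expect_equal(percentile_cutoff(rep(3.5, 20), 0.9), 3.5)
  expect_equal(percentile_cutoff(c(1, 2, 3, 4, 5), 0.5), 3)  # median
  expect_error(percentile_cutoff(1:10, 0), "tau")
  expect_error(percentile_cutoff(1:10, 1), "tau")
  expect_error(percentile_cutoff(numeric(0), 0.5), "empty")
})

test_that("binarization keeps ties and honours the cutoff", {
  # 5-node connectome whose upper triangle is exactly 1..10
  a <- matrix(0, 5, 5)
  a[upper.tri(a)] <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("r%d", 1:5), sprintf("r%d", 1:5))
  phi <- percentile_cutoff(a[upper.tri(a)], 0.7)
  g <- binarize(a, phi, tau = 0.7)
  expect_equal(igraph::ecount(g), 3)          # exactly the weights {8, 9, 10}
  kept <- sort(a[upper.tri(a)][a[upper.tri(a)] >= phi])
  expect_equal(kept, c(8, 9, 10))

  expect_equal(igraph::ecount(binarize(a, 0)), 10)       # complete graph
  expect_equal(igraph::ecount(binarize(a, max(a) + 1)), 0)
  # tie at the cutoff is retained
  expect_equal(igraph::ecount(binarize(a, 10)), 1)
  expect_error(binarize(a, -1), "phi")
})

test_that("edge sets are nested across increasing tau", {
  cohort <- built_cohort(tiny_cohort_config(seed = 13, q = 10))
  pooled <- pool_weights(cohort)
  taus <- c(0.2, 0.5, 0.8)
  for (a in cohort$connectome[1:5]) {
    prev <- NULL
    for (tau in taus) {
      g <- binarize(a, percentile_cutoff(pooled, tau))
      el <- apply(igraph::as_edgelist(g), 1, paste, collapse = "|")
      if (!is.null(prev)) expect_true(all(el %in% prev))
      prev <- el
    }
  }
})

test_that("pooled retention matches 1 - tau and mean density follows", {
  cohort <- built_cohort(tiny_cohort_config(seed = 17, q = 12, scans = 4))
  pooled <- pool_weights(cohort)
  for (tau in c(0.1, 0.5, 0.7, 0.9)) {
    phi <- percentile_cutoff(pooled, tau)
    retained <- mean(pooled >= phi)
    expect_lt(abs(retained - (1 - tau)), 1 / length(pooled) + 1e-12)
    dens <- vapply(cohort$connectome,
                   function(a) graph_density(binarize(a, phi)), numeric(1))
    expect_lt(abs(mean(dens) - (1 - tau)), 0.02)
  }
})

test_that("standardization flag rescales features before the distance", {
  set.seed(6)
  x <- cbind(thick = runif(6, 2, 3), area = runif(6, 100, 900))
  rownames(x) <- sprintf("r%d", 1:6)
  raw <- build_connectome(x)
  std <- build_connectome(x, standardize = TRUE)
  # raw distances are dominated by the large-unit feature; standardized not
  expect_gt(max(raw), 50)
  expect_lt(max(std), 10)
})
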