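fast_metrics_for_test <- function(g) {
  c(BC = avg_betweenness(g), r = graph_assortativity(g),
    T = graph_transitivity(g), Eg = global_efficiency(g),
    Q = graph_modularity(g), D = graph_density(g))
}

complete_graph <- function(n) adj_to_graph(matrix(1, n, n) - diag(n))
path_graph <- function(n) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
  adj_to_graph(adj)
}
star_graph <- function(n) {
  adj <- matrix(0, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- 1
  adj_to_graph(adj)
}

test_that("closed-form metric values on canonical graphs", {
  k4 <- complete_graph(4)
  expect_equal(avg_betweenness(k4), 0)
  expect_equal(graph_transitivity(k4), 1)
  expect_equal(global_efficiency(k4), 1)
  expect_equal(graph_density(k4), 1)
  expect_true(is.na(graph_assortativity(k4)))   # zero degree variance
  expect_equal(graph_modularity(k4), 0)         # single trivial community

  s5 <- star_graph(5)
  expect_equal(graph_assortativity(s5), -1)
  expect_equal(graph_transitivity(s5), 0)
  expect_equal(avg_betweenness(s5), 1.2)        # center C(4,2)=6, leaves 0

  p3 <- path_graph(3)
  expect_equal(global_efficiency(p3), 5 / 6)
  expect_equal(avg_betweenness(p3), 1 / 3)
  expect_equal(graph_density(p3), 2 / 3)

  p4 <- path_graph(4)
  expect_equal(graph_assortativity(p4), -0.5)

  # two disjoint triangles: the two-component partition maximizes Q at 0.5
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1; diag(adj) <- 0
  expect_equal(graph_modularity(adj_to_graph(adj)), 0.5)
  expect_equal(oracle_max_modularity(adj), 0.5)

  # triangle plus a pendant edge: 3 triangles-counts / 5 two-paths
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 3] <- adj[1, 3] <- adj[3, 4] <- 1
  adj <- adj + t(adj) - diag(diag(adj))
  adj[adj > 1] <- 1
  expect_equal(graph_transitivity(adj_to_graph(adj)), 0.6)
})

test_that("degenerate graphs are flagged, not zeroed", {
  empty <- graph_from_edges(integer(0), 4)
  v <- metric_vector(empty)
  expect_equal(v$BC, 0)
  expect_true(is.na(v$r))
  expect_equal(v$T, 0)
  expect_equal(v$Eg, 0)
  expect_true(is.na(v$Q))
  expect_equal(v$D, 0)

  two <- graph_from_edges(integer(0), 2)
  expect_equal(global_efficiency(two), 0)
  expect_equal(avg_betweenness(two), 0)
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(42)
  for (i in 1:25) {
    q <- sample(4:9, 1)
    adj <- random_adjacency(q, p = runif(1, 0.2, 0.7))
    g <- adj_to_graph(adj)
    expect_equal(graph_density(g), oracle_density(adj), tolerance = 1e-9)
    expect_equal(graph_transitivity(g), oracle_transitivity(adj),
                 tolerance = 1e-9)
    expect_equal(global_efficiency(g), oracle_efficiency(adj),
                 tolerance = 1e-9)
    expect_equal(avg_betweenness(g), oracle_avg_betweenness(adj),
                 tolerance = 1e-9)
    r <- graph_assortativity(g)
    ro <- oracle_assortativity(adj)
    expect_equal(is.na(r), is.na(ro))
    if (!is.na(r)) expect_equal(r, ro, tolerance = 1e-9)
  }
})

test_that("all six metrics are isomorphism-invariant", {
  set.seed(7)
  for (i in 1:5) {
    adj <- random_adjacency(8, 0.4)
    perm <- sample(8)
    adj_p <- adj[perm, perm]
    a <- fast_metrics_for_test(adj_to_graph(adj))
    b <- fast_metrics_for_test(adj_to_graph(adj_p))
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("metric ranges hold on random binarized scans", {
  cohort <- built_cohort(tiny_cohort_config(seed = 30, q = 14))
  for (tau in c(0.3, 0.7, 0.9)) {
    m <- compute_metrics(cohort, tau = tau, long = FALSE)
    expect_true(all(m$D >= 0 & m$D <= 1))
    expect_true(all(m$T >= 0 & m$T <= 1))
    expect_true(all(m$Eg >= 0 & m$Eg <= 1))
    expect_true(all(is.na(m$r) | (m$r >= -1 & m$r <= 1)))
    expect_true(all(is.na(m$Q) | m$Q <= 1))
    expect_true(all(m$BC >= 0))
  }
})

test_that("density decreases as tau increases", {
  cohort <- built_cohort(tiny_cohort_config(seed = 31, q = 12))
  dens <- vapply(c(0.2, 0.5, 0.8), function(tau) {
    mean(compute_metrics(cohort, tau = tau, long = FALSE)$D)
  }, numeric(1))
  expect_true(all(diff(dens) < 0))
})

test_that("CV summary follows the definition", {
  # three scans with metric values {1, 2, 3}: sd = 1, mean = 2, CV% = 50
  cohort <- built_cohort(tiny_cohort_config(seed = 32, q = 10, scans = 2))
  sweep <- cv_sweep(cohort, taus = c(0.5, 0.7))
  expect_setequal(unique(sweep$metric), metric_names())
  expect_true(all(sweep$cv >= 0, na.rm = TRUE))
  # hand check one cell against its own components
  row <- sweep[which(!is.na(sweep$cv))[1], ]
  expect_equal(row$cv, 100 * row$sd / abs(row$mean))
  # the direct formula on a known vector
  expect_equal(100 * sd(c(1, 2, 3)) / abs(mean(c(1, 2, 3))), 50)
  # negative-mean metric keeps CV nonnegative through |mean|
  r_cells <- sweep[sweep$metric == "r" & !is.na(sweep$cv), ]
  if (nrow(r_cells) > 0) {
    expect_true(all(r_cells$mean < 0))
    expect_true(all(r_cells$cv >= 0))
  }
})
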