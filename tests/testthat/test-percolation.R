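test_that("torus L1 distance wraps, is symmetric and triangle-bounded", {
  expect_identical(torus_l1_distance(c(0, 0), c(0, 0), 8), 0L)
  expect_identical(torus_l1_distance(c(0, 0), c(7, 7), 8), 2L)
  expect_identical(torus_l1_distance(c(0, 0), c(3, 4), 8), 7L)
  expect_error(torus_l1_distance(c(0, 0), c(8, 0), 8), "range")
  set.seed(1)
  for (i in 1:50) {
    N <- sample(3:12, 1)
    a <- c(sample(0:(N - 1), 1), sample(0:(N - 1), 1))
    b <- c(sample(0:(N - 1), 1), sample(0:(N - 1), 1))
    d <- c(sample(0:(N - 1), 1), sample(0:(N - 1), 1))
    expect_identical(torus_l1_distance(a, b, N), torus_l1_distance(b, a, N))
    expect_lte(torus_l1_distance(a, b, N),
               torus_l1_distance(a, d, N) + torus_l1_distance(d, b, N))
    expect_lte(torus_l1_distance(a, b, N), N)
  }
})

test_that("long-edge probability follows c/(N d^alpha), clamped to [0, 1]", {
  expect_equal(long_edge_probability(10, 100, long_edge_model(1, 1)), 0.001)
  expect_equal(long_edge_probability(1, 10, long_edge_model(200, 1, d_min = 1)), 1)
  expect_equal(long_edge_probability(4, 16, long_edge_model(2, 2)), 2 / 256)
  expect_error(long_edge_probability(0, 10, long_edge_model()), "self-loops")
})

test_that("distance counts and expected long degree match exhaustive enumeration", {
  ## every vertex of the 4-torus classified by hand-enumerable distance
  expect_identical(torus_distance_counts(4L), c(4L, 6L, 4L, 1L))
  expect_identical(sum(torus_distance_counts(9L)), 80L)

  expect_equal(expected_long_degree(16, long_edge_model(0)), 0)

  ## brute force over all partner vertices of (0,0) on the 4-torus
  m <- long_edge_model(1, 1)
  brute <- 0
  for (i in 0:3) for (j in 0:3) {
    if (i == 0 && j == 0) next
    d <- min(i, 4 - i) + min(j, 4 - j)
    if (d >= m$d_min) brute <- brute + min(1, 1 / (4 * d))
  }
  expect_equal(expected_long_degree(4, m), brute, tolerance = 1e-12)

  ## continuum limit of the exact enumeration: lambda -> 4 log(2) * c
  expect_equal(expected_long_degree(256, long_edge_model(3)) / 3,
               4 * log(2), tolerance = 0.05)
})

test_that("lambda_to_c inverts the expected long degree", {
  for (lam in c(0.5, 1, 2)) {
    cc <- lambda_to_c(32, lam)
    expect_equal(expected_long_degree(32, long_edge_model(cc)), lam,
                 tolerance = 1e-8)
  }
  expect_equal(lambda_to_c(32, 0), 0)
})

test_that("graph construction is deterministic with the advertised edge content", {
  g0 <- build_graph(8, long_edge_model(0), seed = 1)
  expect_identical(g0$n_long, 0L)
  expect_equal(Matrix::nnzero(g0$adjacency), 4 * 64)   # 2 N^2 undirected edges

  g1 <- build_graph(12, long_edge_model(2), seed = 9)
  g2 <- build_graph(12, long_edge_model(2), seed = 9)
  expect_identical(g1$long_edges, g2$long_edges)
  g3 <- build_graph(12, long_edge_model(2), seed = 10)
  expect_false(identical(g1$long_edges, g3$long_edges))

  ## no self-loops, no duplicates, all long pairs at distance >= d_min
  le <- g1$long_edges
  expect_true(all(le[, 1] != le[, 2]))
  key <- paste(pmin(le[, 1], le[, 2]), pmax(le[, 1], le[, 2]))
  expect_identical(anyDuplicated(key), 0L)
  rc <- function(idx) c((idx - 1) %/% 12, (idx - 1) %% 12)
  dists <- vapply(seq_len(nrow(le)), function(r)
    torus_l1_distance(rc(le[r, 1]), rc(le[r, 2]), 12), integer(1))
  expect_true(all(dists >= 2))
})

test_that("empirical long degree agrees with the enumeration expectation", {
  m <- long_edge_model(1, 1)
  lam <- expected_long_degree(32, m)
  reps <- 30
  mean_deg <- vapply(seq_len(reps), function(s)
    2 * build_graph(32, m, seed = s)$n_long / 32^2, numeric(1))
  se <- stats::sd(mean_deg) / sqrt(reps)
  expect_lt(abs(mean(mean_deg) - lam), 3 * se + 1e-9)
})

test_that("activation step matches the shift-based oracle on small tori", {
  set.seed(42)
  for (N in c(3L, 4L)) {
    g <- build_graph(N, long_edge_model(0), seed = 0)
    for (rep in 1:50) {
      chi <- as.integer(stats::runif(N^2) < stats::runif(1))
      for (k in 1:4) {
        got <- activation_step(chi, g, update_rule(k))
        want <- mat_to_chi(oracle_torus_step(chi_to_mat(chi, N), k))
        expect_identical(got, want)
      }
    }
  }
})

test_that("absorbing states and monotonicity of the threshold rule", {
  g <- build_graph(6, long_edge_model(0), seed = 0)
  zero <- integer(36); one <- rep(1L, 36)
  for (k in 1:4) {
    expect_identical(activation_step(zero, g, update_rule(k)), zero)
    expect_identical(activation_step(one, g, update_rule(k)), one)
  }
  ## k above the degree kills the all-active state
  expect_identical(activation_step(one, g, update_rule(5)), zero)

  ## state monotonicity: adding active vertices never removes output activity
  set.seed(7)
  gl <- build_graph(8, long_edge_model(2), seed = 3)
  for (rep in 1:30) {
    a <- as.integer(stats::runif(64) < 0.4)
    b <- pmax(a, as.integer(stats::runif(64) < 0.2))
    for (k in c(2L, 3L)) {
      oa <- activation_step(a, gl, update_rule(k))
      ob <- activation_step(b, gl, update_rule(k))
      expect_true(all(ob >= oa))
    }
  }
})

test_that("single seed under k = 1 activates exactly its neighbors", {
  g <- build_graph(4, long_edge_model(0), seed = 0)
  chi <- integer(16); chi[1] <- 1L    # vertex (0,0)
  nxt <- activation_step(chi, g, update_rule(1))
  expect_identical(which(nxt == 1L), c(2L, 4L, 5L, 13L))
})

test_that("trajectories terminate with the right outcome labels", {
  g <- build_graph(8, long_edge_model(0), seed = 2)
  expect_error(run_dynamics(g, 0.5, update_rule(3), max_steps = 0), "max_steps")

  t0 <- run_dynamics(g, 0, update_rule(3), seed = 1)
  expect_identical(t0$outcome, "all_inactive")
  expect_identical(t0$steps_taken, 0L)

  t1 <- run_dynamics(g, 1, update_rule(3), seed = 1)
  expect_identical(t1$outcome, "all_active")
  expect_equal(t1$rho[length(t1$rho)], 1)

  ## two adjacent seeds under k = 1 blink between parity classes -> cycle
  ## (single-parity initial states are period-2 on the torus)
  gl <- build_graph(6, long_edge_model(0), seed = 0)
  tr <- run_dynamics(gl, 0.02, update_rule(1), max_steps = 200, seed = 5)
  expect_true(tr$outcome %in% c("all_active", "cycle"))

  t2 <- run_dynamics(g, 0.6, update_rule(3), max_steps = 200, seed = 9)
  t3 <- run_dynamics(g, 0.6, update_rule(3), max_steps = 200, seed = 9)
  expect_identical(t2$rho, t3$rho)
  expect_identical(t2$final_state, t3$final_state)
})

test_that("high initial density under k = 3 reaches full activation", {
  m <- long_edge_model(1)
  n_full <- 0
  for (s in 1:20) {
    g <- build_graph(32, m, seed = s)
    tr <- run_dynamics(g, 0.95, update_rule(3), max_steps = 200, seed = 100 + s)
    if (tr$rho[length(tr$rho)] >= 0.99) n_full <- n_full + 1
  }
  expect_gte(n_full, 18)   # >= 90% of runs
})

test_that("trajectory and graph CSV exports carry the documented columns", {
  d <- withr::local_tempdir()
  g <- build_graph(6, long_edge_model(1), seed = 4)
  tr <- run_dynamics(g, 0.7, update_rule(2), seed = 4)
  write_trajectory_csv(tr, file.path(d, "traj.csv"))
  df <- utils::read.csv(file.path(d, "traj.csv"))
  expect_identical(names(df), c("step", "rho", "outcome_flag"))
  expect_equal(nrow(df), length(tr$rho))
  expect_identical(unique(df$outcome_flag), tr$outcome)

  write_graph_csv(g, file.path(d, "graph.csv"))
  ge <- utils::read.csv(file.path(d, "graph.csv"))
  expect_identical(names(ge), c("x1", "y1", "x2", "y2", "type"))
  expect_equal(sum(ge$type == "short"), 2 * 36)
  expect_equal(sum(ge$type == "long"), g$n_long)
})
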