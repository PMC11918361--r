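# Connectivity graphs, the RK4 integrator, virtual slabs, deviation
# statistics and the orientation sweep.

test_that("q = 0 gives exactly the distance edges, q = 1 the complete graph", {
  tab <- toy_table()  # pairwise distances: 10, 10, 10, ~14.1, ~14.1, ~14.1
  g0 <- build_connectivity(tab, radius = 20, q = 0)
  A0 <- as.matrix(g0$adjacency)
  expect_true(isSymmetric(A0))
  expect_true(all(diag(A0) == 0))
  expect_equal(sum(A0) / 2, 6)  # all pairs within 20 um

  g0b <- build_connectivity(tab, radius = 12, q = 0)
  expect_equal(sum(as.matrix(g0b$adjacency)) / 2, 3)  # only the 10 um pairs

  g1 <- build_connectivity(tab, radius = 1e-6, q = 1)
  expect_equal(sum(as.matrix(g1$adjacency)) / 2, 6)
  expect_error(build_connectivity(tab, radius = -1),
               class = "scn_config_error")
  expect_error(build_connectivity(tab, q = 2), class = "scn_config_error")
})

test_that("random edge count follows the binomial expectation", {
  snap <- synth_snapshot(snapshot_synth_config(n_neurons = 2000, seed = 1))
  q <- 0.001
  g <- build_connectivity(snap$table, radius = 20, q = q, seed = 2)
  m_all <- 2000 * 1999 / 2
  m_free <- m_all - g$record$n_distance_edges
  expect_lt(abs(g$record$n_random_edges - q * m_free),
            3 * sqrt(m_free * q * (1 - q)))
  # total nonzeros match the edge bookkeeping
  expect_equal(Matrix::nnzero(g$adjacency),
               2 * (g$record$n_distance_edges + g$record$n_random_edges))
})

test_that("RK4 matches the two-oscillator closed form to 1e-6", {
  # For two coupled oscillators the gap obeys d(delta)/dt = -2 K sin(delta),
  # whose solution is tan(delta/2) = tan(delta0/2) exp(-2 K t).
  tab <- scn_neuron_table(1:2, c(0, 10), c(0, 0), c(0, 0), c(1, 1))
  g <- build_connectivity(tab, radius = 20)
  delta0 <- 1
  tr <- simulate_kuramoto(c(0, delta0), g, K = 1)
  for (hour in c(1, 6, 24)) {
    row <- which(tr$times == hour)
    gap <- tr$theta[row, 2] - tr$theta[row, 1]
    exact <- 2 * atan(tan(delta0 / 2) * exp(-2 * 1 * hour))
    expect_lt(abs(gap - exact), 1e-6)
  }
})

test_that("K = 0 advances phases exactly and identical phases stay identical", {
  tab <- toy_table()
  g <- build_connectivity(tab, radius = 20)
  th0 <- c(0.2, 1.4, -0.5, 2.2)
  tr <- simulate_kuramoto(th0, g, K = 0)
  expect_equal(tr$theta[25, ], th0 + 2 * pi, tolerance = 1e-9)

  tr_sync <- simulate_kuramoto(rep(1, 4), g, K = 1.5)
  drift <- tr_sync$theta[25, ] - (1 + 2 * pi)
  expect_equal(max(abs(drift)), 0, tolerance = 1e-9)
  expect_equal(sd(tr_sync$theta[25, ]), 0, tolerance = 1e-12)
})

test_that("simulation is equivariant under global phase rotation", {
  snap <- synth_snapshot(snapshot_synth_config(n_neurons = 150, seed = 2))
  g <- build_connectivity(snap$table, radius = 30, q = 0.01, seed = 3)
  th0 <- rnorm(150, sd = 0.5)
  a <- simulate_kuramoto(th0, g, K = 1)
  b <- simulate_kuramoto(th0 + 2.345, g, K = 1)
  expect_equal(b$theta, a$theta + 2.345, tolerance = 1e-9)
})

test_that("coupling on a connected graph does not desynchronize", {
  for (s in 1:20) {
    set.seed(s)
    tab <- synth_snapshot(snapshot_synth_config(n_neurons = 60,
                                                seed = s))$table
    g <- build_connectivity(tab, radius = 500)  # complete: connected
    th0 <- rnorm(60, sd = 0.6)
    tr <- simulate_kuramoto(th0, g, K = 0.5)
    o0 <- order_parameter(tr$theta[1, ])
    o24 <- order_parameter(tr$theta[25, ])
    expect_gte(o24, o0 - 1e-9)
  }
})

test_that("halving the step leaves final phases essentially unchanged", {
  snap <- synth_snapshot(snapshot_synth_config(n_neurons = 100, seed = 4))
  g <- build_connectivity(snap$table, radius = 30, seed = 1)
  th0 <- rnorm(100, sd = 0.6)
  for (K in c(0.5, 2)) {
    a <- simulate_kuramoto(th0, g, K = K, dt_seconds = 30)
    b <- simulate_kuramoto(th0, g, K = K, dt_seconds = 15)
    expect_lt(max(abs(a$theta[25, ] - b$theta[25, ])), 1e-8)
  }
})

test_that("virtual slabs include the center and honor the axis mapping", {
  tab <- scn_neuron_table(1:3, c(0, 0, 0), c(0, 50, 80), c(0, 0, 0),
                          c(1, 1, 1))
  # mean y = 130/3 = 43.3; coronal slab keeps |y - 43.3| <= 50
  idx <- virtual_slice(tab, "coronal", width = 100)
  expect_equal(idx, 1:3)
  # boundary inclusion: neuron exactly at mean +- width/2 stays
  tab2 <- scn_neuron_table(1:2, c(0, 100), c(0, 0), c(0, 0), c(1, 1))
  expect_equal(virtual_slice(tab2, "sagittal", width = 100), 1:2)

  # uniform cube of side 300: each orientation retains about 1/3
  set.seed(5)
  n <- 6000
  cube <- scn_neuron_table(1:n, runif(n, 0, 300), runif(n, 0, 300),
                           runif(n, 0, 300), rep(1, n))
  for (o in c("coronal", "sagittal", "horizontal")) {
    expect_equal(length(virtual_slice(cube, o)) / n, 1 / 3,
                 tolerance = 0.05)
  }
})

test_that("deviation statistic wraps to the principal value", {
  snap <- synth_snapshot(snapshot_synth_config(n_neurons = 50, seed = 6))
  g <- build_connectivity(snap$table, radius = 30)
  th0 <- rnorm(50, sd = 0.3)
  tr <- simulate_kuramoto(th0, g, K = 0.4)
  idx <- seq_len(50)
  expect_equal(as.numeric(deviation_statistic(tr, tr, idx)), 0)

  # shift the sliced endpoint by pi and by 3*pi/2
  shifted <- tr; shifted$theta <- tr$theta + pi
  expect_equal(as.numeric(deviation_statistic(tr, shifted, idx)), pi,
               tolerance = 1e-12)
  shifted$theta <- tr$theta + 3 * pi / 2
  expect_equal(as.numeric(deviation_statistic(tr, shifted, idx)), pi / 2,
               tolerance = 1e-12)

  sub <- induced_subgraph(g, 1:10)
  tr_sub <- simulate_kuramoto(th0[1:10], sub, K = 0.4)
  expect_error(deviation_statistic(tr, tr_sub, 1:9),
               class = "scn_mismatch_error")
})

test_that("orientation sweep covers the grid and K = 0 cells are exact ties", {
  snap <- calibrated_snapshot(seed = 7, n_neurons = 400)
  sw <- orientation_sweep(snap$table, snap$est$phase_radians,
                          q_grid = c(1e-4, 1e-3), K_grid = c(0, 0.5),
                          seed = 2)
  expect_equal(nrow(sw$results), 2 * 2 * 3)
  expect_true(all(sw$results$ok))
  k0 <- sw$results[sw$results$K == 0, ]
  expect_true(all(k0$deviation_radians == 0))
  expect_true(all(k0$winner == "tie"))
  expect_equal(dim(sw$winner), c(2, 2))
  expect_true(all(sw$winner[, 1] == "tie"))
  # deviation statistics are invariant to a global rotation of theta0
  sw2 <- orientation_sweep(snap$table, snap$est$phase_radians + 1.1,
                           q_grid = c(1e-4, 1e-3), K_grid = c(0, 0.5),
                           seed = 2)
  expect_equal(sw2$results$deviation_radians, sw$results$deviation_radians,
               tolerance = 1e-9)
})
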