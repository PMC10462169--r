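test_that("drift pulls toward the weighted reference centroid", {
  refs <- reference_set(rbind(c(1, 1, 1, 1, 1)))
  expect_equal(drift(rep(0, 5), refs, alpha = 1), rep(1, 5))
  # the centroid is the fixed point
  set.seed(2)
  V <- matrix(rnorm(15), 3, 5)
  w <- c(0.2, 0.5, 0.3)
  refs <- reference_set(V, w)
  m <- as.numeric(w %*% V)
  expect_equal(drift(m, refs, alpha = 2.5), rep(0, 5), tolerance = 1e-12)
  # double-loop oracle over references and coordinates
  x <- rnorm(5); alpha <- 1.7
  manual <- numeric(5)
  for (k in 1:3) for (j in 1:5) {
    manual[j] <- manual[j] + alpha * w[k] * (V[k, j] - x[j])
  }
  expect_equal(drift(x, refs, alpha), manual, tolerance = 1e-12)
})

test_that("reference sets enforce positive normalized weights", {
  expect_error(reference_set(rbind(c(1, 0)), weights = c(0.5, 0.5)),
               class = "sgnc_config_error")
  expect_error(reference_set(rbind(c(1, 0), c(0, 1)), weights = c(0.9, 0.2)),
               class = "sgnc_config_error")
  expect_error(reference_set(rbind(c(1, 0), c(0, 1)), weights = c(1.2, -0.2)),
               class = "sgnc_config_error")
})

test_that("one noiseless Euler step matches hand evaluation", {
  refs <- reference_set(rbind(1))
  cfg <- generator_config(alpha = 1, dt = 0.1, n_steps = 1,
                          noise_amplitude = 0)
  expect_equal(langevin_step(0, refs, cfg), 0.1)
  # centroid is a fixed point without noise
  V <- rbind(c(2, -1), c(0, 3))
  refs2 <- reference_set(V, c(0.25, 0.75))
  m <- as.numeric(c(0.25, 0.75) %*% V)
  expect_equal(langevin_step(m, refs2, cfg), m)
})

test_that("uniform noise increments stay inside [-A, A] per coordinate", {
  refs <- reference_set(rbind(c(0, 0, 0)))
  cfg <- generator_config(alpha = 1, dt = 0.01, n_steps = 10000L,
                          noise_law = "uniform", noise_amplitude = 0.1,
                          seed = 9)
  traj <- simulate_langevin(c(1, -1, 0.5), refs, cfg)
  inc <- diff(traj$states)
  det_part <- -cfg$alpha * cfg$dt *
    traj$states[-nrow(traj$states), , drop = FALSE]
  eta <- inc - det_part
  expect_true(all(eta >= -0.1 & eta <= 0.1))
})

test_that("zero-noise trajectories follow the closed-form relaxation", {
  set.seed(3)
  V <- matrix(rnorm(12), 3, 4)
  w <- c(0.5, 0.3, 0.2)
  refs <- reference_set(V, w)
  m <- as.numeric(w %*% V)
  x0 <- m + c(2, -1, 0.5, 1)
  alpha <- 1
  dt <- 0.01
  n <- 100L  # horizon 1/alpha
  cfg <- generator_config(alpha = alpha, dt = dt, n_steps = n,
                          noise_amplitude = 0)
  traj <- simulate_langevin(x0, refs, cfg)
  tol <- 5 * alpha^2 * dt * sqrt(sum((x0 - m)^2))
  for (s in c(10L, 50L, 100L)) {
    exact <- m + (x0 - m) * exp(-alpha * s * dt)
    expect_lt(sqrt(sum((traj$states[s + 1L, ] - exact)^2)), tol)
  }
  # deviation from centroid contracts monotonically
  dev <- sqrt(rowSums(sweep(traj$states, 2L, m)^2))
  expect_true(all(diff(dev) <= 1e-12))
})

test_that("halving dt roughly halves the discretization error", {
  refs <- reference_set(rbind(c(3, -2)))
  m <- c(3, -2); x0 <- c(0, 0); alpha <- 1; horizon <- 1
  err_at <- function(dt) {
    n <- as.integer(round(horizon / dt))
    cfg <- generator_config(alpha = alpha, dt = dt, n_steps = n,
                            noise_amplitude = 0)
    traj <- simulate_langevin(x0, refs, cfg)
    exact <- m + (x0 - m) * exp(-alpha * horizon)
    sqrt(sum((traj$states[n + 1L, ] - exact)^2))
  }
  e1 <- err_at(0.02); e2 <- err_at(0.01)
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.4)
})

test_that("trajectories are reproducible from the seed and alpha=0 freezes", {
  refs <- reference_set(rbind(c(1, 2), c(-1, 0)))
  cfg <- generator_config(alpha = 0.5, dt = 0.05, n_steps = 50L, seed = 21)
  t1 <- simulate_langevin(c(0, 0), refs, cfg)
  t2 <- simulate_langevin(c(0, 0), refs, cfg)
  expect_identical(t1$states, t2$states)
  cfg3 <- generator_config(alpha = 1e-12, dt = 0.05, n_steps = 10L,
                           noise_amplitude = 0)
  t3 <- simulate_langevin(c(4, 5), refs, cfg3)
  expect_equal(t3$states, matrix(rep(c(4, 5), each = 11L), ncol = 2),
               tolerance = 1e-9)
})

test_that("step cap rescales large displacements to the cap norm", {
  refs <- reference_set(rbind(c(100, 0)))
  cfg <- generator_config(alpha = 1, dt = 0.5, n_steps = 1,
                          noise_amplitude = 0, step_cap = 0.3)
  x1 <- langevin_step(c(0, 0), refs, cfg)
  expect_equal(sqrt(sum(x1^2)), 0.3, tolerance = 1e-12)
})

test_that("generator config rejects unstable or inconsistent settings", {
  expect_error(generator_config(alpha = 2, dt = 1), class = "sgnc_config_error")
  expect_error(generator_config(burn_in = 10, n_steps = 10),
               class = "sgnc_config_error")
  expect_error(generator_config(noise_amplitude = -0.1),
               class = "sgnc_config_error")
})

test_that("snapshot decoding deduplicates and tracks visited cells", {
  mols <- tiny_molecules(3)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  cdc <- codebook_codec(mols, centers)
  # frozen trajectory: a single decoded candidate
  refs <- reference_set(rbind(c(0, 0)))
  cfg <- generator_config(alpha = 1e-9, dt = 0.1, n_steps = 20L,
                          noise_amplitude = 0, snapshot_every = 5L)
  frozen <- simulate_langevin(c(0.1, 0.1), refs, cfg)
  cand <- generate_candidates(frozen, cdc)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$smiles, mols$smiles[1])
  # snapshot_every = n_steps - burn_in gives exactly two snapshots
  cfg2 <- generator_config(alpha = 0.5, dt = 0.1, n_steps = 20L,
                           burn_in = 10L, snapshot_every = 10L)
  expect_equal(length(snapshot_steps(cfg2)), 2L)
  # candidates equal the distinct Voronoi cells visited at snapshots
  cfg3 <- generator_config(alpha = 0.9, dt = 0.5, n_steps = 40L,
                           noise_law = "uniform", noise_amplitude = 2,
                           snapshot_every = 2L, seed = 31)
  traj <- simulate_langevin(c(5, 5), reference_set(centers[2:3, ]), cfg3)
  cand3 <- generate_candidates(traj, cdc)
  snaps <- traj$states[snapshot_steps(cfg3) + 1L, , drop = FALSE]
  cells <- apply(snaps, 1L, function(z) brute_nearest(z, centers))
  expect_setequal(cand3$smiles, mols$smiles[unique(cells)])
  expect_equal(nrow(cand3), length(unique(cells)))
  # source latent columns round-trip through latent_matrix
  expect_equal(dim(latent_matrix(cand3)), c(nrow(cand3), 2L))
})
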