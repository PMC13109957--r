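test_that("the modified-ReLU weight hits its anchor points", {
  expect_equal(recovery_weight(0, 0.01, 0.3125), 0)
  expect_equal(recovery_weight(0.3125, 0.01, 0.3125), 0.01)
  expect_equal(recovery_weight(1, 0.01, 0.3125), 1)
  y <- seq(0, 1, by = 0.01)
  w <- recovery_weight(y, 0.01, 0.4)
  expect_true(all(diff(w) >= -1e-12))          # monotone
  expect_lt(abs(recovery_weight(0.4 + 1e-9, 0.01, 0.4) -
                  recovery_weight(0.4 - 1e-9, 0.01, 0.4)), 1e-6)
  expect_error(recovery_weight(1.2), "outside")
})

test_that("deterministic repairs follow the occupancy distances", {
  # excess alpha electron: w(|1-1|) = 0 for orbital 0, w(|1-0|) = 1 for 1
  x <- parse_configuration("0011")
  r <- recover_configuration(x, c(1, 0, 0, 0), 1, 0)
  expect_equal(format(r), "0001")
  # deficit case: the empty up-half gains the bit with w(1) = 1
  x2 <- parse_configuration("0100")
  r2 <- recover_configuration(x2, c(0, 1, 0, 1), 1, 1)
  expect_equal(format(r2), "0110")
  # already at target: unchanged
  x3 <- parse_configuration("1001")
  expect_equal(format(recover_configuration(x3, runif(4), 1, 1)),
               "1001")
})

test_that("repairs always land in the target sector with conserved counts", {
  set.seed(20)
  n_orb <- 5L
  s <- sample_set(sample.int(2^n_orb, 300, replace = TRUE) - 1L,
                  sample.int(2^n_orb, 300, replace = TRUE) - 1L,
                  sample.int(3L, 300, replace = TRUE), n_orb)
  parts <- filter_by_particle_number(s, 2, 3)
  nvec <- runif(2 * n_orb)
  fixed <- recover_all(parts$rejected, nvec, 2, 3)
  expect_equal(total_shots(fixed), total_shots(parts$rejected))
  refiltered <- filter_by_particle_number(fixed, 2, 3)
  expect_equal(nrow(refiltered$rejected), 0L)
  empty <- recover_all(sample_set(integer(0), integer(0), integer(0),
                                  n_orb), nvec, 2, 3)
  expect_equal(nrow(empty), 0L)
})

test_that("flip probabilities are monotone in the occupancy distance", {
  # one excess bit, two candidates with distances 0.9 vs 0.2: the
  # far-from-reference orbital must be flipped most often
  set.seed(21)
  x <- configuration(rep(3L, 400L), rep(1L, 400L), 2L)  # up = 11, dn = 01
  nvec <- c(0.1, 0.8, 1, 0)  # up occupancies: orbital0 0.1, orbital1 0.8
  fixed <- recover_configuration(x, nvec, 1, 1)
  # w(|1-0.1|) = w(0.9) >> w(|1-0.8|) = w(0.2): orbital 0 cleared mostly,
  # leaving up = 10 (2L)
  frac <- mean(fixed$up == 2L)
  expect_gt(frac, 0.9)
})

test_that("noiseless samples drive SQD to the exact energy in one pass", {
  h <- make_toy_hamiltonian("random", 6, 3, 3, seed = 7)
  st <- exact_ground_state(h, solver_options(spin_penalty_lambda = 0))
  s <- sample_exact(st, 4000, seed = 30)
  res <- run_sqd(h, s, d = 2 * subspace_dimension(st$basis), n_batches = 2,
                 solver_opts = solver_options(spin_penalty_lambda = 0.2),
                 seed = 31)
  expect_equal(res$final_energy, st$energy, tolerance = 1e-8)
  expect_equal(res$iterations, 1L)
  expect_true(res$converged)
})

test_that("recovery does not hurt the variational energy in the median", {
  h <- make_toy_hamiltonian("random", 6, 3, 3, seed = 7)
  st <- exact_ground_state(h, solver_options(spin_penalty_lambda = 0))
  diffs <- vapply(1:10, function(s) {
    noisy <- depolarize(st, 0.5, 3000, seed = 300 + s)
    raw <- run_sqd_raw(h, noisy, d = 80, n_batches = 3, seed = 400 + s)
    rec <- run_sqd(h, noisy, d = 80, n_batches = 3,
                   recovery_opts = recovery_options(), seed = 400 + s)
    raw$final_energy - rec$final_energy   # > 0 when recovery helps
  }, numeric(1))
  expect_gte(median(diffs), 0)
})

test_that("the energy trajectory decreases and the loop is reproducible", {
  h <- make_toy_hamiltonian("random", 6, 3, 3, seed = 7)
  st <- exact_ground_state(h, solver_options(spin_penalty_lambda = 0))
  noisy <- depolarize(st, 0.5, 3000, seed = 301)
  r1 <- run_sqd(h, noisy, d = 80, n_batches = 3, seed = 401)
  r2 <- run_sqd(h, noisy, d = 80, n_batches = 3, seed = 401)
  expect_identical(r1$energies, r2$energies)
  expect_identical(as.numeric(r1$occupancies), as.numeric(r2$occupancies))
  traj <- r1$min_energies
  expect_lte(traj[length(traj)], traj[1] + 1e-9)
  # stopping rule: energy change below tolerance or the hard cap
  expect_lte(r1$iterations, recovery_options()$max_iterations)
})

test_that("an empty in-sector pool without warm start is an error", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 1)
  s <- sample_set(0L, 0L, 5L, 4L)   # empty determinant only
  expect_error(run_sqd(h, s, d = 10), "no samples")
  # warm start bypasses the setup phase
  warm <- structure(rep(0.5, 8), n_orbitals = 4L,
                    class = "occupancy_vector")
  res <- run_sqd(h, s, d = 10, n_batches = 2, warm_start_n = warm,
                 seed = 50)
  expect_true(is.finite(res$final_energy))
})
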