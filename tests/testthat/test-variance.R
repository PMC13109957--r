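test_that("exact eigenstates have zero Hamiltonian variance", {
  h <- make_toy_hamiltonian("random", 6, 3, 3, seed = 7)
  st <- exact_ground_state(h, solver_options(spin_penalty_lambda = 0))
  vp <- hamiltonian_variance(h, st)
  expect_lt(abs(vp$variance), 1e-9)
  expect_equal(vp$energy, st$energy, tolerance = 1e-10)
})

test_that("a two-eigenstate superposition has variance (E1 - E2)^2 / 4", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 3)
  basis <- full_sector_basis(h)
  es <- eigen(oracle_dense_h(h, basis), symmetric = TRUE)
  D <- nrow(es$vectors)
  v <- (es$vectors[, D] + es$vectors[, D - 1]) / sqrt(2)
  st <- ci_vector(basis, matrix(v, length(basis$alpha_strings)))
  vp <- hamiltonian_variance(h, st)
  gap <- es$values[D] - es$values[D - 1]
  expect_equal(vp$variance, gap^2 / 4, tolerance = 1e-8)
})

test_that("subspace-state variance matches the dense computation", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 5)
  full <- full_sector_basis(h)
  Hd <- oracle_dense_h(h, full)
  strs <- sector_strings(4, 2)
  sub <- subspace_basis(strs[1:4], strs[1:4], 4L)
  st <- random_state(sub, seed = 6)
  vp <- hamiltonian_variance(h, st)
  # embed into the full sector for the dense reference
  vfull <- numeric(nrow(Hd))
  ia <- match(sub$alpha_strings, full$alpha_strings)
  ib <- match(sub$beta_strings, full$beta_strings)
  nA <- length(full$alpha_strings)
  vfull[as.numeric(outer(ia, (ib - 1) * nA, "+"))] <-
    as.numeric(st$amplitudes)
  e_ref <- sum(vfull * (Hd %*% vfull))
  v_ref <- sum((Hd %*% vfull)^2) - e_ref^2
  expect_equal(vp$energy, e_ref, tolerance = 1e-10)
  expect_equal(vp$variance, v_ref, tolerance = 1e-8)
  # invariant under a global sign flip
  st2 <- ci_vector(sub, -st$amplitudes)
  expect_equal(hamiltonian_variance(h, st2)$variance, vp$variance,
               tolerance = 1e-10)
  expect_error(hamiltonian_variance(h, st, max_dimension = 4), "cap")
})

test_that("variance shrinks as nested bases approach the full sector", {
  h <- make_toy_hamiltonian("random", 6, 3, 3, seed = 7)
  opts <- solver_options(spin_penalty_lambda = 0)
  vars <- vapply(1:3, function(l) {
    st <- project_and_solve(h, excitation_basis(h, l), opts)
    hamiltonian_variance(h, st)$variance
  }, numeric(1))
  expect_true(all(diff(vars) <= 1e-9))
  expect_lt(vars[3], 1e-9)   # level 3 is the full (6o, 3e) sector
})

test_that("extrapolation recovers exact lines and the FCI limit", {
  pts <- lapply(c(0.4, 0.1, 0.25), function(v)
    list(energy = -5 + 3 * v, variance = NULL, dimension = NA))
  for (i in seq_along(pts)) {
    # construct variance so that variance / energy^2 equals the abscissa
    vshare <- c(0.4, 0.1, 0.25)[i]
    pts[[i]]$variance <- vshare * pts[[i]]$energy^2
  }
  fit <- extrapolate(pts)
  expect_equal(fit$intercept, -5, tolerance = 1e-10)
  expect_equal(fit$slope, 3 * pts[[1]]$energy^2 / pts[[1]]$energy^2,
               tolerance = 1)
  fit_rev <- extrapolate(rev(pts))
  expect_equal(fit_rev$intercept, fit$intercept, tolerance = 1e-12)
  expect_error(extrapolate(pts[1]), "at least 2")
  same <- list(pts[[1]], pts[[1]])
  expect_error(extrapolate(same), "degenerate")

  h <- make_toy_hamiltonian("random", 6, 3, 3, seed = 7)
  opts <- solver_options(spin_penalty_lambda = 0)
  series <- lapply(1:3, function(l)
    hamiltonian_variance(h, project_and_solve(h, excitation_basis(h, l),
                                              opts)))
  fci <- oracle_ground_energy(h)
  fit2 <- extrapolate(series)
  expect_lt(abs(fit2$intercept - fci), 3 * fit2$intercept_stderr + 1e-9)
  # the zero-variance anchor dominates near the intercept
  expect_lt(abs(fit2$intercept - series[[3]]$energy),
            max(fit2$intercept_stderr, 1e-6))
})

test_that("energy-variance tables round-trip through CSV", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 8)
  st <- exact_ground_state(h, solver_options(spin_penalty_lambda = 0))
  pts <- list(hamiltonian_variance(h, st))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_ev_points(pts, tf)
  back <- read_ev_points(tf)
  expect_equal(back$energy, pts[[1]]$energy, tolerance = 1e-10)
  expect_equal(back$variance, pts[[1]]$variance, tolerance = 1e-10)
})
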