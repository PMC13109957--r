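test_that("spin-closure batches reproduce the worked 2-orbital example", {
  cfg <- parse_configuration("1001")
  pool <- sample_set(cfg$up, cfg$dn, 1L, 2L)
  b <- build_batches(pool, 2, 1)[[1]]
  dets <- configuration(rep(b$alpha_strings, length(b$beta_strings)),
                        rep(b$beta_strings, each = length(b$alpha_strings)),
                        2L)
  expect_setequal(format(dets), c("1001", "1010", "0101", "0110"))
})

test_that("a single closed-shell sample spans only itself", {
  cfg <- parse_configuration("0101")
  pool <- sample_set(cfg$up, cfg$dn, 1L, 2L)
  b <- build_batches(pool, 10, 1)[[1]]
  expect_equal(subspace_dimension(b), 1)
  expect_equal(b$alpha_strings, b$beta_strings)
})

test_that("every batch basis is closed under spin inversion", {
  h <- make_toy_hamiltonian("random", 5, 2, 2, seed = 1)
  st <- exact_ground_state(h, solver_options(spin_penalty_lambda = 0))
  s <- sample_exact(st, 500, seed = 9)
  set.seed(10)
  for (b in build_batches(s, 40, 3)) {
    expect_identical(b$alpha_strings, b$beta_strings)
    dets_up <- rep(b$alpha_strings, length(b$beta_strings))
    dets_dn <- rep(b$beta_strings, each = length(b$alpha_strings))
    inv <- paste(dets_dn, dets_up)
    expect_setequal(paste(dets_up, dets_dn), inv)
  }
})

test_that("a one-determinant projection gives the closed-form energy", {
  h <- molecular_hamiltonian(1, 1, 1, core_energy = 0.5,
                             one_body = matrix(-1, 1, 1),
                             two_body = array(2, dim = rep(1, 4)))
  b <- subspace_basis(1L, 1L, 1L)
  st <- project_and_solve(h, b)
  expect_equal(st$energy, 0.5, tolerance = 1e-12)
})

test_that("full-sector projection matches dense diagonalization", {
  for (case in list(c(4, 2, 2), c(6, 3, 3))) {
    h <- make_toy_hamiltonian("random", case[1], case[2], case[3],
                              seed = case[1])
    basis <- full_sector_basis(h)
    st <- project_and_solve(h, basis,
                            solver_options(spin_penalty_lambda = 0))
    expect_equal(st$energy, oracle_ground_energy(h), tolerance = 1e-8)
  }
})

test_that("Davidson agrees with dense diagonalization beyond the dense cutoff", {
  h <- make_toy_hamiltonian("random", 6, 3, 3, seed = 11)
  basis <- full_sector_basis(h)
  st <- project_and_solve(h, basis,
                          solver_options(spin_penalty_lambda = 0,
                                         dense_cutoff = 10L))
  expect_true(st$converged)
  expect_equal(st$energy, oracle_ground_energy(h), tolerance = 1e-8)
})

test_that("energies are variational and monotone under basis growth", {
  h <- make_toy_hamiltonian("random", 6, 3, 3, seed = 5)
  e_fci <- oracle_ground_energy(h)
  strs <- sector_strings(6, 3)
  set.seed(6)
  sub1 <- sort(sample(strs, 8))
  sub2 <- sort(unique(c(sub1, sample(strs, 6))))
  opts <- solver_options(spin_penalty_lambda = 0)
  e1 <- project_and_solve(h, subspace_basis(sub1, sub1, 6L), opts)$energy
  e2 <- project_and_solve(h, subspace_basis(sub2, sub2, 6L), opts)$energy
  expect_gte(e1, e_fci - 1e-10)
  expect_gte(e2, e_fci - 1e-10)
  expect_lte(e2, e1 + 1e-10)
})

test_that("the sigma kernel matches the dense matrix and is symmetric", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 3)
  basis <- full_sector_basis(h)
  Hd <- oracle_dense_h(h, basis)
  na <- length(basis$alpha_strings)
  set.seed(7)
  for (rep in 1:3) {
    v <- rnorm(nrow(Hd))
    y <- as.numeric(apply_hamiltonian(h, basis, matrix(v, na)))
    expect_lt(max(abs(y - as.numeric(Hd %*% v))), 1e-10)
  }
  x <- rnorm(nrow(Hd)); y <- rnorm(nrow(Hd))
  hx <- as.numeric(apply_hamiltonian(h, basis, matrix(x, na)))
  hy <- as.numeric(apply_hamiltonian(h, basis, matrix(y, na)))
  expect_equal(sum(x * hy), sum(hx * y), tolerance = 1e-10)
  z <- apply_hamiltonian(h, basis, matrix(0, na, na))
  expect_true(all(z == 0))
})

test_that("S^2 expectations reproduce the known spin combinations", {
  # closed-shell determinant: singlet
  b1 <- subspace_basis(1L, 1L, 2L)
  cs <- list(basis = b1, amplitudes = matrix(1, 1, 1))
  expect_equal(s_squared_expectation(cs), 0, tolerance = 1e-10)
  # open-shell combinations over the spin-closed 2-orbital basis
  b <- subspace_basis(c(1L, 2L), c(1L, 2L), 2L)
  S2d <- oracle_dense_s2(b)
  amp_plus <- matrix(0, 2, 2); amp_plus[1, 2] <- amp_plus[2, 1] <- 1 / sqrt(2)
  amp_minus <- matrix(0, 2, 2); amp_minus[1, 2] <- 1 / sqrt(2)
  amp_minus[2, 1] <- -1 / sqrt(2)
  vals <- vapply(list(amp_plus, amp_minus), function(a) {
    s_squared_expectation(list(basis = b, amplitudes = a))
  }, numeric(1))
  oracle_vals <- vapply(list(amp_plus, amp_minus), function(a)
    as.numeric(t(as.numeric(a)) %*% S2d %*% as.numeric(a)), numeric(1))
  expect_equal(vals, oracle_vals, tolerance = 1e-10)
  expect_setequal(round(vals, 8), c(0, 2))
  # single open-shell determinant: singlet/triplet average
  amp1 <- matrix(0, 2, 2); amp1[1, 2] <- 1
  expect_equal(s_squared_expectation(list(basis = b, amplitudes = amp1)),
               1, tolerance = 1e-10)
})

test_that("the spin penalty reduces contamination on spin-open bases", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 13)
  strs <- sector_strings(4, 2)
  # deliberately not closed under spin inversion
  b <- subspace_basis(strs[1:4], strs[2:6], 4L)
  s0 <- project_and_solve(h, b, solver_options(spin_penalty_lambda = 0))
  s1 <- project_and_solve(h, b, solver_options(spin_penalty_lambda = 0.2))
  expect_lte(s1$s_squared, s0$s_squared + 1e-10)
  expect_gte(s1$s_squared, -1e-10)
})

test_that("occupancies average number operators over batches", {
  b1 <- subspace_basis(3L, 3L, 4L)  # RHF determinant of (4o, 2+2e)
  st <- list(basis = b1, amplitudes = matrix(1, 1, 1))
  n1 <- occupancies(list(st))
  expect_equal(as.numeric(n1), c(1, 1, 0, 0, 1, 1, 0, 0))
  expect_equal(as.numeric(occupancies(list(st, st, st))), as.numeric(n1))
  h <- make_toy_hamiltonian("random", 5, 3, 2, seed = 2)
  stx <- exact_ground_state(h, solver_options(spin_penalty_lambda = 0))
  nx <- occupancies(list(stx))
  expect_equal(sum(nx[1:5]), 3, tolerance = 1e-10)
  expect_equal(sum(nx[6:10]), 2, tolerance = 1e-10)
  expect_true(all(nx >= 0 & nx <= 1))
})
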