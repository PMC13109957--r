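test_that("exact sampling follows the Born distribution", {
  b <- subspace_basis(c(1L, 2L), c(1L, 2L), 2L)
  single <- matrix(0, 2, 2); single[1, 1] <- 1
  s <- sample_exact(ci_vector(b, single), 100, seed = 1)
  expect_equal(nrow(s), 1L)
  expect_equal(total_shots(s), 100L)
  expect_equal(s$up, 1L); expect_equal(s$dn, 1L)
  eq <- matrix(0, 2, 2); eq[1, 1] <- eq[2, 2] <- 1 / sqrt(2)
  s2 <- sample_exact(ci_vector(b, eq), 10000, seed = 2)
  freqs <- s2$count / total_shots(s2)
  expect_true(all(abs(freqs - 0.5) < 0.02))   # 4 sigma binomial
  s3a <- sample_exact(ci_vector(b, eq), 500, seed = 7)
  s3b <- sample_exact(ci_vector(b, eq), 500, seed = 7)
  expect_identical(s3a$count, s3b$count)
  expect_identical(s3a$up, s3b$up)
  expect_error(ci_vector(b, matrix(0, 2, 2)), "zero-norm")
})

test_that("alpha = 1 depolarization degenerates to exact sampling", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 4)
  st <- exact_ground_state(h, solver_options(spin_penalty_lambda = 0))
  s <- depolarize(st, 1, 2000, seed = 3)
  parts <- filter_by_particle_number(s, 2, 2)
  expect_equal(nrow(parts$rejected), 0L)
  expect_error(depolarize(st, 1.2, 10), "alpha")
})

test_that("alpha = 0 depolarization is uniform over all bit words", {
  h <- make_toy_hamiltonian("random", 3, 1, 1, seed = 4)
  st <- exact_ground_state(h, solver_options(spin_penalty_lambda = 0))
  s <- depolarize(st, 0, 1e5, seed = 5)
  m <- 2L * 3L
  counts <- integer(2^m)
  key <- s$up + 2^3 * s$dn + 1L
  counts[key] <- s$count
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("the wrong-sector fraction matches the mixture expectation", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 6)
  st <- exact_ground_state(h, solver_options(spin_penalty_lambda = 0))
  alpha <- 0.3
  n <- 40000L
  s <- depolarize(st, alpha, n, seed = 6)
  wrong <- total_shots(filter_by_particle_number(s, 2, 2)$rejected) / n
  vol <- hilbert_dimension(4, 2, 2) / 2^8
  expected <- (1 - alpha) * (1 - vol)
  expect_lt(abs(wrong - expected),
            4 * sqrt(expected * (1 - expected) / n))
})

test_that("CCSD-style factorization reconstructs t2 and is Hermitian", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 9)
  amps <- mp2_amplitudes(h)
  f <- factorize_ccsd(amps$t1, amps$t2)
  recon <- f$U %*% diag(f$tau) %*% t(f$U)
  expect_lt(max(abs(recon - f$t2_matrix)), 1e-8)
  expect_equal(order(abs(f$tau), decreasing = TRUE), seq_along(f$tau))
  for (part in f$parts[1:2]) {
    expect_lt(max(Mod(part$xplus - Conj(t(part$xplus)))), 1e-10)
    expect_lt(max(Mod(part$xminus - Conj(t(part$xminus)))), 1e-10)
  }
  # rank-1 doubles: single nonzero eigenvalue with its vector
  u <- c(1, 2, -1, 3) / sqrt(15)
  t2r1 <- array(0.7 * outer(u, u), dim = c(2, 2, 2, 2))
  fr <- factorize_ccsd(matrix(0, 2, 2), t2r1)
  expect_equal(fr$tau[1], 0.7, tolerance = 1e-10)
  expect_lt(max(abs(fr$tau[-1])), 1e-10)
  expect_equal(abs(sum(fr$U[, 1] * u)), 1, tolerance = 1e-10)
  bad <- array(stats::rnorm(16), dim = c(2, 2, 2, 2))
  expect_error(factorize_ccsd(matrix(0, 2, 2), bad), "symmetric")
})

test_that("locality masks keep only adjacent and selected couplings", {
  set.seed(10)
  n <- 8
  J <- crossprod(matrix(rnorm(n * n), n))
  K <- matrix(0 + 0i, n, n)
  p <- lucj_parameters(list(list(K = K, j_ss = J, j_os = J)))
  sp <- sparsify_local(p)
  l <- sp$layers[[1]]
  nz <- which(l$j_os != 0, arr.ind = TRUE)
  expect_true(all(nz[, 1] == nz[, 2]))
  expect_setequal(unique(nz[, 1]), c(1L, 5L))       # p = 0 and p = 4
  nz_ss <- which(l$j_ss != 0, arr.ind = TRUE)
  expect_true(all(abs(nz_ss[, 1] - nz_ss[, 2]) == 1))
  sp2 <- sparsify_local(sp)
  expect_identical(sp2$layers[[1]]$j_ss, l$j_ss)    # idempotent
  expect_identical(sp2$layers[[1]]$j_os, l$j_os)
})

test_that("the zero-parameter ansatz is exactly the RHF determinant", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 11)
  z <- matrix(0, 4, 4)
  st <- lucj_state(lucj_parameters(list(list(K = z + 0i, j_ss = z,
                                             j_os = z))), h)
  rhf <- rhf_bitstring(4, 2, 2)
  ia <- match(rhf$up, st$basis$alpha_strings)
  ib <- match(rhf$dn, st$basis$beta_strings)
  expect_equal(Mod(st$amplitudes[ia, ib]), 1, tolerance = 1e-12)
  expect_equal(sum(Mod(st$amplitudes)^2), 1, tolerance = 1e-10)
})

test_that("orbital rotations obey the Thouless determinant overlap", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 12)
  z <- matrix(0, 4, 4)
  ref <- lucj_state(lucj_parameters(list(list(K = z + 0i, j_ss = z,
                                              j_os = z))), h)
  set.seed(12)
  A <- matrix(rnorm(16, sd = 0.4), 4)
  K <- A - t(A)
  rot <- apply_orbital_rotation(ref, K + 0i)
  U <- as.matrix(Matrix::expm(K))
  rhf <- rhf_bitstring(4, 2, 2)
  ia <- match(rhf$up, rot$basis$alpha_strings)
  ib <- match(rhf$dn, rot$basis$beta_strings)
  # amplitude on RHF = det(occupied block)^2 (one factor per spin)
  expect_equal(Mod(rot$amplitudes[ia, ib]), abs(det(U[1:2, 1:2]))^2,
               tolerance = 1e-8)
  expect_equal(sum(Mod(rot$amplitudes)^2), 1, tolerance = 1e-10)
})

test_that("ansatz states stay normalized, in-sector, and improve with depth", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 9)
  amps <- mp2_amplitudes(h)
  f <- factorize_ccsd(amps$t1, amps$t2)
  energies <- vapply(1:2, function(L) {
    par <- lucj_from_ccsd(f, n_layers = L, truncated = FALSE)
    st <- lucj_state(par, h)
    expect_equal(sum(Mod(st$amplitudes)^2), 1, tolerance = 1e-8)
    s <- sample_exact(st, 200, seed = L)
    parts <- filter_by_particle_number(s, 2, 2)
    expect_equal(nrow(parts$rejected), 0L)
    C <- st$amplitudes
    hr <- apply_hamiltonian(h, st$basis, Re(C))
    hi <- apply_hamiltonian(h, st$basis, Im(C))
    Re(sum(Conj(C) * (hr + 1i * hi)))
  }, numeric(1))
  expect_lte(energies[2], energies[1] + 1e-8)
})

test_that("truncated two-layer states depend on the sign convention", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 9)
  amps <- mp2_amplitudes(h)
  f <- factorize_ccsd(amps$t1, amps$t2)
  st_res <- lucj_state(lucj_from_ccsd(f, 2, truncated = TRUE,
                                      sign_convention = "results"), h)
  st_met <- lucj_state(lucj_from_ccsd(f, 2, truncated = TRUE,
                                      sign_convention = "methods"), h)
  expect_equal(sum(Mod(st_res$amplitudes)^2), 1, tolerance = 1e-8)
  expect_gt(max(Mod(st_res$amplitudes - st_met$amplitudes)), 1e-8)
})

test_that("CCSD amplitude JSON interchange round-trips", {
  h <- make_toy_hamiltonian("random", 4, 2, 2, seed = 14)
  amps <- mp2_amplitudes(h)
  tf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_occ = 2, n_virt = 2,
                            t1 = as.numeric(amps$t1),
                            t2 = as.numeric(amps$t2)),
                       tf, auto_unbox = TRUE, digits = NA)
  back <- read_ccsd_amplitudes(tf)
  expect_equal(back$t2, amps$t2, tolerance = 1e-12)
})
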