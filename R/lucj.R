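#' Local unitary cluster Jastrow (LUCJ) parameters
#'
#' A list of ansatz layers, each holding a complex anti-Hermitian orbital
#' rotation generator `K` (spatial `n x n`, shared by both spins), a real
#' symmetric same-spin density-density matrix `j_ss` (the coefficient of
#' `n[p, sigma] n[r, sigma]` in the full double sum over `p, r` for each
#' spin) and a real symmetric opposite-spin matrix `j_os` (coefficient of
#' `n[p, alpha] n[r, beta]`, counted once per ordered spin pair, so the
#' total opposite-spin phase is `2 * sum_{pr} j_os[p, r] n_pa n_rb`).
#' With `truncated = TRUE` the state is the two-layer circuit with the
#' final Jastrow and rotation dropped:
#' `exp(-K2) exp(K1) exp(i J1) exp(-K1) |RHF>` (the `"results"` sign
#' convention; `"methods"` flips the placement of the signs).
#'
#' @param layers list of layers `list(K =, j_ss =, j_os =)`.
#' @param truncated logical; drop the last layer's Jastrow and use its
#'   rotation as the final free rotation.
#' @param sign_convention `"results"` or `"methods"` placement of the
#'   rotation signs in the truncated form.
#' @return object of class `lucj_parameters`.
#' @export
lucj_parameters <- function(layers, truncated = FALSE,
                            sign_convention = c("results", "methods")) {
  sign_convention <- match.arg(sign_convention)
  for (l in layers) {
    if (max(Mod(l$K + Conj(t(l$K)))) > 1e-10)
      stop("K must be anti-Hermitian")
    if (max(abs(l$j_ss - t(l$j_ss))) > 1e-10 ||
        max(abs(l$j_os - t(l$j_os))) > 1e-10)
      stop("Jastrow matrices must be symmetric")
  }
  structure(list(layers = layers, truncated = truncated,
                 sign_convention = sign_convention),
            class = "lucj_parameters")
}

#' Low-rank factorization of CCSD doubles amplitudes
#'
#' Reshapes the doubles tensor into the symmetric matrix `t2[(ai), (bj)]`
#' (occupied index fastest), diagonalizes it with eigenvalues sorted by
#' decreasing magnitude, embeds each eigenvector into the virtual-occupied
#' block of an `n x n` matrix, and forms the Hermitian combinations
#' `X[±, y] = (1 ∓ i)/2 (U_y ± i U_y^T)` with their eigenpairs — the
#' ingredients from which cluster-Jastrow layers are assembled
#' ([lucj_from_ccsd]). Singles amplitudes `t1` are accepted for interface
#' completeness but do not enter the layer construction.
#'
#' @param t1 occ x virt singles amplitudes (unused in layer construction).
#' @param t2 4-d doubles array, dimensions `(occ, virt, occ, virt)` with
#'   element `[i, a, j, b]`, symmetric under `(ai) <-> (bj)`.
#' @return object of class `ccsd_factorization`: `tau` (eigenvalues),
#'   `U` (eigenvectors, `(ai) x y`), `n_occ`, `n_virt`, and per-`y` lists
#'   `xplus`, `xminus` with eigenpairs `g`, `V`.
#' @export
factorize_ccsd <- function(t1, t2) {
  dm <- dim(t2)
  no <- dm[1L]; nv <- dm[2L]
  stopifnot(dm[3L] == no, dm[4L] == nv)
  m <- matrix(aperm(t2, c(1L, 2L, 3L, 4L)), no * nv, no * nv)
  if (max(abs(m - t(m))) > 1e-8)
    stop("t2 matrix is not symmetric under (ai) <-> (bj)")
  m <- (m + t(m)) / 2
  es <- eigen(m, symmetric = TRUE)
  ord <- order(abs(es$values), decreasing = TRUE)
  tau <- es$values[ord]
  U <- es$vectors[, ord, drop = FALSE]
  n <- no + nv
  # embed: U-tilde[p = no + a, r = i] = U[(ai), y]; (ai) runs i fastest
  embed <- function(y) {
    ut <- matrix(0, n, n)
    ut[no + seq_len(nv), seq_len(no)] <- t(matrix(U[, y], no, nv))
    ut
  }
  xs <- lapply(seq_along(tau), function(y) {
    ut <- embed(y)
    xp <- (1 - 1i) / 2 * (ut + 1i * t(ut))
    xm <- (1 + 1i) / 2 * (ut - 1i * t(ut))
    ep <- eigen(xp, symmetric = TRUE)
    em <- eigen(xm, symmetric = TRUE)
    list(xplus = xp, xminus = xm,
         gplus = ep$values, vplus = ep$vectors,
         gminus = em$values, vminus = em$vectors)
  })
  structure(list(tau = tau, U = U, n_occ = no, n_virt = nv,
                 t1 = t1, t2_matrix = m, parts = xs),
            class = "ccsd_factorization")
}

unitary_log <- function(V) {
  es <- eigen(V)
  lv <- log(es$values)  # principal branch; eigenvalues on the unit circle
  K <- es$vectors %*% diag(lv, nrow = length(lv)) %*% solve(es$vectors)
  K <- (K - Conj(t(K))) / 2
  if (max(Mod(expm_unitary(K) - V)) > 1e-6)
    warning("matrix logarithm of rotation inaccurate")
  K
}

# exp of an anti-Hermitian matrix via Hermitian eigendecomposition
expm_unitary <- function(K, scale = 1) {
  Hm <- 1i * K  # Hermitian
  es <- eigen(Hm, symmetric = TRUE)
  es$vectors %*% diag(exp(-1i * scale * es$values),
                      nrow = length(es$values)) %*% Conj(t(es$vectors))
}

#' Assemble cluster-Jastrow layers from a CCSD factorization
#'
#' Builds the interleaved layer sequence
#' `J[2y] = tau_y g+ (x) g+`, `K[2y] = log V+`,
#' `J[2y + 1] = -tau_y g- (x) g-`, `K[2y + 1] = log V-`
#' and retains the first `n_layers` of it. The same matrix parameterizes
#' the same-spin and opposite-spin density-density couplings.
#'
#' @param fact a [factorize_ccsd] result.
#' @param n_layers number of layers `L` to retain.
#' @param truncated,sign_convention passed to [lucj_parameters].
#' @return an [lucj_parameters].
#' @export
lucj_from_ccsd <- function(fact, n_layers = 2L, truncated = TRUE,
                           sign_convention = "results") {
  layers <- vector("list", n_layers)
  for (mu in seq_len(n_layers)) {
    y <- (mu - 1L) %/% 2L + 1L
    if (y > length(fact$tau)) stop("not enough factorized layers")
    part <- fact$parts[[y]]
    if ((mu - 1L) %% 2L == 0L) {
      g <- Re(part$gplus)
      J <- fact$tau[y] * outer(g, g)
      K <- unitary_log(part$vplus)
    } else {
      g <- Re(part$gminus)
      J <- -fact$tau[y] * outer(g, g)
      K <- unitary_log(part$vminus)
    }
    layers[[mu]] <- list(K = K, j_ss = J, j_os = J)
  }
  lucj_parameters(layers, truncated = truncated,
                  sign_convention = sign_convention)
}

#' Apply the hardware locality masks to Jastrow matrices
#'
#' Zeroes every same-spin coupling except nearest-neighbour orbital pairs
#' `(p, p + 1)` and every opposite-spin coupling except diagonal entries
#' `(p, p)` with `p` in the retained set (default `p` with `p %% 4 == 0`,
#' the heavy-hex auxiliary-qubit pattern). Idempotent.
#'
#' @param params an [lucj_parameters].
#' @param opposite_spin_orbitals 0-based orbitals keeping their diagonal
#'   opposite-spin coupling.
#' @param same_spin_pairs optional 2-column 0-based matrix of retained
#'   same-spin pairs; default adjacent `(p, p + 1)`.
#' @return masked [lucj_parameters].
#' @export
sparsify_local <- function(params, opposite_spin_orbitals = NULL,
                           same_spin_pairs = NULL) {
  n <- nrow(params$layers[[1L]]$K)
  if (is.null(opposite_spin_orbitals))
    opposite_spin_orbitals <- seq(0L, n - 1L, by = 4L)
  mask_ss <- matrix(FALSE, n, n)
  if (is.null(same_spin_pairs)) {
    if (n >= 2L) for (p in seq_len(n - 1L)) {
      mask_ss[p, p + 1L] <- TRUE
      mask_ss[p + 1L, p] <- TRUE
    }
  } else {
    for (r in seq_len(nrow(same_spin_pairs))) {
      i <- same_spin_pairs[r, 1L] + 1L; j <- same_spin_pairs[r, 2L] + 1L
      mask_ss[i, j] <- TRUE; mask_ss[j, i] <- TRUE
    }
  }
  mask_os <- matrix(FALSE, n, n)
  diag(mask_os)[opposite_spin_orbitals + 1L] <- TRUE
  params$layers <- lapply(params$layers, function(l) {
    l$j_ss[!mask_ss] <- 0
    l$j_os[!mask_os] <- 0
    l
  })
  params
}

#' Apply an orbital-rotation exponential to a CI vector
#'
#' `exp(scale * Khat) |psi>` where `Khat` is the spin-summed one-body
#' operator generated by the (anti-Hermitian) spatial matrix `K`. Applied
#' exactly as `exp(Ka) C exp(Kb)^T` over the factorized basis.
#'
#' @param state a `ci_vector` over a full-sector basis.
#' @param K complex anti-Hermitian `n x n` generator.
#' @param scale scalar multiplier of the generator.
#' @return a `ci_vector`.
#' @export
apply_orbital_rotation <- function(state, K, scale = 1) {
  basis <- state$basis
  Ga <- one_body_generator(basis$alpha_strings, basis$n_orbitals, K)
  Gb <- if (identical(basis$beta_strings, basis$alpha_strings)) Ga else
    one_body_generator(basis$beta_strings, basis$n_orbitals, K)
  Ua <- expm_antiherm_action(Ga, scale)
  Ub <- if (identical(basis$beta_strings, basis$alpha_strings)) Ua else
    expm_antiherm_action(Gb, scale)
  amps <- Ua %*% state$amplitudes %*% t(Ub)
  ci_vector(basis, amps)
}

one_body_generator <- function(strings, n_orb, K) {
  links <- cpp_build_links(strings, n_orb)
  ns <- length(strings)
  G <- matrix(0 + 0i, ns, ns)
  vals <- K[cbind(links$p + 1L, links$r + 1L)] * links$sign
  # accumulate duplicates (multiple (p, r) can connect the same pair)
  idx <- cbind(links$ia + 1L, links$ja + 1L)
  for (grp in split(seq_along(vals), (idx[, 1L] - 1L) * ns + idx[, 2L])) {
    G[idx[grp[1L], 1L], idx[grp[1L], 2L]] <- sum(vals[grp])
  }
  G
}

expm_antiherm_action <- function(G, scale = 1) {
  es <- eigen(1i * G, symmetric = TRUE)
  es$vectors %*% diag(exp(-1i * scale * es$values),
                      nrow = length(es$values)) %*% Conj(t(es$vectors))
}

#' Statevector simulation of the LUCJ ansatz
#'
#' Builds the normalized ansatz state in the `(n_alpha, n_beta)` sector by
#' dense sector-restricted simulation: orbital rotations act as exact
#' one-body exponentials on the factorized string basis and Jastrow
#' factors as diagonal phases over determinants. The untruncated product
#' is `prod_mu exp(K_mu) exp(i J_mu) exp(-K_mu) |RHF>`; see
#' [lucj_parameters] for the truncated two-layer form.
#'
#' @param params an [lucj_parameters].
#' @param h a [molecular_hamiltonian] fixing the sector.
#' @param max_orbitals simulable cap on spatial orbitals (default 14).
#' @return a `ci_vector` over the full sector basis (complex amplitudes).
#' @export
lucj_state <- function(params, h, max_orbitals = 14L) {
  if (h$n_orbitals > max_orbitals)
    stop("n_orbitals ", h$n_orbitals, " exceeds simulable cap ",
         max_orbitals)
  basis <- full_sector_basis(h)
  na <- length(basis$alpha_strings); nb <- length(basis$beta_strings)
  C <- matrix(0 + 0i, na, nb)
  rhf <- rhf_bitstring(h$n_orbitals, h$n_alpha, h$n_beta)
  C[match(rhf$up, basis$alpha_strings),
    match(rhf$dn, basis$beta_strings)] <- 1 + 0i
  st <- ci_vector(basis, C)
  L <- length(params$layers)
  res_form <- params$sign_convention == "results"
  for (mu in seq_len(L)) {
    lay <- params$layers[[mu]]
    last <- mu == L
    if (params$truncated && last) {
      # final free rotation only
      st <- apply_orbital_rotation(st, lay$K, if (res_form) -1 else 1)
    } else {
      st <- apply_orbital_rotation(st, lay$K, if (res_form) -1 else 1)
      st <- apply_jastrow(st, lay$j_ss, lay$j_os)
      st <- apply_orbital_rotation(st, lay$K, if (res_form) 1 else -1)
    }
  }
  st
}

apply_jastrow <- function(state, j_ss, j_os) {
  basis <- state$basis
  occa <- string_bits(basis$alpha_strings, basis$n_orbitals)
  occb <- string_bits(basis$beta_strings, basis$n_orbitals)
  fa <- rowSums((occa %*% j_ss) * occa)
  fb <- rowSums((occb %*% j_ss) * occb)
  cross <- 2 * occa %*% j_os %*% t(occb)
  phase <- exp(1i * (outer(fa, fb, "+") + cross))
  ci_vector(basis, state$amplitudes * phase)
}

#' Second-order perturbative doubles amplitudes
#'
#' Lightweight closed-shell MP2-style doubles from a Hamiltonian's own
#' integrals, `t2[i, a, j, b] = (ai|bj) / (e_i + e_j - e_a - e_b)` with
#' orbital energies from the diagonal Fock operator of the RHF
#' determinant. Useful for initializing cluster-Jastrow layers when no
#' external coupled-cluster amplitudes are available.
#'
#' @param h a [molecular_hamiltonian] (closed shell:
#'   `n_alpha == n_beta`).
#' @return list with `t1` (zeros) and `t2` in the `(occ, virt, occ,
#'   virt)` layout of [factorize_ccsd].
#' @export
mp2_amplitudes <- function(h) {
  stopifnot(h$n_alpha == h$n_beta)
  n <- h$n_orbitals; no <- h$n_alpha; nv <- n - no
  occ <- seq_len(no); vir <- no + seq_len(nv)
  g <- h$two_body
  eps <- vapply(seq_len(n), function(p) {
    h$one_body[p, p] + sum(vapply(occ, function(j)
      2 * g[p, p, j, j] - g[p, j, j, p], numeric(1)))
  }, numeric(1))
  t2 <- array(0, dim = c(no, nv, no, nv))
  for (i in occ) for (a in seq_len(nv)) for (j in occ) for (b in seq_len(nv)) {
    denom <- eps[i] + eps[j] - eps[no + a] - eps[no + b]
    t2[i, a, j, b] <- g[no + a, i, no + b, j] / denom
  }
  list(t1 = matrix(0, no, nv), t2 = t2)
}

#' Read CCSD amplitudes from a JSON interchange file
#'
#' The file holds an object with fields `n_occ`, `n_virt`, `t1`
#' (row-major occ x virt) and `t2` (flattened in the `(occ, virt, occ,
#' virt)` layout, occupied index fastest, as documented for
#' [factorize_ccsd]).
#'
#' @param path file path.
#' @return list with `t1` and `t2` arrays.
#' @export
read_ccsd_amplitudes <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  no <- obj$n_occ; nv <- obj$n_virt
  list(t1 = matrix(obj$t1, no, nv),
       t2 = array(obj$t2, dim = c(no, nv, no, nv)))
}
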