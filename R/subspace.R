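#' Factorized determinant subspace bases
#'
#' A subspace spanned by all products of a sorted, duplicate-free list of
#' spin-up half-strings with a list of spin-down half-strings. All spin-up
#' strings carry `n_alpha` electrons and all spin-down strings `n_beta`;
#' the realized dimension is `length(alpha_strings) * length(beta_strings)`.
#' For closed-shell sectors built by [build_batches] the two lists coincide,
#' which makes the basis closed under spin inversion.
#'
#' @param alpha_strings,beta_strings integer half-string words.
#' @param n_orbitals half-string width.
#' @return object of class `subspace_basis`.
#' @export
subspace_basis <- function(alpha_strings, beta_strings, n_orbitals) {
  a <- sort(unique(as.integer(alpha_strings)))
  b <- sort(unique(as.integer(beta_strings)))
  if (!length(a) || !length(b)) stop("empty string list")
  wa <- unique(popcount(a)); wb <- unique(popcount(b))
  if (length(wa) != 1L || length(wb) != 1L)
    stop("strings of one spin species must share a Hamming weight")
  structure(list(alpha_strings = a, beta_strings = b,
                 n_orbitals = as.integer(n_orbitals),
                 n_alpha = wa, n_beta = wb),
            class = "subspace_basis")
}

#' @export
print.subspace_basis <- function(x, ...) {
  cat("<subspace_basis>", length(x$alpha_strings), "x",
      length(x$beta_strings), "strings, dimension",
      subspace_dimension(x), "\n")
  invisible(x)
}

#' @rdname subspace_basis
#' @param basis a `subspace_basis`.
#' @export
subspace_dimension <- function(basis) {
  length(basis$alpha_strings) * length(basis$beta_strings)
}

#' All half-strings of a particle-number sector
#' @param n_orbitals width; `n_elec` Hamming weight.
#' @param n_elec electrons of the spin species.
#' @return sorted integer vector of all `choose(n_orbitals, n_elec)` words.
#' @export
sector_strings <- function(n_orbitals, n_elec) {
  if (n_elec == 0L) return(0L)
  if (n_elec == n_orbitals) return(as.integer(2^n_orbitals - 1))
  combos <- utils::combn(n_orbitals, n_elec)
  sort(as.integer(colSums(matrix(2L^(combos - 1L), nrow = n_elec))))
}

#' Full configuration-interaction basis of a sector
#' @param h a [molecular_hamiltonian] (or explicit sizes).
#' @return a [subspace_basis] spanning the whole sector.
#' @export
full_sector_basis <- function(h) {
  subspace_basis(sector_strings(h$n_orbitals, h$n_alpha),
                 sector_strings(h$n_orbitals, h$n_beta), h$n_orbitals)
}

#' Excitation-truncated basis around the RHF determinant
#'
#' Alpha and beta string lists limited to at most `level` single
#' excitations from the restricted Hartree-Fock half-string of each spin
#' species. With `level = 2` the product basis contains all determinants up
#' to double excitations per spin species (quadruples overall).
#'
#' @param h a [molecular_hamiltonian].
#' @param level maximum excitation level per spin species.
#' @return a [subspace_basis].
#' @export
excitation_basis <- function(h, level = 2L) {
  rhf <- rhf_bitstring(h$n_orbitals, h$n_alpha, h$n_beta)
  subspace_basis(cpp_excite_strings(rhf$up, h$n_orbitals, level),
                 cpp_excite_strings(rhf$dn, h$n_orbitals, level),
                 h$n_orbitals)
}

#' Spin-closed determinant batches from a sample pool
#'
#' Draws `ceiling(d / 2)` configurations per batch from the pool, with
#' replacement and probability proportional to the empirical frequencies,
#' splits each draw into its spin halves, pools the halves of each
#' Hamming weight into a unique string set and spans the full product
#' basis. For closed-shell sectors the two string lists are identical, so
#' every batch is closed under spin inversion. `d` is the sampling budget;
#' the realized dimension of the product basis is reported alongside and
#' can exceed `d`.
#'
#' @param pool a [sample_set], all entries in the correct sector.
#' @param d sampling budget per batch (`d / 2` draws).
#' @param n_batches number of batches `K`.
#' @return list of `n_batches` [subspace_basis] objects.
#' @export
build_batches <- function(pool, d, n_batches) {
  if (!nrow(pool)) stop("empty sample pool")
  stopifnot(d >= 1, n_batches >= 1)
  n_orb <- attr(pool, "n_orbitals")
  na <- popcount(pool$up[1L]); nb <- popcount(pool$dn[1L])
  m <- ceiling(d / 2)
  prob <- pool$count / sum(pool$count)
  lapply(seq_len(n_batches), function(k) {
    idx <- sample.int(nrow(pool), m, replace = TRUE, prob = prob)
    halves <- unique(c(pool$up[idx], pool$dn[idx]))
    w <- popcount(halves)
    astr <- halves[w == na]
    bstr <- if (na == nb) astr else halves[w == nb]
    subspace_basis(astr, bstr, n_orb)
  })
}

# ---- operator context: link tables and same-spin Hamiltonians ----

hamiltonian_context <- function(h, basis) {
  n <- h$n_orbitals
  stopifnot(n == basis$n_orbitals,
            h$n_alpha == basis$n_alpha, h$n_beta == basis$n_beta)
  eri <- as.numeric(h$two_body)
  la <- cpp_build_links(basis$alpha_strings, n)
  lb <- if (identical(basis$beta_strings, basis$alpha_strings)) la else
    cpp_build_links(basis$beta_strings, n)
  ha <- cpp_samespin_ham(basis$alpha_strings, n, h$one_body, eri)
  hb <- if (identical(basis$beta_strings, basis$alpha_strings)) ha else
    cpp_samespin_ham(basis$beta_strings, n, h$one_body, eri)
  list(h = h, basis = basis, eri = eri, la = la, lb = lb, ha = ha, hb = hb)
}

context_apply_h <- function(ctx, C) {
  out <- cpp_apply_spin(C, ctx$ha$i, ctx$ha$j, ctx$ha$val, 0L)
  out <- out + cpp_apply_spin(C, ctx$hb$i, ctx$hb$j, ctx$hb$val, 1L)
  out <- out + cpp_sigma_ab(C, ctx$la, ctx$lb, ctx$eri,
                            ctx$basis$n_orbitals)
  out + ctx$h$core_energy * C
}

context_apply_s2 <- function(ctx, C) {
  cpp_s2_apply(C, ctx$la, ctx$lb, ctx$basis$n_orbitals,
               ctx$basis$n_alpha, ctx$basis$n_beta)
}

context_h_diagonal <- function(ctx) {
  h <- ctx$h; basis <- ctx$basis
  n <- h$n_orbitals
  da <- samespin_diagonal(basis$alpha_strings, n, h$one_body, h$two_body)
  db <- if (identical(basis$beta_strings, basis$alpha_strings)) da else
    samespin_diagonal(basis$beta_strings, n, h$one_body, h$two_body)
  occa <- string_bits(basis$alpha_strings, n)
  occb <- string_bits(basis$beta_strings, n)
  gpq <- matrix(h$two_body[cbind(rep(1:n, n), rep(1:n, n),
                                 rep(1:n, each = n), rep(1:n, each = n))],
                n, n)
  cross <- occa %*% gpq %*% t(occb)
  outer(da, db, "+") + cross + h$core_energy
}

samespin_diagonal <- function(strings, n, h1, g2) {
  occ <- string_bits(strings, n)
  d1 <- occ %*% diag(h1)
  gj <- matrix(g2[cbind(rep(1:n, n), rep(1:n, n),
                        rep(1:n, each = n), rep(1:n, each = n))], n, n)
  gk <- matrix(g2[cbind(rep(1:n, n), rep(1:n, each = n),
                        rep(1:n, each = n), rep(1:n, n))], n, n)
  # 0.5 * sum_{p != q occ} [(pp|qq) - (pq|qp)]
  q2 <- 0.5 * (rowSums((occ %*% (gj - gk)) * occ) -
                 occ %*% (diag(gj) - diag(gk)))
  as.numeric(d1 + q2)
}

context_s2_diagonal <- function(ctx) {
  basis <- ctx$basis
  sz <- 0.5 * (basis$n_alpha - basis$n_beta)
  occa <- string_bits(basis$alpha_strings, basis$n_orbitals)
  occb <- string_bits(basis$beta_strings, basis$n_orbitals)
  sz^2 + 0.5 * (basis$n_alpha + basis$n_beta) - occa %*% t(occb)
}

#' Apply the projected Hamiltonian to amplitude matrices
#'
#' Computes `P H P c` over a factorized [subspace_basis] using
#' Slater-Condon rules on the alpha/beta string lists (the sigma-vector
#' kernel behind the Davidson solver and the variance module).
#'
#' @param h a [molecular_hamiltonian].
#' @param basis a [subspace_basis] in the matching sector.
#' @param amplitudes matrix `length(alpha_strings) x length(beta_strings)`.
#' @return matrix of the same shape.
#' @export
apply_hamiltonian <- function(h, basis, amplitudes) {
  stopifnot(nrow(amplitudes) == length(basis$alpha_strings),
            ncol(amplitudes) == length(basis$beta_strings))
  ctx <- hamiltonian_context(h, basis)
  context_apply_h(ctx, amplitudes)
}

# ---- Davidson ----

#' Options for the projected eigensolver
#'
#' @param spin_penalty_lambda weight of the total-spin penalty
#'   `lambda * (S^2 - s(s+1))^2` added to the projected Hamiltonian when
#'   selecting the state (default 0.2; 0 disables it). Reported energies
#'   always exclude the penalty.
#' @param target_spin_s target total spin `s` (default 0, singlet).
#' @param davidson_tol residual 2-norm convergence threshold.
#' @param max_davidson_iter iteration cap.
#' @param max_subspace Davidson trial-space size before thick restart.
#' @param dense_cutoff dimensions up to this are diagonalized densely.
#' @return list of class `solver_options`.
#' @export
solver_options <- function(spin_penalty_lambda = 0.2, target_spin_s = 0,
                           davidson_tol = 1e-8, max_davidson_iter = 500L,
                           max_subspace = 24L, dense_cutoff = 400L) {
  stopifnot(spin_penalty_lambda >= 0)
  structure(list(spin_penalty_lambda = spin_penalty_lambda,
                 target_spin_s = target_spin_s,
                 davidson_tol = davidson_tol,
                 max_davidson_iter = as.integer(max_davidson_iter),
                 max_subspace = as.integer(max_subspace),
                 dense_cutoff = as.integer(dense_cutoff)),
            class = "solver_options")
}

davidson_lowest <- function(apply_fn, diag_vec, n, v0, tol = 1e-8,
                            max_iter = 500L, max_subspace = 24L) {
  V <- matrix(0, n, max_subspace)
  W <- matrix(0, n, max_subspace)
  v <- v0 / sqrt(sum(v0^2))
  m <- 0L
  theta <- NA_real_
  second <- NA_real_
  for (it in seq_len(max_iter)) {
    # orthogonalize v against V (twice for stability)
    if (m > 0L) for (rep in 1:2) {
      v <- v - V[, seq_len(m), drop = FALSE] %*%
        crossprod(V[, seq_len(m), drop = FALSE], v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) {
      v <- stats::rnorm(n)
      if (m > 0L) v <- v - V[, seq_len(m), drop = FALSE] %*%
          crossprod(V[, seq_len(m), drop = FALSE], v)
      nv <- sqrt(sum(v^2))
    }
    v <- v / nv
    m <- m + 1L
    V[, m] <- v
    W[, m] <- apply_fn(v)
    Tm <- crossprod(V[, seq_len(m), drop = FALSE],
                    W[, seq_len(m), drop = FALSE])
    Tm <- (Tm + t(Tm)) / 2
    es <- eigen(Tm, symmetric = TRUE)
    theta <- es$values[m]
    second <- if (m >= 2L) es$values[m - 1L] else NA_real_
    y <- es$vectors[, m]
    x <- V[, seq_len(m), drop = FALSE] %*% y
    wx <- W[, seq_len(m), drop = FALSE] %*% y
    r <- wx - theta * x
    rn <- sqrt(sum(r^2))
    if (rn < tol)
      return(list(value = theta, vector = as.numeric(x), iterations = it,
                  residual = rn, converged = TRUE, second = second))
    if (m == max_subspace) {
      # thick restart with the four lowest Ritz vectors
      keep <- min(4L, m)
      sel <- m - seq_len(keep) + 1L
      Xk <- V[, seq_len(m), drop = FALSE] %*% es$vectors[, sel, drop = FALSE]
      Wk <- W[, seq_len(m), drop = FALSE] %*% es$vectors[, sel, drop = FALSE]
      V[, seq_len(keep)] <- Xk
      W[, seq_len(keep)] <- Wk
      m <- keep
    }
    denom <- diag_vec - theta
    denom[abs(denom) < 1e-8] <- 1e-8 * sign(denom[abs(denom) < 1e-8] + 1e-300)
    v <- as.numeric(r) / denom
  }
  list(value = theta, vector = as.numeric(x), iterations = max_iter,
       residual = rn, converged = FALSE, second = second)
}

#' Project and diagonalize the Hamiltonian in a sampled subspace
#'
#' Finds the lowest eigenpair of `P (H + lambda (S^2 - s(s+1))^2) P` over
#' the factorized basis by iterative Davidson with string-based operator
#' application (dense diagonalization below `dense_cutoff`). The penalty
#' operator is squared after projection, `(P S^2 P - s(s+1))^2`; spin
#' closure of the batches makes the subspace nearly `S^2`-invariant, so
#' this computable form stays close to the projection of the squared
#' operator. The reported `energy` is the plain Hamiltonian expectation
#' `<psi|P H P|psi>`; the penalty only steers the selection.
#'
#' @param h a [molecular_hamiltonian].
#' @param basis a [subspace_basis].
#' @param opts a [solver_options].
#' @return object of class `subspace_state`: fields `basis`, `amplitudes`
#'   (unit Frobenius norm), `energy`, `s_squared`, `converged`,
#'   `residual`, `iterations`, `near_degenerate`.
#' @export
project_and_solve <- function(h, basis, opts = solver_options()) {
  ctx <- hamiltonian_context(h, basis)
  na <- length(basis$alpha_strings); nb <- length(basis$beta_strings)
  n <- na * nb
  lam <- opts$spin_penalty_lambda
  cc <- opts$target_spin_s * (opts$target_spin_s + 1)
  apply_pen <- function(v) {
    C <- matrix(v, na, nb)
    out <- context_apply_h(ctx, C)
    if (lam > 0) {
      w <- context_apply_s2(ctx, C) - cc * C
      out <- out + lam * (context_apply_s2(ctx, w) - cc * w)
    }
    as.numeric(out)
  }
  if (n <= opts$dense_cutoff) {
    M <- vapply(seq_len(n), function(j) {
      ej <- numeric(n); ej[j] <- 1
      apply_pen(ej)
    }, numeric(n))
    M <- (M + t(M)) / 2
    es <- eigen(M, symmetric = TRUE)
    vec <- es$vectors[, n]
    res <- list(vector = vec, converged = TRUE, residual = 0,
                iterations = 1L,
                second = if (n >= 2L) es$values[n - 1L] else NA_real_,
                value = es$values[n])
  } else {
    dmat <- context_h_diagonal(ctx)
    if (lam > 0) dmat <- dmat + lam * (context_s2_diagonal(ctx) - cc)^2
    dvec <- as.numeric(dmat)
    v0 <- numeric(n)
    v0[which.min(dvec)] <- 1
    res <- davidson_lowest(apply_pen, dvec, n, v0, tol = opts$davidson_tol,
                           max_iter = opts$max_davidson_iter,
                           max_subspace = opts$max_subspace)
    if (!res$converged)
      warning("Davidson did not converge: residual ", format(res$residual))
  }
  C <- matrix(res$vector, na, nb)
  C <- C / sqrt(sum(C^2))
  hC <- context_apply_h(ctx, C)
  energy <- sum(C * hC)
  s2 <- sum(C * context_apply_s2(ctx, C))
  structure(list(basis = basis, amplitudes = C, energy = energy,
                 s_squared = s2, converged = res$converged,
                 residual = res$residual, iterations = res$iterations,
                 near_degenerate = is.finite(res$second) &&
                   !is.na(res$second) &&
                   abs(res$second - res$value) < 1e-6),
            class = "subspace_state")
}

#' @export
print.subspace_state <- function(x, ...) {
  cat("<subspace_state> dimension", subspace_dimension(x$basis),
      " energy", format(x$energy, digits = 10),
      " <S^2> =", format(x$s_squared, digits = 4), "\n")
  invisible(x)
}

#' Total-spin expectation value of a subspace state
#'
#' `<psi| P S^2 P |psi>` over the state's own basis.
#'
#' @param state a `subspace_state`.
#' @return nonnegative scalar (up to numerical floor).
#' @export
s_squared_expectation <- function(state) {
  basis <- state$basis
  la <- cpp_build_links(basis$alpha_strings, basis$n_orbitals)
  lb <- if (identical(basis$beta_strings, basis$alpha_strings)) la else
    cpp_build_links(basis$beta_strings, basis$n_orbitals)
  sum(state$amplitudes *
        cpp_s2_apply(state$amplitudes, la, lb, basis$n_orbitals,
                     basis$n_alpha, basis$n_beta))
}

#' Batch-averaged spin-orbital occupancies
#'
#' `n[p, sigma] = (1/K) sum_k <psi_k| n_{p sigma} |psi_k>`, the quantity
#' that drives configuration recovery. Layout: entries `1..n_orbitals` are
#' spin-up orbitals `0..n_orbitals - 1`, the following `n_orbitals` entries
#' spin-down.
#'
#' @param states list of `subspace_state` objects over one orbital count.
#' @return numeric vector of class `occupancy_vector`, length
#'   `2 * n_orbitals`, entries in `[0, 1]`.
#' @export
occupancies <- function(states) {
  if (inherits(states, "subspace_state")) states <- list(states)
  stopifnot(length(states) >= 1L)
  n <- states[[1L]]$basis$n_orbitals
  acc <- numeric(2L * n)
  for (st in states) {
    stopifnot(st$basis$n_orbitals == n)
    occa <- string_bits(st$basis$alpha_strings, n)
    occb <- string_bits(st$basis$beta_strings, n)
    wa <- rowSums(st$amplitudes^2)
    wb <- colSums(st$amplitudes^2)
    acc <- acc + c(as.numeric(crossprod(occa, wa)),
                   as.numeric(crossprod(occb, wb)))
  }
  structure(pmin(1, pmax(0, acc / length(states))),
            n_orbitals = n, class = "occupancy_vector")
}
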