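# Independent dense oracles built by naive second-quantized operator
# application with explicit Jordan-Wigner phases over the full 2n-bit word
# (spin-up block in the low spin-orbital indices). Deliberately separate
# from the package's Slater-Condon kernels.

oracle_parity_below <- function(up, dn, spin, p) {
  mask <- if (p == 0L) 0L else as.integer(2L^p - 1L)
  if (spin == 0L) cpp_popcount_oracle(bitwAnd(up, mask))
  else cpp_popcount_oracle(up) + cpp_popcount_oracle(bitwAnd(dn, mask))
}

cpp_popcount_oracle <- function(x) {
  # independent popcount: digit sum of the binary expansion
  vapply(x, function(v) sum(floor(v / 2^(0:30)) %% 2), numeric(1))
}

# apply an operator string (rightmost first) to determinant vectors.
# ops: list of c(type, spin, orb) with type 1 = creation, 0 = annihilation,
# spin 0 = alpha, 1 = beta.
oracle_apply_ops <- function(up, dn, ops) {
  phase <- rep(1, length(up))
  alive <- rep(TRUE, length(up))
  for (op in rev(ops)) {
    type <- op[1L]; spin <- op[2L]; p <- op[3L]
    word <- if (spin == 0L) up else dn
    bit <- bitwAnd(bitwShiftR(word, p), 1L)
    ok <- if (type == 1L) bit == 0L else bit == 1L
    alive <- alive & ok
    par <- oracle_parity_below(up, dn, spin, p)
    phase <- phase * (-1)^par
    word <- bitwXor(word, bitwShiftL(1L, p))
    if (spin == 0L) up <- ifelse(alive, word, up)
    else dn <- ifelse(alive, word, dn)
  }
  list(up = up, dn = dn, phase = phase, alive = alive)
}

oracle_basis_dets <- function(basis) {
  nA <- length(basis$alpha_strings); nB <- length(basis$beta_strings)
  list(up = basis$alpha_strings[rep(seq_len(nA), nB)],
       dn = basis$beta_strings[rep(seq_len(nB), each = nA)],
       key = function(up, dn) up + 2^basis$n_orbitals * dn)
}

oracle_dense_matrix <- function(basis, terms) {
  # terms: list of list(coef, ops)
  dets <- oracle_basis_dets(basis)
  D <- length(dets$up)
  keys <- dets$key(dets$up, dets$dn)
  H <- matrix(0, D, D)
  for (term in terms) {
    res <- oracle_apply_ops(dets$up, dets$dn, term$ops)
    idx <- match(res$key <- dets$key(res$up, res$dn), keys)
    ok <- res$alive & !is.na(idx)
    if (any(ok))
      H[cbind(idx[ok], which(ok))] <- H[cbind(idx[ok], which(ok))] +
        term$coef * res$phase[ok]
  }
  H
}

oracle_dense_h <- function(h, basis) {
  n <- h$n_orbitals
  terms <- list()
  for (spin in 0:1) for (p in 0:(n - 1L)) for (r in 0:(n - 1L)) {
    v <- h$one_body[p + 1L, r + 1L]
    if (v != 0)
      terms[[length(terms) + 1L]] <-
        list(coef = v, ops = list(c(1L, spin, p), c(0L, spin, r)))
  }
  for (s1 in 0:1) for (s2 in 0:1)
    for (p in 0:(n - 1L)) for (r in 0:(n - 1L))
      for (q in 0:(n - 1L)) for (s in 0:(n - 1L)) {
        v <- h$two_body[p + 1L, r + 1L, q + 1L, s + 1L]
        if (v != 0)
          terms[[length(terms) + 1L]] <- list(
            coef = v / 2,
            ops = list(c(1L, s1, p), c(1L, s2, q), c(0L, s2, s),
                       c(0L, s1, r)))
      }
  M <- oracle_dense_matrix(basis, terms)
  M + diag(h$core_energy, nrow(M))
}

oracle_dense_s2 <- function(basis) {
  # S^2 = S- S+ + Sz + Sz^2, with S+ routed through the (Na + 1, Nb - 1)
  # intermediate sector (it leaves the fixed-particle-number basis).
  n <- basis$n_orbitals
  dets <- oracle_basis_dets(basis)
  D <- length(dets$up)
  na <- cpp_popcount_oracle(dets$up[1L])
  nb <- cpp_popcount_oracle(dets$dn[1L])
  sz <- 0.5 * (cpp_popcount_oracle(dets$up) - cpp_popcount_oracle(dets$dn))
  diag_part <- diag(sz + sz^2, D)
  if (nb == 0 || na == n) return(diag_part)
  words <- 0:(2^n - 1)
  ups <- words[cpp_popcount_oracle(words) == na + 1]
  dns <- words[cpp_popcount_oracle(words) == nb - 1]
  mup <- ups[rep(seq_along(ups), length(dns))]
  mdn <- dns[rep(seq_along(dns), each = length(ups))]
  mkey <- mup + 2^n * mdn
  Sp <- matrix(0, length(mkey), D)
  for (p in 0:(n - 1L)) {
    res <- oracle_apply_ops(dets$up, dets$dn,
                            list(c(1L, 0L, p), c(0L, 1L, p)))
    idx <- match(res$up + 2^n * res$dn, mkey)
    ok <- res$alive & !is.na(idx)
    if (any(ok))
      Sp[cbind(idx[ok], which(ok))] <- Sp[cbind(idx[ok], which(ok))] +
        res$phase[ok]
  }
  t(Sp) %*% Sp + diag_part
}

oracle_ground_energy <- function(h, basis = full_sector_basis(h)) {
  min(eigen(oracle_dense_h(h, basis), symmetric = TRUE)$values)
}

# brute-force sector enumeration for cross-checking hilbert_dimension
oracle_sector_count <- function(n_orb, na, nb) {
  words <- 0:(2^n_orb - 1)
  wa <- sum(cpp_popcount_oracle(words) == na)
  wb <- sum(cpp_popcount_oracle(words) == nb)
  wa * wb
}

random_state <- function(basis, seed = 1) {
  set.seed(seed)
  amp <- matrix(rnorm(length(basis$alpha_strings) *
                        length(basis$beta_strings)),
                length(basis$alpha_strings))
  ci_vector(basis, amp / sqrt(sum(amp^2)))
}
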