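#' Second-quantized molecular Hamiltonians
#'
#' Container for an electronic Hamiltonian over `n_orbitals` spatial
#' orbitals: a scalar core energy, a real symmetric one-body integral matrix
#' `h[p, r]` and a real two-body integral array `(pr|qs)` in chemist
#' notation with full 8-fold permutation symmetry. All energies in Hartree.
#' Integrals refer to an orthonormal (molecular-orbital) basis; any frozen
#' core or relativistic corrections are assumed folded into the supplied
#' integrals.
#'
#' @param n_orbitals number of spatial orbitals.
#' @param n_alpha,n_beta electron counts per spin species.
#' @param core_energy scalar constant (nuclear repulsion plus any folded
#'   inactive-space energy), Hartree.
#' @param one_body `n_orbitals x n_orbitals` symmetric matrix, Hartree.
#' @param two_body `n_orbitals^4` array `(pr|qs)`, Hartree.
#' @param validate check invariants (symmetries, electron counts).
#' @return object of class `molecular_hamiltonian`.
#' @export
molecular_hamiltonian <- function(n_orbitals, n_alpha, n_beta,
                                  core_energy = 0,
                                  one_body = NULL, two_body = NULL,
                                  validate = TRUE) {
  n <- as.integer(n_orbitals)
  if (is.null(one_body)) one_body <- matrix(0, n, n)
  if (is.null(two_body)) two_body <- array(0, dim = rep(n, 4L))
  h <- structure(list(n_orbitals = n,
                      n_alpha = as.integer(n_alpha),
                      n_beta = as.integer(n_beta),
                      core_energy = as.numeric(core_energy),
                      one_body = one_body, two_body = two_body),
                 class = "molecular_hamiltonian")
  if (validate) validate_hamiltonian(h)
  h
}

#' @rdname molecular_hamiltonian
#' @param h a `molecular_hamiltonian`.
#' @param tol symmetry tolerance.
#' @export
validate_hamiltonian <- function(h, tol = 1e-10) {
  n <- h$n_orbitals
  stopifnot(n >= 1L, n <= 30L,
            h$n_alpha > 0L, h$n_beta > 0L,
            h$n_alpha <= n, h$n_beta <= n,
            identical(dim(h$one_body), c(n, n)),
            identical(dim(h$two_body), rep(n, 4L)))
  if (max(abs(h$one_body - t(h$one_body))) > tol)
    stop("one_body is not symmetric")
  g <- h$two_body
  perms <- list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2))
  for (p in perms)
    if (max(abs(g - aperm(g, p))) > tol)
      stop("two_body violates 8-fold permutation symmetry")
  invisible(h)
}

#' @export
print.molecular_hamiltonian <- function(x, ...) {
  cat("<molecular_hamiltonian>", x$n_orbitals, "orbitals, (",
      x$n_alpha, "+", x$n_beta, ") electrons, core energy",
      format(x$core_energy, digits = 10), "Eh\n")
  invisible(x)
}

symmetrize_two_body <- function(g) {
  (g + aperm(g, c(2, 1, 3, 4)) + aperm(g, c(1, 2, 4, 3)) +
     aperm(g, c(2, 1, 4, 3)) + aperm(g, c(3, 4, 1, 2)) +
     aperm(g, c(4, 3, 1, 2)) + aperm(g, c(3, 4, 2, 1)) +
     aperm(g, c(4, 3, 2, 1))) / 8
}

#' Dimension of a fixed-particle-number Hilbert space sector
#'
#' The number of Slater determinants with `n_alpha` spin-up and `n_beta`
#' spin-down electrons in `n_orbitals` spatial orbitals,
#' `choose(M, Na) * choose(M, Nb)`, computed as an exact integer product
#' (exact up to 2^53).
#'
#' @param n_orbitals,n_alpha,n_beta sector sizes.
#' @return the sector dimension as a double holding an exact integer.
#' @export
hilbert_dimension <- function(n_orbitals, n_alpha, n_beta) {
  if (n_alpha < 0 || n_beta < 0 || n_orbitals < 0)
    stop("negative counts")
  if (n_alpha > n_orbitals || n_beta > n_orbitals) return(0)
  binom_exact <- function(n, k) {
    k <- min(k, n - k)
    r <- 1
    if (k > 0) for (i in seq_len(k)) r <- (r * (n - k + i)) / i
    round(r)
  }
  binom_exact(n_orbitals, n_alpha) * binom_exact(n_orbitals, n_beta)
}

# ---- FCIDUMP ----

#' Read an FCIDUMP integral file
#'
#' Molpro-dialect FCIDUMP: a namelist header declaring `NORB`, `NELEC` and
#' `MS2` followed by lines `value i j k l` with 1-based orbital indices.
#' Four nonzero indices store the chemist-notation integral `(ij|kl)`
#' (expanded to all 8 symmetry partners), `k = l = 0` stores the one-body
#' element `h[i, j]`, and the all-zero index line the core energy.
#'
#' @param path file path.
#' @return a [molecular_hamiltonian] with
#'   `n_alpha = (NELEC + MS2) / 2`, `n_beta = (NELEC - MS2) / 2`.
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr_end <- grep("(&END|^\\s*/\\s*$)", lines, ignore.case = TRUE)[1L]
  if (is.na(hdr_end)) stop("malformed FCIDUMP header: no &END")
  hdr <- paste(lines[seq_len(hdr_end)], collapse = " ")
  getval <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "\\s*=\\s*-?[0-9]+"), hdr,
                                 ignore.case = TRUE))
    if (!length(m)) stop("malformed FCIDUMP header: missing ", key)
    as.integer(sub(".*=\\s*", "", m))
  }
  norb <- getval("NORB"); nelec <- getval("NELEC"); ms2 <- getval("MS2")
  if ((nelec + ms2) %% 2L != 0L)
    stop("inconsistent NELEC/MS2: NELEC + MS2 must be even")
  body <- lines[-seq_len(hdr_end)]
  body <- body[nzchar(trimws(body))]
  toks <- scan(text = body, what = numeric(), quiet = TRUE)
  if (length(toks) %% 5L != 0L) stop("malformed FCIDUMP data line")
  m <- matrix(toks, ncol = 5L, byrow = TRUE)
  val <- m[, 1L]; ii <- m[, 2L]; jj <- m[, 3L]; kk <- m[, 4L]; ll <- m[, 5L]
  if (any(ii != round(ii) | jj != round(jj) | kk != round(kk) |
            ll != round(ll)))
    stop("non-integer orbital index")
  if (any(c(ii, jj, kk, ll) < 0) || any(c(ii, jj, kk, ll) > norb))
    stop("orbital index out of range [0, NORB]")
  h1 <- matrix(0, norb, norb)
  g2 <- array(0, dim = rep(norb, 4L))
  e0 <- 0
  two <- ii > 0 & jj > 0 & kk > 0 & ll > 0
  one <- ii > 0 & jj > 0 & kk == 0 & ll == 0
  zer <- ii == 0 & jj == 0 & kk == 0 & ll == 0
  bad <- !(two | one | zer)
  if (any(bad)) stop("unsupported index pattern in FCIDUMP line")
  if (any(zer)) e0 <- val[which(zer)[sum(zer)]]
  for (t in which(one)) {
    h1[ii[t], jj[t]] <- val[t]
    h1[jj[t], ii[t]] <- val[t]
  }
  for (t in which(two)) {
    i <- ii[t]; j <- jj[t]; k <- kk[t]; l <- ll[t]
    for (pr in list(c(i, j), c(j, i)))
      for (qs in list(c(k, l), c(l, k))) {
        g2[pr[1L], pr[2L], qs[1L], qs[2L]] <- val[t]
        g2[qs[1L], qs[2L], pr[1L], pr[2L]] <- val[t]
      }
  }
  molecular_hamiltonian(norb, (nelec + ms2) %/% 2L, (nelec - ms2) %/% 2L,
                        e0, h1, g2)
}

#' Write an FCIDUMP integral file
#'
#' Emits the Molpro dialect described in [read_fcidump]: only
#' symmetry-unique two-body entries with magnitude above `tol` are written,
#' `ORBSYM` is all 1 and `ISYM = 1` (point-group symmetry is not used).
#'
#' @param h a [molecular_hamiltonian].
#' @param path output path.
#' @param tol sparsity threshold for two-body integrals.
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(h, path, tol = 1e-12) {
  n <- h$n_orbitals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n,
                       h$n_alpha + h$n_beta, h$n_alpha - h$n_beta),
               paste0(" ORBSYM=", paste(rep("1,", n), collapse = "")),
               " ISYM=1,", "&END"), con)
  fmt <- function(v, i, j, k, l) sprintf("%.16E %d %d %d %d", v, i, j, k, l)
  out <- character(0)
  for (i in seq_len(n)) for (j in seq_len(i)) for (k in seq_len(i)) {
    lmax <- if (k == i) j else k
    for (l in seq_len(lmax)) {
      v <- h$two_body[i, j, k, l]
      if (abs(v) > tol) out <- c(out, fmt(v, i, j, k, l))
    }
  }
  for (i in seq_len(n)) for (j in seq_len(i))
    if (abs(h$one_body[i, j]) > tol)
      out <- c(out, fmt(h$one_body[i, j], i, j, 0L, 0L))
  out <- c(out, fmt(h$core_energy, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}

#' Generate small test Hamiltonians
#'
#' `"diagonal"`: diagonal one-body `h[p, p] = p` (0-based), no two-body
#' term, so the ground state is the single determinant filling the lowest
#' orbitals. `"pairing"`: an orbital-energy ladder with weak random
#' correlation, giving a correlated but concentrated ground state.
#' `"random"`: dense Gaussian integrals symmetrized to the full 8-fold
#' symmetry, scaled so correlation is appreciable.
#'
#' @param kind one of `"diagonal"`, `"pairing"`, `"random"`.
#' @param n_orbitals,n_alpha,n_beta sector sizes.
#' @param seed RNG seed (used by `"random"` and `"pairing"`); results are
#'   deterministic given the seed.
#' @return a [molecular_hamiltonian].
#' @export
make_toy_hamiltonian <- function(kind = c("diagonal", "pairing", "random"),
                                 n_orbitals, n_alpha, n_beta, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n_orbitals)
  h1 <- matrix(0, n, n)
  g2 <- array(0, dim = rep(n, 4L))
  if (kind == "diagonal") {
    diag(h1) <- 0:(n - 1L)
  } else if (kind == "pairing") {
    # orbital ladder with weak random correlation: the ground state stays
    # concentrated around the determinant filling the lowest orbitals
    set.seed(seed)
    diag(h1) <- 2 * (0:(n - 1L))
    g2 <- array(stats::rnorm(n^4, sd = 0.15), dim = rep(n, 4L))
    g2 <- symmetrize_two_body(g2)
  } else {
    set.seed(seed)
    h1 <- matrix(stats::rnorm(n * n), n, n)
    h1 <- (h1 + t(h1)) / 2
    g2 <- array(stats::rnorm(n^4, sd = 0.3), dim = rep(n, 4L))
    g2 <- symmetrize_two_body(g2)
  }
  molecular_hamiltonian(n, n_alpha, n_beta, 0, h1, g2)
}
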