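#' CI vectors over factorized determinant bases
#'
#' A normalized wave function expanded over a [subspace_basis]: the
#' amplitude matrix (possibly complex for ansatz states) has unit
#' Frobenius norm. A `subspace_state` from [project_and_solve] converts
#' directly.
#'
#' @param basis a [subspace_basis].
#' @param amplitudes numeric or complex matrix
#'   `length(alpha_strings) x length(beta_strings)`.
#' @return object of class `ci_vector`.
#' @export
ci_vector <- function(basis, amplitudes) {
  stopifnot(inherits(basis, "subspace_basis"),
            nrow(amplitudes) == length(basis$alpha_strings),
            ncol(amplitudes) == length(basis$beta_strings))
  nrm <- sqrt(sum(Mod(amplitudes)^2))
  if (nrm < 1e-12) stop("zero-norm state")
  if (abs(nrm - 1) > 1e-10) amplitudes <- amplitudes / nrm
  structure(list(basis = basis, amplitudes = amplitudes),
            class = "ci_vector")
}

#' @rdname ci_vector
#' @param x a `subspace_state` or `ci_vector`.
#' @export
as_ci_vector <- function(x) {
  if (inherits(x, "ci_vector")) return(x)
  ci_vector(x$basis, x$amplitudes)
}

#' Exact ground state of a small Hamiltonian
#'
#' Full-sector diagonalization via [project_and_solve]; intended for test
#' fixtures and for emulating noiseless sampling on desk-scale systems.
#'
#' @param h a [molecular_hamiltonian].
#' @param opts a [solver_options].
#' @param max_dimension guard against accidentally huge sectors.
#' @return a `subspace_state`.
#' @export
exact_ground_state <- function(h, opts = solver_options(),
                               max_dimension = 2e6) {
  dim <- hilbert_dimension(h$n_orbitals, h$n_alpha, h$n_beta)
  if (dim > max_dimension)
    stop("full sector dimension ", dim, " exceeds cap ", max_dimension)
  project_and_solve(h, full_sector_basis(h), opts)
}

#' Sample configurations from a CI vector
#'
#' Draws `n_shots` independent configurations from the Born distribution
#' `P(x) = |<x|psi>|^2`.
#'
#' @param state a `ci_vector` or `subspace_state`.
#' @param n_shots number of draws.
#' @param seed optional RNG seed for reproducibility.
#' @return a [sample_set].
#' @export
sample_exact <- function(state, n_shots, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- as_ci_vector(state)
  p <- as.numeric(Mod(state$amplitudes)^2)
  draw_from_state(state, p, n_shots)
}

draw_from_state <- function(state, p, n_shots) {
  basis <- state$basis
  na <- length(basis$alpha_strings)
  if (n_shots == 0L)
    return(sample_set(integer(0), integer(0), integer(0), basis$n_orbitals))
  idx <- sample.int(length(p), n_shots, replace = TRUE, prob = p)
  ia <- ((idx - 1L) %% na) + 1L
  ib <- ((idx - 1L) %/% na) + 1L
  sample_set(basis$alpha_strings[ia], basis$beta_strings[ib], 1L,
             basis$n_orbitals)
}

#' Sample through a global depolarizing channel
#'
#' Each shot is drawn from the state's Born distribution with probability
#' `alpha` (the signal fraction) and otherwise uniformly over all `2^M`
#' bit words, `M = 2 * n_orbitals` — including words in wrong particle
#' sectors. `alpha = 1` reproduces [sample_exact]; `alpha = 0` is pure
#' uniform noise.
#'
#' @param state a `ci_vector` or `subspace_state`.
#' @param alpha signal fraction in `[0, 1]`.
#' @param n_shots number of draws.
#' @param seed optional RNG seed.
#' @return a [sample_set].
#' @export
depolarize <- function(state, alpha, n_shots, seed = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!is.null(seed)) set.seed(seed)
  state <- as_ci_vector(state)
  n_orb <- state$basis$n_orbitals
  n_sig <- rbinom(1L, n_shots, alpha)
  sig <- sample_exact(state, n_sig)
  n_noise <- n_shots - n_sig
  up <- sample.int(2L^n_orb, n_noise, replace = TRUE) - 1L
  dn <- sample.int(2L^n_orb, n_noise, replace = TRUE) - 1L
  sample_set(c(sig$up, up), c(sig$dn, dn), c(sig$count, rep(1L, n_noise)),
             n_orb)
}
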