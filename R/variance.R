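#' Hamiltonian variance of a subspace state
#'
#' Computes `<psi|H^2|psi> - <psi|H|psi>^2` exactly: the state is embedded
#' in the connected space (all determinants reachable by up to two single
#' excitations per spin species from the basis strings), `H |psi>` is
#' formed there, and `<H^2> = ||H psi||^2`. The connected space grows as
#' the square of the extended string lists; a capacity cap guards against
#' runaway sizes.
#'
#' @param h a [molecular_hamiltonian].
#' @param state a `subspace_state` or `ci_vector` with real amplitudes.
#' @param max_dimension connected-space capacity cap.
#' @return list of class `ev_point`: `energy` (Hartree), `variance`
#'   (Hartree^2), `scaled_variance` (`variance / energy^2`), `dimension`
#'   of the originating subspace.
#' @export
hamiltonian_variance <- function(h, state, max_dimension = 5e7) {
  basis <- state$basis
  n <- basis$n_orbitals
  aext <- cpp_excite_strings(basis$alpha_strings, n, 2L)
  bext <- if (identical(basis$beta_strings, basis$alpha_strings)) aext else
    cpp_excite_strings(basis$beta_strings, n, 2L)
  dim_ext <- as.numeric(length(aext)) * length(bext)
  if (dim_ext > max_dimension)
    stop("connected space dimension ", dim_ext, " exceeds cap ",
         max_dimension)
  ext <- subspace_basis(aext, bext, n)
  C <- matrix(0, length(aext), length(bext))
  C[cbind(match(basis$alpha_strings, aext)[row(state$amplitudes)],
          match(basis$beta_strings, bext)[col(state$amplitudes)])] <-
    as.numeric(state$amplitudes)
  ctx <- hamiltonian_context(h, ext)
  y <- context_apply_h(ctx, C)
  e <- sum(C * y)
  v <- sum(y * y) - e^2
  structure(list(energy = e, variance = v, scaled_variance = v / e^2,
                 dimension = subspace_dimension(basis)),
            class = "ev_point")
}

#' @export
print.ev_point <- function(x, ...) {
  cat("<ev_point> E =", format(x$energy, digits = 10),
      " Var(H) =", format(x$variance, digits = 6), "Eh^2\n")
  invisible(x)
}

#' Energy-variance extrapolation to the zero-variance limit
#'
#' Ordinary least squares of the variational energies against the
#' Hamiltonian variance; the intercept estimates the exact eigenstate
#' energy. The default abscissa is the variance scaled by the squared
#' energy (`variance / energy^2`); `abscissa = "raw"` fits against the
#' plain variance. Optional inverse-variance weighting.
#'
#' @param points list of `ev_point`s (or a data frame with columns
#'   `energy` and `variance`).
#' @param abscissa `"scaled"` or `"raw"`.
#' @param weights optional fit weights.
#' @return list of class `ev_extrapolation`: `intercept` (energy
#'   estimate, Hartree), `slope`, `intercept_stderr`, `n_points`,
#'   `abscissa`.
#' @export
extrapolate <- function(points, abscissa = c("scaled", "raw"),
                        weights = NULL) {
  abscissa <- match.arg(abscissa)
  df <- as_ev_frame(points)
  if (nrow(df) < 2L) stop("need at least 2 energy-variance points")
  x <- if (abscissa == "scaled") df$variance / df$energy^2 else df$variance
  if (max(x) - min(x) < 1e-14) stop("degenerate abscissae: no spread")
  fit <- if (is.null(weights)) lm(df$energy ~ x) else
    lm(df$energy ~ x, weights = weights)
  # suppressWarnings: an exact line triggers a "perfect fit" note in
  # summary.lm; the zero standard error it yields is the right answer
  vc <- suppressWarnings(vcov(fit))
  structure(list(intercept = unname(coef(fit)[1L]),
                 slope = unname(coef(fit)[2L]),
                 intercept_stderr = sqrt(vc[1L, 1L]),
                 n_points = nrow(df), abscissa = abscissa),
            class = "ev_extrapolation")
}

#' @export
print.ev_extrapolation <- function(x, ...) {
  cat("<ev_extrapolation> E(var -> 0) =", format(x$intercept, digits = 10),
      "+-", format(x$intercept_stderr, digits = 3), "Eh from",
      x$n_points, "points\n")
  invisible(x)
}

as_ev_frame <- function(points) {
  if (is.data.frame(points)) return(points)
  if (inherits(points, "ev_point")) points <- list(points)
  data.frame(
    dimension = vapply(points, function(p)
      if (is.null(p$dimension)) NA_real_ else p$dimension, numeric(1)),
    energy = vapply(points, function(p) p$energy, numeric(1)),
    variance = vapply(points, function(p) p$variance, numeric(1)))
}

#' Read and write energy-variance tables
#'
#' CSV with columns `dimension`, `energy`, `variance` for interchange with
#' external plotting tools.
#'
#' @param points list of `ev_point`s or a data frame.
#' @param path file path.
#' @return `read_ev_points`: a data frame; `write_ev_points`: the path.
#' @export
write_ev_points <- function(points, path) {
  write.csv(as_ev_frame(points), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ev_points
#' @export
read_ev_points <- function(path) {
  read.csv(path)
}
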