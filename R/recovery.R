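#' Options for self-consistent configuration recovery
#'
#' @param delta corner value of the modified-ReLU flip weight,
#'   `w(h) = delta` (default 0.01).
#' @param corner corner location `h` in `(0, 1)`; default `NULL` means the
#'   filling factor `N / M` of the target sector, resolved at run time.
#' @param max_iterations cap on self-consistent recovery iterations
#'   (default 5).
#' @param energy_tolerance stopping threshold on the change of the
#'   min-over-batches energy, Hartree (default 1e-3).
#' @return list of class `recovery_options`.
#' @export
recovery_options <- function(delta = 0.01, corner = NULL,
                             max_iterations = 5L, energy_tolerance = 1e-3) {
  stopifnot(delta >= 0, delta < 1,
            is.null(corner) || (corner > 0 && corner < 1))
  structure(list(delta = delta, corner = corner,
                 max_iterations = as.integer(max_iterations),
                 energy_tolerance = energy_tolerance),
            class = "recovery_options")
}

resolve_corner <- function(opts, n_orbitals, n_alpha, n_beta) {
  if (!is.null(opts$corner)) return(opts$corner)
  (n_alpha + n_beta) / (2 * n_orbitals)
}

#' Modified-ReLU recovery weight
#'
#' Piecewise-linear weight of flipping a bit whose value sits at distance
#' `y` from the reference occupancy: `w(y) = delta * y / h` for `y <= h`
#' and `delta + (1 - delta) * (y - h) / (1 - h)` above the corner.
#' Continuous, monotone nondecreasing, `w(0) = 0`, `w(h) = delta`,
#' `w(1) = 1`.
#'
#' @param y distances in `[0, 1]` (vectorized).
#' @param delta corner value.
#' @param corner corner location `h`.
#' @return weights in `[0, 1]`.
#' @export
recovery_weight <- function(y, delta = 0.01, corner = 0.5) {
  if (any(y < 0 | y > 1)) stop("distance outside [0, 1]")
  ifelse(y <= corner, delta * y / corner,
         delta + (1 - delta) * (y - corner) / (1 - corner))
}

# Vectorized repair of one spin species over many shots.
# strings: current half words; target: wanted Hamming weight; nref: NMO
# reference occupancies of this spin species. Returns repaired words.
repair_species <- function(strings, target, nref, n_orb, delta, corner) {
  nx <- popcount(strings)
  need <- which(nx != target)
  if (!length(need)) return(strings)
  s <- strings[need]
  k <- abs(nx[need] - target)
  excess <- nx[need] > target
  bits <- string_bits(s, n_orb)
  # candidate bits: occupied when in excess, empty when in deficit
  cand <- bits == ifelse(excess, 1L, 0L)
  dist <- abs(bits - matrix(nref, length(s), n_orb, byrow = TRUE))
  w <- matrix(recovery_weight(as.numeric(dist), delta, corner),
              nrow = length(s))
  # sequential weighted sampling without replacement == exponential keys
  key <- matrix(rexp(length(w)) / w, nrow = length(s))
  # zero-weight candidates act only as a uniform fallback; non-candidates
  # must sort after every candidate
  key[cand & w == 0] <- 1e300 * (1 + runif(sum(cand & w == 0)))
  key[!cand] <- Inf
  row <- row(key); tie <- runif(length(key))
  ord <- order(row, key, tie)
  rank_in_row <- ave(seq_along(ord), row[ord], FUN = seq_along)
  pick <- matrix(FALSE, length(s), n_orb)
  pick[ord] <- rank_in_row <= k[row[ord]]
  # never pick non-candidates even when k exceeds candidate count
  pick <- pick & cand
  flip_mask <- as.integer(pick %*% 2L^(0:(n_orb - 1L)))
  strings[need] <- bitwXor(s, flip_mask)
  if (any(popcount(strings[need]) != target))
    stop("impossible repair: not enough candidate bits")
  strings
}

#' Repair a single wrong-particle-number configuration
#'
#' Flips `|N_x - N|` bits per spin species — occupied bits cleared in
#' excess, empty bits set in deficit — drawn sequentially without
#' replacement with probability proportional to
#' `w(|x[p, sigma] - n[p, sigma]|)` ([recovery_weight]). The two spin
#' species are repaired independently.
#'
#' @param x a [configuration] (one or more entries).
#' @param n an `occupancy_vector` (see [occupancies]).
#' @param n_alpha,n_beta target per-spin electron counts.
#' @param opts a [recovery_options].
#' @return a [configuration] with exact target particle numbers.
#' @export
recover_configuration <- function(x, n, n_alpha, n_beta,
                                  opts = recovery_options()) {
  n_orb <- x$n_orbitals
  stopifnot(length(n) == 2L * n_orb)
  h <- resolve_corner(opts, n_orb, n_alpha, n_beta)
  up <- repair_species(x$up, n_alpha, n[seq_len(n_orb)], n_orb,
                       opts$delta, h)
  dn <- repair_species(x$dn, n_beta, n[n_orb + seq_len(n_orb)], n_orb,
                       opts$delta, h)
  configuration(up, dn, n_orb)
}

#' Repair every configuration of a rejected sample set
#'
#' Each shot is repaired independently per [recover_configuration];
#' multiplicities are preserved (a configuration observed `c` times is
#' repaired `c` times with independent draws).
#'
#' @param rejected a [sample_set] of wrong-particle-number samples.
#' @param n an `occupancy_vector`.
#' @param n_alpha,n_beta target sector.
#' @param opts a [recovery_options].
#' @return a [sample_set] whose entries all lie in the target sector.
#' @export
recover_all <- function(rejected, n, n_alpha, n_beta,
                        opts = recovery_options()) {
  n_orb <- attr(rejected, "n_orbitals")
  if (!nrow(rejected))
    return(sample_set(integer(0), integer(0), integer(0), n_orb))
  up <- rep(rejected$up, rejected$count)
  dn <- rep(rejected$dn, rejected$count)
  x <- configuration(up, dn, n_orb)
  fixed <- recover_configuration(x, n, n_alpha, n_beta, opts)
  sample_set(fixed$up, fixed$dn, 1L, n_orb)
}
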