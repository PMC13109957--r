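#' @useDynLib sqdr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rexp runif sd setNames lm coef vcov
#' @importFrom utils read.csv write.csv head
NULL

# ---- bit helpers (half-strings are non-negative integers over n_orb bits) ----

popcount <- function(x) cpp_popcount(as.integer(x))

string_bits <- function(strings, n_orb) {
  # rows: strings, cols: orbitals 0..n_orb-1
  matrix(vapply(0:(n_orb - 1L),
                function(b) bitwAnd(bitwShiftR(as.integer(strings), b), 1L),
                integer(length(strings))),
         nrow = length(strings), ncol = n_orb)
}

bits_to_string <- function(bits) {
  # bits: matrix rows = configurations, cols = orbitals (0 fastest)
  as.integer(bits %*% 2L^(0:(ncol(bits) - 1L)))
}

half_to_text <- function(strings, n_orb) {
  bits <- string_bits(strings, n_orb)
  apply(bits[, n_orb:1, drop = FALSE], 1L, paste0, collapse = "")
}

text_to_half <- function(txt) {
  n_orb <- nchar(txt[1L])
  chars <- matrix(as.integer(unlist(strsplit(txt, "")) == "1"),
                  ncol = n_orb, byrow = TRUE)
  bits_to_string(chars[, n_orb:1, drop = FALSE])
}

#' Electronic configurations in the Jordan-Wigner convention
#'
#' A `configuration` holds one or more Slater determinants over `n_orbitals`
#' spatial orbitals as a pair of half-strings: `up` carries the spin-up
#' occupations (bit `p` of `up` is orbital `p`, spin alpha) and `dn` the
#' spin-down occupations. The text rendering places the spin-down half first
#' and orbital indices in decreasing order, so the rightmost character is
#' orbital 0, spin up.
#'
#' @param up,dn integer vectors of half-string bit words.
#' @param n_orbitals number of spatial orbitals (half-string width).
#' @return an object of class `configuration`.
#' @export
configuration <- function(up, dn, n_orbitals) {
  n_orbitals <- as.integer(n_orbitals)
  stopifnot(n_orbitals >= 1L, n_orbitals <= 30L, length(up) == length(dn))
  up <- as.integer(up); dn <- as.integer(dn)
  if (length(up) && (max(up, dn) >= 2L^n_orbitals || min(up, dn) < 0L))
    stop("bit word wider than 2 * n_orbitals")
  structure(list(up = up, dn = dn, n_orbitals = n_orbitals),
            class = "configuration")
}

#' @export
format.configuration <- function(x, ...) {
  paste0(half_to_text(x$dn, x$n_orbitals), half_to_text(x$up, x$n_orbitals))
}

#' @export
print.configuration <- function(x, ...) {
  cat("<configuration> width", 2L * x$n_orbitals, "\n")
  print(format(x))
  invisible(x)
}

#' @export
length.configuration <- function(x) length(x$up)

#' Parse configurations from their text rendering
#'
#' @param text character vector of fixed-width 0/1 strings (width
#'   `2 * n_orbitals`, spin-down half leftmost).
#' @return a [configuration].
#' @export
parse_configuration <- function(text) {
  w <- unique(nchar(text))
  if (length(w) != 1L || w %% 2L != 0L)
    stop("configurations must share one even width")
  n_orb <- w %/% 2L
  dn <- text_to_half(substr(text, 1L, n_orb))
  up <- text_to_half(substr(text, n_orb + 1L, w))
  configuration(up, dn, n_orb)
}

#' Restricted Hartree-Fock configuration
#'
#' The determinant occupying the lowest `n_alpha` spin-up and `n_beta`
#' spin-down orbitals.
#'
#' @param n_orbitals,n_alpha,n_beta sizes of the sector.
#' @return a single [configuration].
#' @export
rhf_bitstring <- function(n_orbitals, n_alpha, n_beta) {
  stopifnot(n_alpha >= 0, n_beta >= 0,
            n_alpha <= n_orbitals, n_beta <= n_orbitals)
  fill <- function(k) if (k == 0L) 0L else as.integer(2L^k - 1L)
  configuration(fill(as.integer(n_alpha)), fill(as.integer(n_beta)),
                n_orbitals)
}

#' Per-spin particle numbers of configurations
#'
#' @param x a [configuration].
#' @return a two-column integer matrix with columns `n_alpha`, `n_beta`.
#' @export
particle_numbers <- function(x) {
  cbind(n_alpha = popcount(x$up), n_beta = popcount(x$dn))
}

#' Spin inversion (swap the spin-up and spin-down halves)
#'
#' @param x a [configuration].
#' @return the spin-inverted [configuration].
#' @export
spin_invert <- function(x) configuration(x$dn, x$up, x$n_orbitals)

#' Split a configuration into its spin halves
#'
#' @param x a [configuration].
#' @return list with character vectors `dn` and `up` (text form).
#' @export
split_halves <- function(x) {
  list(dn = half_to_text(x$dn, x$n_orbitals),
       up = half_to_text(x$up, x$n_orbitals))
}

#' Join spin halves into a configuration
#'
#' @param dn,up equal-width 0/1 text halves (spin-down, spin-up).
#' @return a [configuration].
#' @export
join_halves <- function(dn, up) {
  if (!all(nchar(dn) == nchar(up))) stop("halves must have equal width")
  parse_configuration(paste0(dn, up))
}

# ---- sample sets ----

#' Multisets of sampled configurations
#'
#' A `sample_set` maps configurations to positive multiplicities. Duplicate
#' entries are merged on construction; `total_shots` is the multiset size.
#'
#' @param up,dn half-string words (recycled against each other).
#' @param count positive integer multiplicities.
#' @param n_orbitals half-string width.
#' @return an object of class `sample_set`: a data frame with columns
#'   `up`, `dn`, `count` and attribute `n_orbitals`.
#' @export
sample_set <- function(up, dn, count = 1L, n_orbitals) {
  n_orbitals <- as.integer(n_orbitals)
  count <- as.integer(rep_len(count, length(up)))
  stopifnot(all(count > 0L) || length(count) == 0L)
  df <- data.frame(up = as.integer(up), dn = as.integer(dn), count = count)
  if (nrow(df)) {
    ord <- order(df$dn, df$up)
    u <- df$up[ord]; d <- df$dn[ord]; cnt <- df$count[ord]
    grp <- cumsum(c(TRUE, diff(u) != 0L | diff(d) != 0L))
    first <- !duplicated(grp)
    df <- data.frame(up = u[first], dn = d[first],
                     count = as.integer(rowsum(cnt, grp)[, 1L]))
  }
  structure(df, n_orbitals = n_orbitals, class = c("sample_set", "data.frame"))
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set>", nrow(x), "unique configurations,",
      total_shots(x), "shots, n_orbitals =", attr(x, "n_orbitals"), "\n")
  invisible(x)
}

#' Total number of shots in a sample set
#' @param x a [sample_set].
#' @return integer multiset size.
#' @export
total_shots <- function(x) sum(x$count)

#' @rdname sample_set
#' @param x a [sample_set].
#' @export
as_configuration <- function(x) {
  configuration(x$up, x$dn, attr(x, "n_orbitals"))
}

#' Partition samples by particle sector
#'
#' Splits a sample set into configurations with exactly (`n_alpha`,
#' `n_beta`) electrons per spin species and the rest.
#'
#' @param samples a [sample_set].
#' @param n_alpha,n_beta target per-spin electron counts.
#' @return list with [sample_set]s `kept` and `rejected`; total shots are
#'   conserved.
#' @export
filter_by_particle_number <- function(samples, n_alpha, n_beta) {
  ok <- popcount(samples$up) == n_alpha & popcount(samples$dn) == n_beta
  n_orb <- attr(samples, "n_orbitals")
  list(kept = sample_set(samples$up[ok], samples$dn[ok], samples$count[ok],
                         n_orb),
       rejected = sample_set(samples$up[!ok], samples$dn[!ok],
                             samples$count[!ok], n_orb))
}

#' Read and write sample tables
#'
#' CSV files have a header `bitstring,count` with bitstrings in the text
#' rendering of [configuration]; JSON files are one object mapping bitstring
#' to count.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @param n_orbitals expected half-width; checked against the file.
#' @return a [sample_set].
#' @export
read_samples <- function(path, n_orbitals = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- data.frame(bitstring = names(m), count = as.integer(unlist(m)))
  } else {
    df <- read.csv(path, colClasses = c("character", "integer"))
    names(df) <- c("bitstring", "count")
  }
  cfg <- parse_configuration(df$bitstring)
  if (!is.null(n_orbitals) && cfg$n_orbitals != n_orbitals)
    stop("sample width ", 2L * cfg$n_orbitals,
         " does not match 2 * n_orbitals = ", 2L * n_orbitals)
  sample_set(cfg$up, cfg$dn, df$count, cfg$n_orbitals)
}

#' @rdname read_samples
#' @param samples a [sample_set] to write.
#' @export
write_samples <- function(samples, path) {
  txt <- format(as_configuration(samples))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(setNames(samples$count, txt)), path,
                         auto_unbox = TRUE)
  } else {
    write.csv(data.frame(bitstring = txt, count = samples$count), path,
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
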