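Package: sqdr
Title: Sample-Based Quantum Diagonalization for Molecular Hamiltonians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical toolkit for sample-based quantum diagonalization (SQD)
    of second-quantized molecular Hamiltonians. Reads and writes FCIDUMP
    integral files, emulates configuration sampling from exact states, global
    depolarizing mixtures and a local unitary cluster Jastrow (LUCJ) ansatz,
    repairs wrong-particle-number samples by self-consistent configuration
    recovery, projects and diagonalizes the Hamiltonian in spin-closed
    sampled determinant subspaces with a total-spin penalty using a
    string-based Davidson solver, and extrapolates variational energies to
    the zero-variance limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr,
    Matrix
Config/testthat/edition: 3
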