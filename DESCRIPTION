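Package: adaptvqe
Title: Adaptive Ansatz-Growth Variational Quantum Eigensolver Emulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Classical statevector emulation of the adaptive,
    gradient-screened variational quantum eigensolver (ADAPT-VQE) for
    molecular electronic ground states, together with its standard
    baselines: un-Trotterized unitary coupled cluster with singles and
    doubles (UCCSD), Trotterized generalized UCC, fixed-order
    ansatz-growth controls, and sector-restricted full configuration
    interaction. Includes a Molpro-style FCIDUMP reader and writer,
    Jordan-Wigner fermion-to-qubit mapping, spin-complemented excitation
    operator pools, an analytic-gradient VQE inner loop, and
    dissociation-curve scan drivers with error summaries against FCI.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
LinkingTo: Rcpp
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
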