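Package: dmrgfq
Title: Polarizable QM/MM Excited States with DMRG and Fluctuating Charges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Matrix-product-state density matrix renormalization group (DMRG)
    solver for complete-active-space wave functions, self-consistently coupled
    to a fluctuating-charge (FQ) polarizable classical environment. Provides
    an Ohno-kernel electronegativity-equalization charge solver, a minimal
    s-type Gaussian integral backend and FCIDUMP import for active-space
    Hamiltonians, two-site DMRG sweeps with excited-state targeting, orbital
    optimization under the extended Brillouin condition with FQ contributions
    in the gradient, a mutual-polarization macro-iteration for state-specific
    ground- and excited-state energies, and a snapshot pipeline for
    droplet extraction, ensemble statistics and solvatochromic shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
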