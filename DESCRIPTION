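Package: tautodyn
Title: Entanglement Dynamics of a DNA-mRNA Qubit Pair Under Tautomeric
    Decoherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Open-quantum-systems model of a DNA-mRNA pair of two-level
    systems (tautomeric base superpositions), each coupled to an
    independent bosonic reservoir. Provides the survival probability of
    the initial entangled state, the time-evolved reduced density matrix
    in X form, Wootters concurrence (both the general spin-flip
    eigenvalue procedure and the model's closed form), entanglement of
    formation, entanglement sudden-death detection, Ohmic
    spectral-density and decay-rate integrals with principal-value
    quadrature, a Zurek-style decoherence-time estimator, and
    figure-style parameter sweeps with CSV/JSON output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
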