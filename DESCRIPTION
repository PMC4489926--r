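Package: stickyknots
Title: Knotting of Coarse-Grained DNA Chains with Adhesive Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the circularization of a coarse-grained bead-spring
    (Kremer-Grest) DNA chain carrying two pairs of permanently adhesive
    monomers under Langevin dynamics, identifies the knot type of the
    resulting ring through geometric chain simplification and Alexander
    polynomial determinants, classifies whether the internal sticky loop
    is topologically relevant to the knot, and aggregates relative
    knotting probabilities, loop-closure fractions and knot spectra over
    a grid of adhesive-site placements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
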