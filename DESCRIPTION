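Package: cellchains
Title: Stochastic Dynamics of Cell Populations Across Compartment Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for multi-type branching-process models of cell division,
    death and differentiation across an ordered sequence of compartments.
    Cells self-renew, divide symmetrically or asymmetrically, differentiate
    forwards or backwards, and die, each at a per-cell rate that may differ
    between compartments. The package provides exact stochastic simulation
    (Gillespie algorithm) of the population process, single-cell lifeline and
    progeny-tree simulation, closed-form and recursive summary statistics
    (mean compartment dynamics via matrix exponentials and closed forms,
    progeny means and distributions via probability generating functions and
    tridiagonal first-step systems, lifeline lifespans, division counts and
    death-compartment probabilities), local sensitivity/elasticity analysis,
    and a bifurcated thymocyte-development topology, together with presets
    for published hematopoietic and thymic parameterisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
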