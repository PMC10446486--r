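Package: transportfe
Title: Free-Energy Analysis of Membrane Transporter Energetics and Ion Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the energetics of substrate transport by
    membrane proteins from molecular simulation output. Reconstructs one
    dimensional potentials of mean force from umbrella-sampling windows by the
    weighted histogram analysis method (WHAM) with Bayesian-bootstrap error
    estimation; estimates alchemical free energies from reduced-potential
    sample matrices with the multistate Bennett acceptance ratio (MBAR),
    Bennett acceptance ratio (BAR) and exponential averaging; composes
    directed free-energy legs into transport cycles with quadrature error
    propagation; models electrochemical ion gradients and derives
    coupling-ion stoichiometries as a function of membrane potential; and
    provides geometric probes of trajectories (cylinder-partitioned hydration
    counts, ion contact fractions, residue occupancies, minimum-image
    distances, positional RMSD and time-averaged density grids). Synthetic
    generators produce umbrella windows from analytic potentials, lambda
    coupled harmonic systems with closed-form free energies and toy
    membrane-protein trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
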