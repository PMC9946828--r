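Package: famhal
Title: Family-Wide Hallucination of Protein Scaffolds by Sequence-Space MCMC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates idealized protein scaffolds by family-wide hallucination:
    inter-residue distance and orientation (d, omega, theta, phi) restraint
    distributions are built from an ensemble of family backbones mapped through a
    common alignment, and a simulated-annealing Metropolis Monte Carlo search over
    sequences (substitutions everywhere, insertions and deletions confined to
    variable loops) minimizes a multicomponent loss: restraint cross-entropy over
    structurally conserved region pairs plus a confidence term equal to the
    negative KL divergence of predicted geometries from a background distribution
    over variable-region pairs. The structure-prediction oracle is a pluggable
    contract; a deterministic surrogate predictor and a synthetic-family fixture
    generator make the whole method testable at desk scale. Includes PDB backbone
    I/O, ideal C-beta reconstruction, and design-model inspection utilities
    (residue counts, chain masses, inter-atom distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
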