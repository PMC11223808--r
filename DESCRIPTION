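Package: actionpath
Title: Minimum-Action Transition Paths for Macromolecules with Elastic Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates non-linear transition paths between two conformations of a
    macromolecule or large assembly by minimizing the Onsager-Machlup action on a
    two-well coarse-grained energy surface. Each well is a quadratic expansion of an
    elastic network model (Tirion or Go-like potential) around one endpoint; the
    Euler-Lagrange equations are solved analytically per well and joined at a
    transition state that is continuous in position, velocity and energy. Large
    systems are handled with Krylov-subspace (Lanczos) evaluation of the required
    matrix functions. Includes PDB/mmCIF input, sequence-based chain matching of
    endpoints with different atom counts, Delaunay- or cutoff-based network
    geometries, multi-model mmCIF trajectory output, and per-frame analytics
    (energy, RMSD, native-contact fractions Q1/Q2).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    bio3d,
    Biostrings,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
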