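Package: azogeom
Title: Geometric Analysis of Azobenzene Photoswitch Side Chains in
    Host-Guest Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the structural analysis of azobenzene-based
    photoswitches displayed on proteins and enclosed by cyclodextrin
    hosts. Computes the conformational descriptor set of an azobenzene
    moiety (the chi_pre, chi_azo and chi_post dihedrals about the
    ring-N, N=N and N-ring bonds, and the interplanar angle between the
    two best-fit phenyl ring planes), optimal rigid-body (Kabsch)
    superpositions and C-alpha RMSDs over multi-interval residue
    ranges, Shrake-Rupley solvent-accessible surface areas with a
    three-context burial report for a guest side chain, donor/acceptor
    hydrogen-bond enumeration at the host rim, and average molecular
    masses of biosynthetic proteins carrying noncanonical residues and
    a matured GFP-type chromophore. A synthetic-structure generator
    builds azobenzene residues with exactly planted dihedrals, toroidal
    six-unit hosts and helical scaffolds so that every analysis stage
    is testable without external coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
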