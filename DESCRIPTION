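Package: patchsampler
Title: Side-Chain Conformational Ensembles for Protein Surface Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates small ensembles of side-chain conformations for
    protein surface patches, intended as docking candidates for flexible
    protein-protein docking. Surface patches of eight or nine flexible
    residues are carved out of the interface region, side chains are
    enumerated from a rotamer library supplemented with the unbound
    conformation, candidate conformations are filtered with a
    self-consistent mean field (SCMF) optimization stratified by chi1
    torsion bins under a capped Lennard-Jones plus Coulomb energy, and the
    surviving set is reduced by k-means clustering to at most 50
    representatives plus the unbound conformation. Includes the evaluation
    constructs (bound_UBB and rotamer_UBB grafts, best-pick RMSD summaries)
    used to measure how well an ensemble approximates a bound conformation,
    and a synthetic-fixture generator so the whole pipeline is testable
    without external structure files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
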