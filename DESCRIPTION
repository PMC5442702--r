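Package: flexfort
Title: Flexibility-Guided Enzyme Thermostabilization from B-Factor
    Comparison, Sequence Conservation and Trajectory Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for rigidifying flexible regions of an enzyme using a
    thermophilic homolog as a template. Normalizes crystallographic
    B-factors to z-scores, aligns the two sequences and maps the
    normalized profiles across gaps, and calls contiguous segments of
    elevated flexibility in the target. Combines the called segments
    with per-column residue frequencies from a family multiple sequence
    alignment to propose consensus substitutions and the minimal codon
    edits that realize them. Also provides self-contained trajectory
    analytics used to characterize designed mutants (superposition and
    per-residue RMSF, minimal inter-residue distance distributions,
    Shrake-Rupley solvent-accessible surface area, geometric
    hydrogen-bond occupancy with block errors, and a simplified
    Kabsch-Sander helix/strand/coil assignment), Michaelis-Menten /
    Lineweaver-Burk kinetics arithmetic, and deterministic seeded
    generators for synthetic structures, alignments, trajectories and
    rate data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'conservation.R'
    'flexfort-package.R'
    'flexibility.R'
    'utils.R'
    'kinetics.R'
    'proposer.R'
    'pipeline.R'
    'structure-io.R'
    'synthetic-data.R'
    'traj-metrics.R'
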