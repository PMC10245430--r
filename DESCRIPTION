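Package: torsionconf
Title: Autoregressive Torsion-Angle Prediction for Small-Molecule Conformer
    Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates 3D conformer ensembles for drug-like small molecules by
    predicting the normalized torsion angles of all rotatable bonds with an
    energy-conditioned autoregressive transformer, then rebuilding conformers
    from an initial distance-geometry structure by rigid fragment rotation.
    Includes a featurized molecular-graph reader, Weisfeiler-Lehman graph
    position encodings, normalized torsion geometry, a desk-scale training
    loop, coverage/matching (COV/MAT) ensemble evaluation with symmetry-aware
    heavy-atom RMSD, a synthetic torsion-potential fixture generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    ChemmineOB,
    bio3d,
    yaml,
    testthat (>= 3.0.0)
SystemRequirements: python3 with rdkit (seeded distance-geometry embedding)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
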