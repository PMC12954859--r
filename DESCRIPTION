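Package: LigandForge
Title: Ligand Restraint Dictionary Generation and Geometry Validation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates crystallographic refinement restraint dictionaries
    (bonds, angles, torsions, chiral volumes, planes) for chemical
    components from their bonded structure and 3D geometry, validates
    geometries against a reference table of ideal bond and angle values
    using a maximum-Z-score classification scheme, and verifies
    dictionaries by restraint-driven geometry minimization round-trips.
    Reads and writes chemical-component CIF and MDL SDF inputs and
    Monomer-Library-style restraint CIF output, handles protonation-state
    variants of acidic moieties and polymer-terminus trimming, and ships
    a synthetic fixture generator so the whole pipeline runs without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ChemmineR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Cheminformatics, StructuralPrediction, DataImport
RoxygenNote: 7.3.3
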