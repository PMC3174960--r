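Package: pepgeom
Title: Peptide-Bond Planarity and Pyramidalization Geometry from Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures peptide-bond geometry from atomic coordinates: backbone
    torsions (phi, psi, omega, omega3), the signed planarity deviation
    delta-omega, and the carbonyl-carbon pyramidalization angle theta-C,
    together with the survey machinery used to study their conformational
    dependence -- residue-level filtering (B-factor, occupancy, Gly/Pro,
    cis bonds, chain breaks), 15x15 degree Ramachandran binning with circular
    means, and period-120 harmonic plus linear trend fitting. Includes an
    internal-coordinate backbone builder (NeRF) able to synthesize ensembles
    with a prescribed sinusoidal delta-omega(psi) coupling, to idealize all
    trans omega angles to 180 degrees, and to quantify the resulting
    cumulative C-alpha trace distortion with and without Kabsch superposition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'angles.R'
    'structure-io.R'
    'backbone.R'
    'trends.R'
    'survey.R'
    'cli.R'
    'pepgeom-package.R'
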