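Package: liece
Title: Linear Interaction Energy with Continuum Electrostatics for
    Protein-Ligand Binding Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-point estimation of protein-ligand binding free energies by
    the linear interaction energy with continuum electrostatics (LIECE)
    approach. Computes van der Waals, Coulombic and Poisson continuum
    desolvation interaction terms on energy-minimized structures, screens
    docking poses with geometric interaction filters (salt bridge to the
    binding-pocket anchor residue, hydrogen-bond geometry, burial of polar
    atoms, solvent exposure of hydrophobic moieties), fits linear binding
    models with and without an intercept, monitors model stability by
    leave-one-out cross-validation, and predicts affinities for external
    ligand sets. Includes a synthetic-data layer that generates
    energy-affinity tables with known linear structure and toy charged
    pocket-ligand complexes whose component energies are brute-force
    checkable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
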