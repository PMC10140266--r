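Package: nesfe
Title: Non-Equilibrium Switching Relative Binding Free Energy Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale computational core of an automated SMILES-to-ddG
    relative binding free energy (RBFE) workflow based on non-equilibrium
    switching. Provides ligand ingestion with formal-charge consistency
    filtering, maximum-common-substructure (MCS) pose selection against a
    reference ligand, perturbation-map construction, work-based free energy
    estimation via the Crooks/Bennett maximum-likelihood estimator with
    bootstrapped and replica-aggregated uncertainties, cycle-closure
    reconstruction of absolute binding free energies by weighted least
    squares, benchmark metrics against experimental affinities with
    bootstrap confidence intervals and experimental-uncertainty null bands,
    synthetic data generators consistent with the Crooks fluctuation
    theorem, and a JSON-configured sequential workflow runner. Molecular
    dynamics and docking engines are out of scope and replaced by mock
    backends writing the same file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
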