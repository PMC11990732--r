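Package: quenchbind
Title: Fluorescence Quenching and Thermodynamic Analysis of
    Protein-Ligand Binding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of protein fluorescence titrations for small-molecule
    binding studies. Implements inner-filter correction of emission spectra,
    Stern-Volmer quenching analysis with static/dynamic mechanism
    classification, double-logarithm estimation of binding constants and
    stoichiometry with free-ligand depletion correction, van't Hoff
    thermodynamics (enthalpy, entropy, Gibbs energy and binding-force
    interpretation), competitive site-marker displacement analysis,
    synchronous-fluorescence peak-shift probes, and post-processing of
    docking free energies into inhibition constants. Includes a mass-action
    titration simulator with known ground truth for validating every
    analysis stage, and a pipeline that assembles a full study report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Proteomics, Pharmacogenomics
RoxygenNote: 7.3.3
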