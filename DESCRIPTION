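Package: nmrdyn
Title: Protein Stability and Backbone Dynamics from NMR Titrations,
    Relaxation, CPMG Dispersion and Thermal Melts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for denaturant-destabilization
    studies of small folded protein domains. Computes weighted amide
    chemical shift differences from HSQC titrations and fits per-residue
    dissociation constants with the one-site quadratic binding isotherm;
    implements the Lipari-Szabo (and extended) model-free formalism for
    backbone 15N R1/R2/heteronuclear-NOE data, including overall
    correlation time estimation, per-residue model selection and exchange
    (Rex) detection; evaluates and fits two-state Carver-Richards /
    Korzhnev CPMG relaxation-dispersion profiles globally across two
    static fields, with a Bloch-McConnell propagation oracle for
    verification; and fits two-state van't Hoff thermal unfolding curves
    of near-UV CD ellipticity to extract melting temperatures. Seeded
    forward-model generators produce every input table the pipeline
    consumes, so all stages are testable without spectrometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
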