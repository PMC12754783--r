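Package: G4LigandMS
Title: Native Mass Spectrometry Workflow for G-Quadruplex Ligand Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative workflow for characterizing ligand binding to DNA
    G-quadruplexes from native electrospray mass spectrometry, drift-tube ion
    mobility, circular dichroism and UV-melting data. Converts species
    intensities to concentrations and sequential dissociation constants (KD1,
    KD2) for 1:1 and 2:1 complexes, fits full titration series with free
    response factors, determines collision cross sections from stepped-field
    arrival times via the Mason-Schamp equation, classifies potassium adducts
    as specific or nonspecific (Poisson background) to count G-quartets, and
    processes optical melting and CD curves. Includes seeded synthetic-data
    generators emulating every instrument so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'masses.R'
    'spectra.R'
    'mzml.R'
    'equilibria.R'
    'titration.R'
    'mobility.R'
    'adducts.R'
    'optical.R'
    'synthetic.R'
    'pipeline.R'
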