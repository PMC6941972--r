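Package: gexmol
Title: Gene-Expression-Conditioned Molecular Generation with a Grammar
    SMILES Autoencoder and a Stacked Conditional WGAN-GP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates candidate small molecules conditioned on
    transcriptomic signatures. A context-free-grammar SMILES codec and a
    recurrent (GRU) autoencoder define a continuous molecular latent
    space; a two-stage conditional Wasserstein GAN with gradient penalty
    and an auxiliary signature-matching network generates latent
    molecules conditioned on landmark-gene expression signatures.
    Includes Frechet-distance training monitoring, a full evaluation
    suite (validity, uniqueness, synthetic accessibility filtering,
    MACCS/Morgan/Fraggle similarity, Murcko scaffold analysis,
    signature nearest-neighbour baselines, rank-test score comparison)
    and a synthetic L1000-style molecule/signature simulator for
    desk-scale training and testing. Cheminformatics primitives
    (sanitization, fingerprints, SA score, scaffolds) are delegated to
    RDKit through a bundled Python bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python'
    on the PATH (used by the cheminformatics bridge).
Config/testthat/edition: 3
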