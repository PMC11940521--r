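Package: gramdta
Title: Grammar-Based Drug-Target Affinity Regression with Chemical
    Perturbation Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Drug-target binding affinity regression that fuses three views of
    a drug-protein pair: a context-free-grammar encoding of the drug SMILES
    (production-rule one-hot matrices in the style of the grammar variational
    autoencoder), a 978-landmark-gene regulatory vector derived from
    L1000-style chemical-perturbation exports (replicate-normalised up/down
    regulation frequencies), and a one-hot encoding of the target amino-acid
    sequence. The three branches (1-D convolutional drug encoder, fully
    connected RNA-Seq encoder, convolutional or LSTM protein encoder) feed a
    fully connected regression head trained end-to-end with Adam on mean
    squared error; models are evaluated by MSE and concordance index.
    Includes an Earley chart parser for the SMILES grammar, readers for
    affinity tables and perturbation exports, deterministic synthetic-data
    generators, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
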