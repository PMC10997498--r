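Package: hitea
Title: Statistical Reactome Analysis of High-Throughput Experimentation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Extracts the 'reactome' of a high-throughput experimentation (HTE)
    reaction dataset: which reaction variables matter (random-forest variable
    importance on one-hot encoded conditions), which reagents are statistically
    best- or worst-in-class (Z-score normalised yields, one-way ANOVA and Tukey
    honest-significant-difference ranking), and how the ranked ligands populate
    chemical space (PCA of Morgan-type circular fingerprints). Includes the
    dataset curation pipeline (cleanup, catalyst/ligand splitting, one-hot
    encoding with correlation merging), reaction-class/substrate-subclass
    splitting with an inclusion rule, a seeded synthetic HTE campaign generator
    with planted ground truth, zero-yield and temporal ablations, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    randomForest,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
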