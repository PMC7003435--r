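Package: connectosync
Title: Comparing Structural and Transcriptome-Derived Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing a diffusion-MRI structural brain connectome
    with a transcriptome-derived genomic connectome. Implements tract-to-ROI
    reach probability from probabilistic-tractography path-distribution
    volumes, tissue-to-tissue transcriptional correlation (TTC) networks with
    covariate residualization, Barber-modularity bipartite module detection
    via two-stage LPAb+ label propagation, pathway over-representation and
    pathway-interaction chi-square analysis, tract-wise diffusion-measure
    association statistics with replication checks, and a sum-of-chi-square
    permutation gene-set test linking blood expression to tract diffusion
    measures. A synthetic-data module generates every input with planted
    ground truth so the full pipeline is testable without restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    RNifti,
    fgsea
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
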