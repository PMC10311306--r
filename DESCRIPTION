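Package: fedstrat
Title: Privacy-Preserving Federated Population Stratification via Projected PCA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Client-server population stratification for collaborative genomic
    studies without pooling genotypes. A server trains a PCA model on a public
    genotype panel and ships the projection matrix together with per-component
    sensitivities; each collaborator projects its local minor-allele dosage
    matrix through the model, perturbs the coordinates with Laplace noise to
    satisfy epsilon-local differential privacy, and shares pseudonymized
    metadata. The server aggregates the noisy coordinates, selects the number
    of clusters by the elbow method, and assigns samples to population clusters
    with k-means. Companion tools quantify membership-inference risk via a
    Euclidean-distance attack calibrated at a fixed false-positive rate and a
    likelihood-ratio test over released minor-allele frequencies, and a
    Balding-Nichols simulator generates structured multi-population genotype
    data for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
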