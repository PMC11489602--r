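Package: symptomnet
Title: Mutual-Information Symptom Networks for Binary Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and characterization of symptom networks from
    patient-by-symptom binary (lifetime present/absent) matrices. Edge
    weights are plug-in mutual information in bits; edges are retained when
    they survive a surrogate-permutation null with false-discovery-rate
    correction. The resulting network is characterized by degree, strength,
    betweenness centrality, Borgatti-Everett core-periphery decomposition,
    and Louvain modularity communities. Includes a dichotomized-Gaussian
    synthetic-cohort generator with calibrated pairwise dependencies so the
    full pipeline can be exercised and validated without patient data, plus
    an end-to-end two-cohort analysis pipeline with reproducible,
    seed-deterministic outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
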