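Package: hic3dqc
Title: Quality Control and Reproducibility Scoring for Hi-C Contact Matrices
Version: 0.1.0
Authors@R:
    person("hic3dqc", "developers", email = "hic3dqc@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the quality and reproducibility of binned
    intrachromosomal Hi-C contact matrices. Implements four replicate
    similarity scores (a stratum-adjusted correlation coefficient with 2D
    mean-filter smoothing, a random-walk graph-smoothing concordance score,
    a spectral score based on leading eigenvectors of the normalized graph
    Laplacian, and an enrichment-weighted interaction-correlation score)
    plus a single-sample quality score derived from the same weighted
    correlation transform. Also provides a realistic noise model for contact
    maps (genomic-distance-effect noise and random-ligation noise, mixed at
    chosen proportions), uniform downsampling, pseudo-replicate
    construction, a synthetic contact-matrix generator with distance decay,
    domain and compartment structure, and a benchmark harness with
    empirical score thresholds and replicate-type ranking experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
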