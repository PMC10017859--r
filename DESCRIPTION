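Package: sdohmap
Title: Semantic Harmonization of Social-Determinants-of-Health Survey Items
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters syntactically distinct questionnaire items into
    social-determinants-of-health (SDOH) categories and maps the resulting
    categories onto a reference taxonomy.  The pipeline embeds question text
    as unit-norm vectors (a deterministic hashed n-gram encoder is built in;
    external sentence encoders plug in), reduces dimension with locally
    linear embedding, clusters on the unit sphere with spherical k-means
    (cosine distance), validates cluster reproducibility across train/test
    partitions with the In-Group Proportion statistic, and thresholds
    cosine similarities at the boxplot upper hinge to derive a bipartite
    category-to-reference mapping with coverage.  Includes generators for
    planted von Mises-Fisher mixtures and template-based question corpora
    so every stage is testable without external data, plus a reproducibility
    manifest for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
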