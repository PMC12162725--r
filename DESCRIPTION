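Package: irmaharm
Title: Iterated Relevance Matrix Analysis for Multi-Center Feature Harmonization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonization of multi-center, high-dimensional feature vectors
    (for example PCA features derived from brain FDG-PET scans) by iterated
    relevance matrix analysis (IRMA). A Generalized Matrix Learning Vector
    Quantization (GMLVQ) classifier is trained to recognise the acquisition
    center of healthy-control cohorts; the leading eigenvector of its
    relevance matrix is projected out and the model retrained, until center
    classification drops to chance. The accumulated eigenvectors span a
    center-specific subspace V whose orthogonal projector corrects both
    feature vectors and subsequently trained disease classifiers. The package
    also provides PCA-based feature extraction from masked image vectors,
    analytic reconstruction of original, removed and corrected profiles in
    voxel space, principal-angle diagnostics between model subspaces,
    per-feature Kruskal-Wallis group-difference counting, a center-wise
    z-scoring baseline, and a seeded multi-center synthetic data generator
    with planted center and disease subspaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
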