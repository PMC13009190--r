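Package: hippdiff
Title: Synthetic Multi-Shell Diffusion MRI Analysis of Hippocampal Microstructure Across Age
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses multi-shell diffusion MRI studies of
    age-related hippocampal gray-matter microstructure. Provides a fully
    synthetic study generator (acquisition scheme, cohort with age and sex
    structure, curved-slab hippocampal domain, compartment ground truth,
    Rician-noise signals), forward signal models and voxel-wise fitters for
    the diffusion tensor (DTI), Watson-dispersed stick (NODDI) and soma and
    neurite density (SANDI) models, Laplace-coordinate geometry with
    cosine-similarity orientation metrics, midthickness surface sampling
    with subfield and long-axis parcellation, and the study-level
    statistics: parcel-averaged Pearson age correlations, nested-GLM
    F-tests with Benjamini-Hochberg correction, vertex-wise age-contrast
    t-maps, positional-gradient correlations, and spatial permutation
    (spin) tests against reference maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    RNifti,
    jsonlite,
    pracma,
    minpack.lm,
    lhs,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
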