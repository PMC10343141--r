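Package: compkernel
Title: Kernel Methods for Supervised Learning on Compositional Data
Version: 0.1.0
Authors@R:
    person("Compkernel", "Developers", email = "compkernel@example.org",
           role = c("aut", "cre"))
Description: Supervised learning and compositionality-aware model
    interpretation for relative-abundance data such as microbiome
    profiles. Provides a family of positive (semi-)definite kernels
    targeted at the simplex (Euclidean, Aitchison/centered log-ratio,
    probability-distance and heat-diffusion kernels), kernel ridge
    regression and classification via the representer theorem, a
    two-step hierarchical cross-validation for joint kernel and
    penalty selection, prior-knowledge weighting of kernels from
    partitions or phylogenetic trees, compositional feature influence
    (CFI) and compositional perturbation dependence (CPD) statistics
    based on simplex-preserving perturbations, kernel PCA with
    component influence, kernel-distance summary scores including a
    data-adaptive alpha-diversity, and seeded synthetic generators for
    compositional covariates and log-contrast responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
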