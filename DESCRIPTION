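Package: bonefrag
Title: Synthetic-Phantom Analysis Chain for Murine Bone Fragility Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of the quantitative analysis chain used in
    preclinical mouse bone-fragility studies: micro-computed-tomography
    morphometry of trabecular and cortical bone (BV/TV, local-thickness Tb.Th
    and Tb.Sp, connectivity density by Euler characteristic, cortical area,
    minimum moment of inertia and section modulus), voxel-based linear-elastic
    micro-finite-element estimation of vertebral failure load by the
    strain-percentile (Pistoia-type) criterion, load-displacement curve
    analysis for three-point bending and vertebral compression (stiffness,
    yield, ultimate force, post-yield displacement, work-to-fracture, crack
    initiation toughness of micro-notched femora), CPMG T2 relaxometry with
    regularized non-negative inversion for matrix bound-water quantification,
    and the branching two-factor statistical procedure (parametric two-way
    ANOVA with residual diagnostics, aligned-rank-transform fallback, and
    family-structured Holm-Sidak or Dunn post-hoc comparisons). Every stage is
    exercised on synthetic phantoms with analytically known ground truth, so
    the full chain is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    nortest,
    car,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
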