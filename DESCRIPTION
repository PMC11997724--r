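Package: tractburden
Title: White-Matter Tract Lesion Burden and EMR Anxiety Phenotyping in
    Multiple Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies white-matter tract lesion burden by streamline
    filtering (streamlines intersecting lesion voxels are isolated and the
    volume they occupy is divided by the canonical tract volume, averaged
    over hemispheres), stratifies multiple-sclerosis patients into anxiety
    severity groups from structured EMR extracts (ICD-10 codes, medication
    orders, PHQ-2/PHQ-9 screens), scores PROMIS physical and emotional
    functioning summaries, and tests burden-phenotype associations with
    generalized additive models (penalized age spline, sex and total brain
    volume covariates), effect sizes and FDR control. A synthetic-cohort
    generator with planted effects makes the whole pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    mgcv,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'grid.R'
    'burden.R'
    'io-emr.R'
    'io-nifti.R'
    'io-streamlines.R'
    'phenotype.R'
    'stats-gam.R'
    'stats-tests.R'
    'synth-bundles.R'
    'synth-mask.R'
    'synth-cohort.R'
    'pipeline.R'
RoxygenNote: 7.3.3
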