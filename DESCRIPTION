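Package: glioVLSM
Title: Voxel-Based Lesion-Symptom Mapping of Tumor-Related Seizure
    Frequency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating the anatomical location of low-grade
    glioma lesions to the preoperative frequency of epileptic seizures.
    Implements mass-univariate voxel-based lesion-symptom mapping
    (VLSM): a per-voxel general linear model of binary lesion status on
    an ordinal seizure-frequency score with sex, age and tumor-volume
    nuisance covariates, permutation-based voxel-wise thresholding,
    lesion-overlap and statistical-power maps, 3D cluster and peak
    extraction, and peak-involvement labeling. Also provides the
    accompanying clinical statistics (contingency tests, rank tests,
    multivariate logistic regression, cohort summary tables) and a
    synthetic lesion-cohort generator with a hidden epileptogenic
    region of interest for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'clinical.R'
    'imaging-io.R'
    'vlsm.R'
    'clusters.R'
    'reference-cohort.R'
    'simulate.R'
    'pipeline.R'
    'utils.R'
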