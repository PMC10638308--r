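Package: rbfshapley
Title: Exact Shapley Values for RBF Kernel Support Vector Machines on
    Binary Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form, exact Shapley values for the Gaussian radial basis
    function (RBF) kernel between sparse binary feature vectors, such as
    molecular fingerprints, and their extension to full support vector
    machine (SVM) explanations. Because the RBF kernel between binary
    vectors depends only on the counts of intersecting and symmetric-
    difference features, per-feature Shapley values admit exact
    combinatorial expressions evaluated stably in log space, avoiding the
    exponential cost of coalition enumeration. The package attributes the
    SVM decision-function distance and Platt-scaled log-odds to individual
    features, provides a brute-force coalition enumeration oracle for
    validation at small union sizes, deterministic generators for synthetic
    vectors and toy SVM models, an adapter for fitted 'e1071' models, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'sparse-vectors.R'
    'vector-io.R'
    'generators.R'
    'kernel-shapley.R'
    'exhaustive.R'
    'svm-explainer.R'
    'model-io.R'
    'reporting.R'
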