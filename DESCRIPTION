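Package: imspeaks
Title: Modular Automated Peak Extraction for MCC/IMS Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular pipeline framework for fully automated peak extraction
    from ion mobility spectrum-chromatograms (IMSCs) produced by ion mobility
    spectrometers coupled to multi-capillary columns (MCC/IMS). Provides three
    preprocessing modules (EM-based baseline correction, mixture-model
    de-noising, FFT lowpass plus Savitzky-Golay smoothing), two peak candidate
    detectors (local maxima, zero-crossing cross finding), three peak pickers
    (merging by signal intensity, weighted cluster editing with an exact
    internal solver, EM clustering), an optional shifted-Inverse-Gaussian peak
    model estimation stage, peak-list evaluation metrics (sensitivity, positive
    predictive value, Fowlkes-Mallows index, Jaccard distance, Pareto fronts),
    and a seeded synthetic-measurement generator with planted ground-truth
    peaks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'params.R'
    'io.R'
    'mixtures.R'
    'preprocess.R'
    'candidates.R'
    'picking.R'
    'cluster-editing.R'
    'modeling.R'
    'evaluation.R'
    'pipeline.R'
    'synthetic.R'
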