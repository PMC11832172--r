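Package: metdms
Title: Inhibitor Deep Mutational Scanning Analysis for the MET Kinase Domain
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled Ba/F3 deep-mutational-scanning selections of
    the MET kinase domain against a panel of ATP-competitive inhibitors.
    Simulates saturation-mutagenesis selection experiments with known
    ground-truth fitness, filters and scores variant counts on a
    cell-doubling-rate scale by wild-type-normalized log2 regression over
    time points, classifies inhibitor-specific resistance mutations and
    gain/loss-of-function effects, aggregates resistance hotspots by
    inhibitor type, compares condition profiles by Pearson correlation, and
    implements a block-holdout machine-learning protocol (feature binning,
    monotone constraints, position/amino-acid/inhibitor splits, exhaustive
    feature-subset enumeration) for fitness prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, PooledScreens, FunctionalGenomics
RoxygenNote: 7.3.3
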