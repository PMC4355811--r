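Package: gpes
Title: Genetic-Programming Ensembles of Decision Trees for Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies high-dimensional, small-sample gene expression data with
    an evolved ensemble of decision trees. Base classifiers are CART trees grown
    on random feature subspaces of a multi-selector candidate pool and on
    class-balanced subsamples; genetic programming evolves ternary fusion trees
    whose internal nodes are Min, Max and Average vote operators over hard
    -1/+1 votes; the final committee is chosen by a forward search that greedily
    minimises majority-voting error on a held-out fold. Includes one-vs-one and
    one-vs-rest decomposition for multiclass problems, micro-averaged F-score and
    average per-class accuracy metrics, and a synthetic microarray-like data
    generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rpart,
    e1071,
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
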