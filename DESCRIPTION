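Package: ftlrec
Title: Crossover Frequency and Interference Analysis for Fluorescent Tagged Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of fluorescent tagged line (FTL) crossover reporter
    experiments. Provides genetic-distance estimators with standard errors for
    four scoring modalities (two- and three-colour pollen flow cytometry,
    fluorescent seed counts, and pollen tetrads via the Perkins formula),
    crossover-interference statistics (coefficient of coincidence,
    adjacent-interval tetrad analysis, Fisher's combined probability test),
    binomial GLM comparisons of recombinant fractions, hot/cold-quartile
    contingency and permutation-thresholded LOD-scan marker association for F2
    populations, and a four-strand meiosis simulator with a gamma-renewal
    interference model that generates every count modality the estimators
    consume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
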