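Package: probesim
Title: Similarity of Alternative Microarray Probe Sets from Transcriptional Covariation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the similarity of alternative Affymetrix probe sets
    (distinct probe sets mapping to the same gene) from their transcriptional
    covariation across many biological comparisons.  Builds positive/negative
    covariation networks from ternary increased/decreased/not-changed calls,
    filters edges against an empirical random-pair null, scores neighbourhood
    overlap with the hypergeometric distribution, classifies probe-set/gene
    biclusters, calibrates a three-condition similarity test across networks,
    aggregates similar probe sets into groups via triangles, and provides
    downstream analyses: rank-difference distributions, per-comparison
    correlation statistics, probe-set merging and Markov clustering with
    reproducibility metrics.  A seeded synthetic-data generator with planted
    transcript modules makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
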