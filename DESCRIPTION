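Package: dropspect
Title: Droplet-Microfluidics Natural-Product Discovery Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational companion for droplet-microfluidics plus
    FACS-based natural-product discovery campaigns. Provides the Poisson
    design mathematics of single-cell encapsulation (occupancy
    distributions, co-encapsulation probability, droplet geometry and
    throughput planning), community diversity statistics on taxon
    abundance tables (rare-taxon filtering, Shannon index,
    Kruskal-Wallis rank test with Dunn's post hoc comparisons),
    LC-MS feature bucketing with cosine-similarity metabolic grouping,
    genotype redundancy curation from binary fingerprint band patterns
    (Dice similarity, Ward clustering, superimposition with metabolic
    groups), bioactivity-guided dereplication by exact monoisotopic mass
    at ppm tolerance, MS/MS molecular networking with shared-fragment
    edge filtering, and seeded synthetic-data generators with planted
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
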