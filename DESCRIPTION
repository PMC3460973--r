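Package: acofold
Title: Hybrid Ant-Colony and Monte-Carlo Fragment Assembly for De Novo
    Protein Backbone Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained (centroid) de novo protein backbone prediction
    by fragment assembly.  Couples MAX-MIN Ant System (MMAS) colonies that
    share a single pheromone matrix -- each colony minimising a different
    composite centroid score -- with a multi-stage Metropolis Monte-Carlo
    fragment-assembly predictor, exchanging accepted fragments and
    iteration-best torsion perturbations in both directions.  Includes
    torsion-space backbone reconstruction, Kabsch C-alpha RMSD, Rosetta
    fragment-file reading and a synthetic fragment-library generator, the
    staged composite centroid scores (score0-score3/score5), and
    decoy-population statistics (lower-half filtering, union-by-score,
    percentile bootstrap, rank-sum comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
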