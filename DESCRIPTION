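Package: hydroscreen
Title: Screening Anaerobic Digester Microbiomes for Hydrolytic Candidate Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate cellulolytic and xylanolytic microorganisms
    in anaerobic digesters by linking fluorometric hydrolase assays to 16S
    rRNA amplicon time series. Converts 4-methylumbelliferone (MUF)
    plate-reader kinetics into blank-corrected hydrolase activities, filters
    and summarizes ASV count tables (read-depth filtering, relative
    abundance, Chao1 and Shannon diversity, taxonomic aggregation), performs
    correspondence analysis and activity-constrained redundancy analysis
    with permutation tests, and screens ASVs for similarity to enzyme
    activity trajectories using z-score normalization, an exact two-sample
    Kolmogorov-Smirnov test, and linear-regression ranking. A synthetic-data
    module simulates reactor time series with planted responder taxa so the
    whole pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    biomformat,
    optparse
Config/testthat/edition: 3
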