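Package: domsuite
Title: Multi-Assay Dominance Analysis for Group-Housed Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying social dominance in group-housed laboratory
    mice across multiple behavioral assays. Implements dyadic outcome scoring
    (Elo ratings with ties, David's scores, the directional consistency index,
    and assay-specific dyad stability classification), post-processing of
    two-animal pose-estimation tracks into agent- and rotation-invariant
    features, unsupervised behavioral-state discovery by k-means with
    rank-difference enrichment statistics, and cross-assay comparison of
    dominance rankings (score correlation matrices and stable-pair rank
    reversals). Synthetic generators for latent-hierarchy match streams and
    scripted two-mouse arena trajectories provide ground truth for
    end-to-end validation, and a pipeline driver chains the stages from a
    single configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    signal,
    uwot,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    rhdf5,
    optparse
Config/testthat/edition: 3
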